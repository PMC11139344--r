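---
title: "Selection on environmentally mediated social traits under isolation by distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection on environmentally mediated social traits under isolation by distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdsel)
```

## The model

`ibdsel` analyses the evolution of a quantitative trait whose fitness
consequences travel through a *lasting environmental variable* — a
common-pool resource, a toxin, habitat quality — in a population of `D`
patches of `N` adults arranged on a circular or toroidal lattice. Because
patches are arranged homogeneously, the set of patch displacements forms
a finite abelian group, and every spatial computation in the package is
an exact Fourier computation on that group: a field of one value per
displacement `k` has a spectrum of one value per frequency `h`, with the
transform defined through the characters
$\chi_k(h) = \exp(2\pi i \sum_j k_j h_j / D_j)$. The package follows the
population-genetics sign convention: the *forward* transform uses
$\chi$, so the transform of a probability kernel is its characteristic
function, and the inverse uses the conjugate. This is the reverse of the
usual engineering convention, and every downstream formula assumes it.

The life cycle each generation is: payoff-dependent reproduction and
(optionally) adult survival; dispersal of offspring by a symmetric
kernel $m_k$; density-dependent regulation back to exactly `N` adults
per patch. Three layers of theory are implemented on top of this:

1. **Neutral genetic structure.** Under a Wright–Fisher life cycle the
   relatedness between a focal individual and a random individual at
   displacement `k`, `t` generations apart, has the closed form
   implemented in `relatedness_wf()`: a frequency sum in
   $M(h)^t / (1 - M(h)^2)$ normalised so that relatedness averages to
   zero over the lattice. Same-generation coefficients equal the
   two-generation ones. `walk_distribution()` gives the distribution
   $p_{k,t}$ of a gene lineage `t` steps forward — the `t`-fold
   convolution of the dispersal kernel.

2. **Scaled relatedness.** What matters for selection is relatedness
   *discounted by kin competition*: the number of payoff units a focal
   individual would exchange with an individual at `(k, t)` without
   changing a rare mutant's fate. The package computes this genetic
   value $\kappa_{k,t}$ by two independent routes — its definition
   (relatedness minus competition terms weighted by the numeric
   coefficients $\lambda_k$ from `lambda_from_fitness()`) and the
   closed life-cycle-specific spectra of `kappa_general()` — and the
   test suite holds the two routes to $10^{-8}$ of each other. Under
   Wright–Fisher reproduction $\kappa_{k,0} = -1/(DN-1)$ for every `k`,
   which is why direct helping of contemporaries is never favoured in
   that life cycle, while $\kappa_{k,t} \propto p_{k,t} - 1/D$ for
   `t ≥ 1`: future patches that a focal lineage is *more* likely than
   average to occupy carry positive genetic value.

3. **Extended phenotypic effects.** A trait change perturbs the
   environment of possibly every patch at every future time. With a
   deterministic environmental map, the whole cascade is summarised by
   two one-generation fields: the focal individual's direct effect
   $\psi_k$ and the environment-to-environment coupling $c_k$. The
   effect at horizon `t` is then the inverse transform of
   $\Psi(h) C(h)^{t-1}$ (`extended_effects()`), a formula the tests
   validate against the direct spatial recursion. Coupled
   multi-variable environments are supported by per-frequency matrix
   powers (`extended_effects_multi()`), computed by repeated
   multiplication rather than eigendecomposition so that defective
   coupling matrices pose no problem.

Selection gradients assemble these pieces. In the payoff-mediated form,
the gradient is (up to a positive constant) the focal's effect on its
own payoff, plus effects on contemporaries weighted by $\kappa_{k,0}$,
plus environmentally mediated effects on future payoffs weighted by
$N \kappa_{k,t}$. With local payoffs everything collapses to three
numbers (`gradient_payoff_local()`), the environmental part carried by
the scalar `K` of `K_statistic()`.

### A note on the resolvent form of K

`K_statistic()` evaluates the infinite double sum
$K = \sum_{t\ge 1}\sum_k e_{k,t}\,\kappa_{k,t}$ in closed form by
summing the geometric series frequency by frequency. Writing
$B(h) = s + (1-s)M(h)$ for the spectrum of one backward lineage step
(an adult survives in place with probability `s`, otherwise its slot is
filled through dispersal), the per-frequency factor is
$B(h)\,/\,[1 - C(-h)B(h)]$. We derived this form directly from the
series because it is the unique resolvent consistent with the
scaled-relatedness spectra and the spectral propagation of extended
effects; the package's tests verify the agreement between the resolvent
and the truncated series to $10^{-8}$ for fecundity, survival and mixed
life cycles. At `s = 0` it reduces to the familiar
$M(h)/[1 - C(-h)M(h)]$ factor of the Wright–Fisher fecundity case.

## The lasting-commons model

`commons_model()` is the package's fitting-style entry point. Payoff is
$\pi = \exp(B n^{\alpha_B} - C z^{\alpha_C})$ with $\alpha_B$ odd,
$\alpha_C$ even and $\alpha_C > \alpha_B$ (costs steepen faster than
benefits), so producing the commons is individually costly whatever its
sign. The commons is produced locally at rate $P(z)$ per patch, moves by
a kernel $d_k$, and decays at rate $\epsilon \in (0, 1]$; in a
monomorphic population it equilibrates at $\hat n = P(z)/\epsilon$.

The central quantity is $\Omega$, the expected genetic value (in payoff
units) of all future individuals reached by a unit of commons produced
in the focal patch. Selection at `z = 0` is proportional to $\Omega$:
a positive value favours building a common good (inter-temporal
altruism), a negative value favours a common bad — indiscriminate,
posthumous spite, since under non-overlapping generations all recipients
live after the actor's death. The object computes $\Omega$ by four
routes (`omega()`): the resolvent closed form; the truncated series over
$\epsilon(1-\epsilon)^{t-1}\kappa_{k,t}q_{k,t}$; for Wright–Fisher
fecundity, the covariance form
$\propto \sum_t (1-\epsilon)^{t-1}\mathrm{cov}(p_t, q_t)$ between the
gene walk and the commons walk, which is the biological reading of the
sign of $\Omega$; and the weak-dispersal limit
$\Omega \approx \frac{D-1}{DN-1}\cdot\frac{\epsilon - m - d}{\epsilon}$,
which we derived by first-order expansion of the resolvent in the total
movement probabilities `m` and `d` (the displayed small-parameter
expression is stated ambiguously in the primary literature, so the
package treats the closed form as authoritative and the limit as an
approximation validated numerically — it is accurate to well under a
percent at `m = d = 0.01`).

With linear production $P(z) = P_0 z$, the singular strategy has the
closed form $z^* = [(B/C)(\alpha_B/\alpha_C)(P_0/\epsilon)^{\alpha_B}\,
\Omega]^{1/(\alpha_C-\alpha_B)}$, interpreted as the real odd root so
that $z^*$ carries the sign of $\Omega$; it is convergence stable
whenever $\alpha_C > \alpha_B$, which `convergence_check()` verifies
numerically.

```{r}
lat <- patch_lattice(c(7, 7))
mod <- commons_model(
  lattice = lat, N = 20,
  m_kernel = truncated_binomial_kernel(lat, 0.3, 1.5),
  d_kernel = truncated_binomial_kernel(lat, 1.0, 5),
  B = 2, alpha_B = 1, C = 1, alpha_C = 4,
  epsilon = 0.5, P0 = 20
)
mod
```

## The individual-based simulator

`simulate()` on a `commons_model` runs a stochastic Wright–Fisher
lattice simulation that makes none of the analytic approximations: `N`
discrete individuals per patch, multinomial recruitment, explicit
mutation. One generation applies, in order: individual payoffs from own
trait and local commons; the commons update from *parental* patch-mean
traits (the deterministic map — the model has no environmental noise, so
under a monomorphic population the simulated commons tracks the analytic
trajectory exactly, which the tests assert); recruitment of each of the
`N` slots per patch by two-stage sampling (source patch proportional to
dispersal times total source fecundity, then parent within source
proportional to individual fecundity — the scheme whose expectation is
exactly the survival–fecundity fitness function, checked on a two-patch
configuration); then Gaussian mutation.

What the generator emulates — and what it does not: trait variation is
mutation-limited (probability $10^{-4}$ per offspring, step s.d.
$10^{-2}$, the worked-example regime), generations do not overlap
(fecundity selection, `s = 0`), and the environment is deterministic
given traits. Real systems add demographic and environmental
stochasticity, overlapping generations and non-lattice geometry, so
passing recovery tests demonstrates correctness of the machinery under
the model's own assumptions, not robustness beyond them.

The recovery experiment initialises the population at the predicted
$z^*$ and asks whether it stays there: the post-burn-in mean trait
should lie within two standard deviations (of the per-generation
population mean) of the analytic prediction. The packaged experiment
uses a 7 × 7 lattice of 20 adults for 4,000 generations with a 1,000
generation burn-in — sizes chosen so the whole suite runs comfortably on
a laptop while leaving the mutation process enough events (~400) to
probe the equilibrium — with one parameter set in the spite regime
(short-range dispersal `m = 0.3`, full long-range commons movement
`d = 1`, mean distance 5) and one in the altruism regime (weak dispersal
and movement, `m = d = 0.1`). The corresponding full-scale setting
(13 × 13, `N = 50`, 20,000 generations) is reproducible with
`run_simulation()` on the bundled `commons_spite_2d.yaml` configuration.

## Numerical choices

* Transforms are explicit matrix products against the precomputed
  character table — exact with respect to the definition, $O(D^2)$
  memory and time, appropriate for the intended `D` of at most a few
  hundred patches.
* Inverse transforms of symmetric inputs must be real: an imaginary
  residue above $10^{-9}(1 + \max|\mathrm{Re}|)$ raises an error rather
  than being silently dropped.
* Kernel validation tolerances: mass within $10^{-10}$ of one, symmetry
  within $10^{-12}$; negative entries beyond $-10^{-12}$ are errors,
  smaller round-off is clipped and renormalised.
* The truncated-binomial distance kernel draws the minimal-image
  Manhattan distance `r` from a binomial with index the largest
  realisable distance, truncated to `r ≥ 1`, with the success
  probability solved by root bracketing so the conditional mean matches
  the requested value; the mass at each distance is split evenly over
  all displacement vectors of that norm, which makes symmetry exact.
  The movement probability may be 1 (everything moves), as in the
  long-range worked examples.
* Numeric differentiation uses central differences with steps
  $10^{-5}$ (competition coefficients, gradient slopes) or $10^{-6}$
  (environmental maps) scaled by the argument magnitude; the
  competition coefficients additionally require agreement between two
  step sizes to $10^{-6}$ and raise otherwise.
* Series truncations stop when a geometric tail bound — driven by
  $(1-\epsilon)$ for the commons series and by $\max_h|C(h)M(h)|$ for
  the generic effect series — falls below $10^{-12}$ of the partial sum.
* Degenerate inputs raise errors rather than being regularised:
  non-mixing kernels (some frequency with $|M(h)| = 1$), vanishing
  scaled-relatedness denominators, amplifying environmental feedback
  ($|C(-h)B(h)| \ge 1$), non-fixed-point environmental states, and
  all-zero fecundities in the simulator.

## Design decisions and limitations

* The definitional route to scaled relatedness combines the
  Wright–Fisher relatedness closed form with numeric competition
  coefficients. That identity is exact only for life cycles without
  baseline adult survival (`s = 0`, any payoff effects on survival or
  fecundity): with overlapping generations the neutral relatedness is no
  longer the Wright–Fisher form, so the package's cross-route tests
  cover `s = 0` grids, and relatedness under adult survival is
  deliberately not offered — life-cycle dependence enters only through
  scaled relatedness.
* Gradients are reported up to their positive proportionality constant;
  zeros and signs are the meaningful output, and the commons closed-form
  gradient equals the generic payoff-form assembly divided by the
  (positive) resident payoff.
* Same-generation relatedness is served by the documented two-generation
  substitution rather than a separate formula; the general
  scaled-relatedness spectra use their own `t = 0` branch directly.
* Conditions under which the scaled-relatedness denominator
  $1 - \sum_j \lambda_j R_{j,0}$ could vanish are not characterised
  analytically; the implementation raises rather than regularises.
* Environmental dynamics must have a unique hyperbolically stable
  monomorphic equilibrium; the only stability diagnostic applied is the
  spectral condition on the feedback ($|C(h)| B$-resolvent bounds), so
  maps violating hyperbolicity fail only at that check.
* Under survival effects (payoff acting on survival, birth–death
  updating), the machinery predicts harming to be favoured at low
  baseline survival in combination with substantial decay of the
  commons; claims in the literature that harming is favoured
  specifically at *low* decay rely on a supplementary closed form this
  package intentionally does not implement, and are not reproduced by
  the self-consistent machinery implemented here.
* Anisotropic or asymmetric dispersal, non-product group structures,
  infinite lattices, stochastic environmental dynamics and multi-trait
  joint evolution are out of scope.
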