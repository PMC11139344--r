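#' Life-cycle specification
#'
#' Survival and fecundity as functions of individual payoff, summarised
#' by their values and derivatives at the resident point (payoff 1):
#' baseline survival `s` in \[0, 1), its payoff-derivative `s_prime`,
#' fecundity `f > 0` and its payoff-derivative `f_prime`. At least one of
#' the derivatives must be nonzero (payoff must affect fitness). The
#' object also carries the survival and fecundity functions themselves
#' (by default the linear extensions around payoff 1), which are used by
#' the numeric fitness machinery.
#'
#' @param s baseline survival probability at the resident payoff.
#' @param s_prime derivative of survival with respect to payoff.
#' @param f fecundity at the resident payoff.
#' @param f_prime derivative of fecundity with respect to payoff.
#' @param s_fun,f_fun optional survival/fecundity functions of payoff;
#'   they must be consistent with the supplied values and derivatives at
#'   payoff 1.
#' @return an object of class `lifecycle`.
#' @export
lifecycle <- function(s, s_prime, f, f_prime, s_fun = NULL, f_fun = NULL) {
  if (s < 0 || s >= 1) stop("'s' must lie in [0, 1)", call. = FALSE)
  if (f <= 0) stop("'f' must be positive", call. = FALSE)
  if (s_prime == 0 && f_prime == 0) {
    stop("payoff must affect fitness: 's_prime' and 'f_prime' cannot both be 0",
         call. = FALSE)
  }
  if (is.null(s_fun)) s_fun <- function(p) s + s_prime * (p - 1)
  if (is.null(f_fun)) f_fun <- function(p) f + f_prime * (p - 1)
  structure(list(s = s, s_prime = s_prime, f = f, f_prime = f_prime,
                 s_fun = s_fun, f_fun = f_fun),
            class = "lifecycle")
}

#' @rdname lifecycle
#' @details `lifecycle_wf()` is the Wright-Fisher fecundity preset: no
#'   adult survival, payoff is directly fecundity (`f(p) = p`).
#'   `lifecycle_survival()` is the survival-effects (birth-death) preset:
#'   constant fecundity, payoff affects survival only.
#' @export
lifecycle_wf <- function() {
  lifecycle(s = 0, s_prime = 0, f = 1, f_prime = 1,
            s_fun = function(p) rep(0, length(p)),
            f_fun = function(p) p)
}

#' @rdname lifecycle
#' @param slope derivative of survival with respect to payoff for the
#'   survival-effects preset.
#' @export
lifecycle_survival <- function(s, slope = 1) {
  lifecycle(s = s, s_prime = slope, f = 1, f_prime = 0,
            f_fun = function(p) rep(1, length(p)))
}

as_lifecycle <- function(x) {
  if (inherits(x, "lifecycle")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(switch(x,
                  wf_fecundity = lifecycle_wf(),
                  survival_effects = lifecycle_survival(s = 0.9),
                  stop(sprintf("unknown life-cycle preset '%s'", x), call. = FALSE)))
  }
  if (is.list(x)) {
    return(lifecycle(s = x$s, s_prime = x$s_prime, f = x$f, f_prime = x$f_prime))
  }
  stop("cannot interpret 'x' as a life cycle", call. = FALSE)
}

#' Survival-fecundity fitness function
#'
#' Expected number of successful offspring (including the surviving
#' self) of a focal individual, given its own payoff, the average payoff
#' in every patch, the dispersal kernel and the life cycle: survival plus
#' offspring that win one of the openings left by deaths in each patch,
#' in competition with all fecundity arriving there. In a monomorphic
#' population at equal payoffs this evaluates to exactly 1.
#'
#' @param pi_focal payoff of the focal individual.
#' @param pi_field numeric vector of average payoffs per patch
#'   (displacement-indexed; entry 1 is the average payoff of the focal
#'   individual's patch neighbours, excluding the focal).
#' @param kernel dispersal `dispersal_kernel`.
#' @param N adults per patch.
#' @param lc a [lifecycle()].
#' @return scalar fitness.
#' @export
fitness_sf <- function(pi_focal, pi_field, kernel, N, lc) {
  lat <- kernel$lattice
  check_field(pi_field, lat, "pi_field")
  lc <- as_lifecycle(lc)
  s_field <- lc$s_fun(pi_field)
  f_field <- lc$f_fun(pi_field)
  sR <- s_field
  fR <- f_field
  sR[1L] <- lc$s_fun(pi_focal) / N + (N - 1) * s_field[1L] / N
  fR[1L] <- lc$f_fun(pi_focal) / N + (N - 1) * f_field[1L] / N
  A <- group_convolve(fR, kernel$field, lat)   # incoming fecundity per patch
  if (any(A <= 0)) stop("degenerate life cycle: non-positive competing fecundity",
                        call. = FALSE)
  lc$s_fun(pi_focal) +
    sum(kernel$field * (1 - sR) * lc$f_fun(pi_focal) / A)
}

#' Competition coefficients from the fitness function
#'
#' The coefficient \eqn{\lambda_k = -(\partial \tilde w / \partial \pi_k)
#' / (\partial \tilde w / \partial \pi_\bullet)} measures how much an
#' increase in the payoff of individuals at displacement `k` reduces the
#' focal individual's fitness, relative to the effect of the focal's own
#' payoff; it is the strength of competition at distance `k`. Derivatives
#' are taken numerically (central differences with a Richardson step
#' check) on [fitness_sf()] at the resident point where all payoffs
#' equal 1 and fitness equals 1.
#'
#' @inheritParams fitness_sf
#' @return numeric field of competition coefficients over displacements.
#' @export
lambda_from_fitness <- function(kernel, N, lc) {
  lc <- as_lifecycle(lc)
  lat <- kernel$lattice
  base <- rep(1, lat$D)
  h <- 1e-5 * 2  # payoff scale is 1

  grad <- function(step) {
    dfocal <- (fitness_sf(1 + step, base, kernel, N, lc) -
               fitness_sf(1 - step, base, kernel, N, lc)) / (2 * step)
    dk <- vapply(seq_len(lat$D), function(k) {
      up <- base; up[k] <- 1 + step
      dn <- base; dn[k] <- 1 - step
      (fitness_sf(1, up, kernel, N, lc) -
       fitness_sf(1, dn, kernel, N, lc)) / (2 * step)
    }, numeric(1L))
    list(dfocal = dfocal, dk = dk)
  }

  g1 <- grad(h / 2)
  g2 <- grad(h)
  if (abs(g1$dfocal) < 1e-10) {
    stop("ill-conditioned: fitness is insensitive to the focal payoff",
         call. = FALSE)
  }
  lam1 <- -g1$dk / g1$dfocal
  lam2 <- -g2$dk / g2$dfocal
  if (max(abs(lam1 - lam2)) > 1e-6) {
    stop("numeric differentiation of the fitness function did not converge",
         call. = FALSE)
  }
  lam1
}

#' Scaled relatedness under a Wright-Fisher process
#'
#' The genetic value, in payoff units, of individuals at displacement
#' `k`, `t` generations in the future, for the Wright-Fisher fecundity
#' life cycle: \eqn{\kappa_{k,0} = -1/(DN-1)} for all `k` (so helping
#' contemporaries is never favoured), and for \eqn{t \ge 1}
#' \eqn{\kappa_{k,t} = D (p_{k,t} - 1/D) / (DN - 1)} where
#' \eqn{p_{k,t}} is the neutral gene random walk ([walk_distribution()]).
#'
#' @param kernel dispersal `dispersal_kernel`.
#' @param N adults per patch (with `DN >= 2`).
#' @param t non-negative integer temporal distance.
#' @return numeric field of scaled-relatedness coefficients.
#' @export
kappa_wf <- function(kernel, N, t) {
  lat <- kernel$lattice
  if (lat$D * N < 2) stop("'DN' must be at least 2", call. = FALSE)
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t != floor(t)) {
    stop("'t' must be a non-negative integer", call. = FALSE)
  }
  if (t == 0) return(rep(-1 / (lat$D * N - 1), lat$D))
  p <- walk_distribution(kernel, t)
  lat$D * (p - 1 / lat$D) / (lat$D * N - 1)
}

#' Scaled relatedness for a general survival-fecundity life cycle
#'
#' Closed-form scaled-relatedness coefficients \eqn{\kappa_{k,t}} for the
#' fitness model of [fitness_sf()], computed by inverse Fourier
#' transforms of the life-cycle-dependent spectra
#' \deqn{F(h) = \frac{-(1-s)(s'f - 2 f' s) M(h)}{1 + s + (1-s) M(h)},
#'   \quad
#'   G_t(h) = \frac{(1+s)\,[s'f + f'(1-s)(1 + M(h))]\,[s + (1-s)M(h)]^t}
#'                 {1 + s + (1-s) M(h)}.}
#' With no adult survival and payoff acting as fecundity this reduces to
#' [kappa_wf()].
#'
#' @inheritParams kappa_wf
#' @param lc a [lifecycle()] or preset name.
#' @return numeric field of scaled-relatedness coefficients.
#' @export
kappa_general <- function(kernel, N, lc, t) {
  lc <- as_lifecycle(lc)
  lat <- kernel$lattice
  check_mixing(kernel)
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t != floor(t)) {
    stop("'t' must be a non-negative integer", call. = FALSE)
  }
  M <- kernel$spectrum
  s <- lc$s; sp <- lc$s_prime; f <- lc$f; fp <- lc$f_prime
  a <- (1 + s) * (sp * f + 2 * fp * (1 - s)) / (2 * lat$D)
  Fh <- -(1 - s) * (sp * f - 2 * fp * s) * M / (1 + s + (1 - s) * M)
  LF <- inverse_transform(as.complex(Fh), lat)
  denom <- N * (sp * f + fp * (1 - s)) + LF[1L] - a
  if (abs(denom) < 1e-12) {
    stop("degenerate life cycle: scaled-relatedness denominator vanishes",
         call. = FALSE)
  }
  if (t == 0) return((LF - a) / denom)
  Gh <- (1 + s) * (sp * f + fp * (1 - s) * (1 + M)) *
    (s + (1 - s) * M)^t / (1 + s + (1 - s) * M)
  LG <- inverse_transform(as.complex(Gh), lat)
  (LG - a) / denom
}

#' Scaled relatedness assembled from its definition
#'
#' Assembles \eqn{\kappa_{k,t}} from relatedness coefficients and the
#' competition coefficients \eqn{\lambda_k}: relatedness toward the
#' recipients, discounted by the relatedness-weighted increase in
#' competition that raising their payoff inflicts on the focal individual
#' and its relatives, normalised by the same discount applied to the
#' focal's own payoff. This is the definitional route; it must agree with
#' the closed forms [kappa_wf()] / [kappa_general()], which is the
#' package's principal internal consistency check.
#'
#' @param lambda_field numeric field of competition coefficients
#'   ([lambda_from_fitness()]).
#' @param relatedness a [relatedness_table()] covering `t` (and 0).
#' @param N adults per patch.
#' @param t non-negative integer temporal distance.
#' @return numeric field of scaled-relatedness coefficients.
#' @export
kappa_from_definition <- function(lambda_field, relatedness, N, t) {
  stopifnot(inherits(relatedness, "relatedness_table"))
  lat <- relatedness$lattice
  check_field(lambda_field, lat, "lambda_field")
  R0 <- rel_at(relatedness, 0)
  Rt <- rel_at(relatedness, t)
  # corr0[k] = sum_j lambda_j R_{j-k, 0}; likewise at temporal distance t
  Rm0 <- matrix(R0[lat$sub], lat$D, lat$D)
  corr0 <- as.vector(crossprod(Rm0, lambda_field))
  den <- 1 - sum(lambda_field * R0)
  if (abs(den) < 1e-12) {
    stop("scaled-relatedness denominator 1 - sum(lambda * R) vanishes",
         call. = FALSE)
  }
  if (t == 0) {
    if (N < 2) stop("the same-generation branch requires N >= 2", call. = FALSE)
    num <- Rt - lambda_field * (1 / N + (N - 1) * R0[1L] / N) -
      (corr0 - lambda_field * R0[1L])
    num[1L] <- Rt[1L] -
      lambda_field[1L] * (1 / (N - 1) + (N - 2) * R0[1L] / (N - 1)) -
      (corr0[1L] - lambda_field[1L] * R0[1L])
    return(num / den)
  }
  Rmt <- matrix(Rt[lat$sub], lat$D, lat$D)
  corrt <- as.vector(crossprod(Rmt, lambda_field))
  (Rt - corrt) / den
}

#' Summary statistic for selection through the environment
#'
#' The scalar \eqn{K = \sum_{t \ge 1} \sum_k e_{k,t} \kappa_{k,t}}
#' summarising selection on environmentally mediated social interactions
#' under local payoffs, evaluated by its closed resolvent form over
#' frequencies. Writing \eqn{B(h) = s + (1-s)M(h)} for the spectrum of
#' one backward lineage step (survive in place or be replaced by a
#' dispersing recruit),
#' \deqn{K = \frac{1}{H} \sum_{h \ne 0}
#'   \frac{(1+s)[s'f + f'(1-s)(1+M(h))]\, B(h)\, \Psi(-h)}
#'        {[1 + s + (1-s)M(h)]\,[1 - C(-h)\,B(h)]},}
#' with \eqn{H = (DN-1)[s'f + f'(1-s)] - \sum_{h \ne 0}
#' (1-s)[s'f - 2f's] M(h) / [1 + s + (1-s)M(h)]}. This is obtained by
#' summing the geometric series in the double sum
#' \eqn{\sum_{t \ge 1} \sum_k e_{k,t} \kappa_{k,t}} frequency by
#' frequency, and agrees with that series to numerical precision for
#' every admissible life cycle. Selection favours
#' trait values that improve (`K > 0`) or deteriorate (`K < 0`) the
#' environment; when `K = 0` selection is blind to environmental effects.
#'
#' @param m_kernel dispersal `dispersal_kernel`.
#' @param psi_spectrum complex spectrum of the one-generation trait
#'   effect field \eqn{\psi_k}.
#' @param c_spectrum complex spectrum of the one-generation
#'   environment-to-environment effect field \eqn{c_k}.
#' @param N adults per patch.
#' @param lc a [lifecycle()] or preset name.
#' @return scalar `K`.
#' @export
K_statistic <- function(m_kernel, psi_spectrum, c_spectrum, N, lc) {
  lc <- as_lifecycle(lc)
  lat <- m_kernel$lattice
  check_field(psi_spectrum, lat, "psi_spectrum")
  check_field(c_spectrum, lat, "c_spectrum")
  check_mixing(m_kernel)
  M <- m_kernel$spectrum
  s <- lc$s; sp <- lc$s_prime; f <- lc$f; fp <- lc$f_prime
  Psim <- psi_spectrum[lat$neg]   # Psi(-h)
  Cm <- c_spectrum[lat$neg]       # C(-h)
  Bh <- s + (1 - s) * M           # backward lineage step spectrum
  if (lat$D > 1L && max(abs(Cm[-1L] * Bh[-1L])) >= 1 - 1e-12) {
    stop("divergent series: the lineage-commons resolvent |C(h) B(h)| ",
         "reaches 1 at a nonzero frequency", call. = FALSE)
  }
  H <- (lat$D * N - 1) * (sp * f + fp * (1 - s)) -
    sum((1 - s) * (sp * f - 2 * fp * s) * M[-1L] / (1 + s + (1 - s) * M[-1L]))
  if (abs(H) < 1e-12) stop("degenerate life cycle: H vanishes", call. = FALSE)
  num <- (1 + s) * (sp * f + fp * (1 - s) * (1 + M)) * Bh * Psim
  den <- (1 + s + (1 - s) * M) * (1 - Cm * Bh)
  terms <- (num / den)[-1L]
  cast_real(sum(terms) / H)
}
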