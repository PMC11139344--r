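#' Lasting-commons model of environmentally mediated social evolution
#'
#' Specifies and analyses the evolution of a costly trait that produces a
#' lasting commons: an environmental state variable (a common good when
#' positive, a common bad when negative) that is produced locally at
#' rate `P(z)` per patch, moves between patches according to a movement
#' kernel, and decays at rate `epsilon` per generation. Individual payoff
#' is \eqn{\pi = \exp(B n^{\alpha_B} - C z_\bullet^{\alpha_C})}: the
#' local commons raises (or lowers) payoff while any trait expression is
#' individually costly. Fitness follows the survival-fecundity life cycle
#' of [fitness_sf()].
#'
#' The constructor validates the parameterisation and immediately
#' computes the quantities that characterise long-term evolution: the
#' expected genetic value `Omega` of a unit of commons produced in the
#' focal patch (its sign decides whether selection favours inter-temporal
#' helping, `Omega > 0`, or harming/posthumous spite, `Omega < 0`), the
#' convergence-stable singular trait value `z_star`, the commons
#' equilibrium `n_hat` at `z_star`, and the gradient slope at `z_star`.
#'
#' @param lattice a [patch_lattice()] (or integer dims vector).
#' @param N adults per patch.
#' @param m_kernel dispersal kernel of the evolving species (a
#'   `dispersal_kernel`, a probability field, or a config list).
#' @param d_kernel movement kernel of the commons (same forms).
#' @param B,alpha_B benefit coefficient (`B > 0`) and exponent
#'   (`alpha_B` a positive odd integer) of the local commons in payoff.
#' @param C,alpha_C cost coefficient (`C > 0`) and exponent (`alpha_C` a
#'   positive even integer, with `alpha_C > alpha_B`) of own trait
#'   expression in payoff.
#' @param epsilon commons decay rate per generation, in (0, 1\].
#' @param P0 slope of the linear production function `P(z) = P0 * z`
#'   (units of commons per unit trait per patch per generation). Supply
#'   `P_fun`/`P_prime` instead for a nonlinear production function with
#'   `P(0) = 0` and `P' > 0`.
#' @param P_fun,P_prime optional production function and its derivative.
#' @param lifecycle a [lifecycle()] object or preset name
#'   (`"wf_fecundity"`, default, or `"survival_effects"`).
#' @return an object of class `commons_model` with the parameterisation
#'   plus computed `omega`, `z_star`, `n_hat`, `gradient_slope` and
#'   `convergence_stable`.
#' @seealso [omega()], [singular_strategy()], [selection_gradient_commons()],
#'   [simulate.commons_model()]
#' @examples
#' lat <- patch_lattice(c(7, 7))
#' mod <- commons_model(
#'   lattice = lat, N = 20,
#'   m_kernel = truncated_binomial_kernel(lat, 0.3, 1.5),
#'   d_kernel = truncated_binomial_kernel(lat, 1.0, 5),
#'   B = 2, alpha_B = 1, C = 1, alpha_C = 4,
#'   epsilon = 0.5, P0 = 20
#' )
#' mod
#' @export
commons_model <- function(lattice, N, m_kernel, d_kernel,
                          B, alpha_B, C, alpha_C,
                          epsilon, P0 = NULL, P_fun = NULL, P_prime = NULL,
                          lifecycle = "wf_fecundity") {
  if (!is_lattice(lattice)) lattice <- patch_lattice(lattice)
  if (B <= 0 || C <= 0) stop("'B' and 'C' must be positive", call. = FALSE)
  if (alpha_B < 1 || alpha_B %% 2 != 1) {
    stop("'alpha_B' must be a positive odd integer", call. = FALSE)
  }
  if (alpha_C < 2 || alpha_C %% 2 != 0) {
    stop("'alpha_C' must be a positive even integer", call. = FALSE)
  }
  if (alpha_C <= alpha_B) {
    stop("costs must steepen faster than benefits: 'alpha_C' > 'alpha_B'",
         call. = FALSE)
  }
  if (epsilon <= 0 || epsilon > 1) stop("'epsilon' must lie in (0, 1]", call. = FALSE)
  linear_P <- is.null(P_fun)
  if (linear_P) {
    if (is.null(P0) || P0 <= 0) stop("'P0' must be positive", call. = FALSE)
    P_fun <- function(z) P0 * z
    P_prime <- function(z) rep(P0, length(z))
  } else {
    if (is.null(P_prime)) stop("supply 'P_prime' with 'P_fun'", call. = FALSE)
    if (abs(P_fun(0)) > 1e-12) stop("production must satisfy P(0) = 0", call. = FALSE)
  }
  m_kernel <- as_kernel(m_kernel, lattice)
  d_kernel <- as_kernel(d_kernel, lattice)
  lc <- as_lifecycle(lifecycle)

  p <- structure(
    list(lattice = lattice, N = N, m_kernel = m_kernel, d_kernel = d_kernel,
         B = B, alpha_B = alpha_B, C = C, alpha_C = alpha_C,
         epsilon = epsilon, P0 = if (linear_P) P0 else NA_real_,
         P_fun = P_fun, P_prime = P_prime, linear_P = linear_P,
         lifecycle = lc),
    class = "commons_model"
  )

  p$omega <- omega(p)
  p$z_star <- singular_strategy(p)
  p$n_hat <- env_equilibrium(p$z_star, p)
  cc <- convergence_check(p$z_star, p)
  p$convergence_stable <- cc$stable
  p$gradient_slope <- cc$slope
  p
}

#' @export
print.commons_model <- function(x, ...) {
  cat("Lasting-commons model under isolation by distance\n")
  cat(sprintf("  lattice %s, N = %d per patch (%d individuals)\n",
              paste(x$lattice$dims, collapse = " x "), x$N, x$N * x$lattice$D))
  cat(sprintf("  payoff: B = %g, alpha_B = %d, C = %g, alpha_C = %d\n",
              x$B, x$alpha_B, x$C, x$alpha_C))
  cat(sprintf("  commons: decay epsilon = %g, production slope P'(0) = %g\n",
              x$epsilon, x$P_prime(0)))
  cat(sprintf("  Omega  = %.6g  (%s favoured)\n", x$omega,
              if (x$omega > 0) "inter-temporal helping / altruism"
              else if (x$omega < 0) "inter-temporal harming / spite"
              else "neither"))
  cat(sprintf("  z*     = %.6g   n_hat(z*) = %.6g\n", x$z_star, x$n_hat))
  cat(sprintf("  convergence stable: %s (gradient slope %.3g)\n",
              x$convergence_stable, x$gradient_slope))
  invisible(x)
}

#' @export
summary.commons_model <- function(object, ...) {
  out <- list(
    omega = object$omega,
    omega_series = omega(object, method = "series"),
    z_star = object$z_star,
    n_hat = object$n_hat,
    gradient_slope = object$gradient_slope,
    convergence_stable = object$convergence_stable
  )
  class(out) <- "summary.commons_model"
  out
}

#' @export
print.summary.commons_model <- function(x, ...) {
  cat(sprintf("Omega (closed form) = %.8g\n", x$omega))
  cat(sprintf("Omega (series)      = %.8g\n", x$omega_series))
  cat(sprintf("z*                  = %.8g\n", x$z_star))
  cat(sprintf("n_hat(z*)           = %.8g\n", x$n_hat))
  cat(sprintf("gradient slope      = %.4g (%s)\n", x$gradient_slope,
              if (x$convergence_stable) "convergence stable" else "unstable"))
  invisible(x)
}

#' @export
coef.commons_model <- function(object, ...) {
  c(omega = object$omega, z_star = object$z_star, n_hat = object$n_hat)
}

#' Commons payoff function
#'
#' \eqn{\pi(z_\bullet, n) = \exp(B n^{\alpha_B} - C z_\bullet^{\alpha_C})}:
#' always positive, equal to 1 when trait and commons are both 0. Use
#' `log = TRUE` for the exponent itself when payoffs would overflow.
#'
#' @param z_self focal individual's trait value (vectorised).
#' @param n_local commons level in the focal patch.
#' @param p a `commons_model`.
#' @param log return the log payoff.
#' @return positive scalar payoff (or its log).
#' @export
payoff_commons <- function(z_self, n_local, p, log = FALSE) {
  lp <- p$B * n_local^p$alpha_B - p$C * z_self^p$alpha_C
  if (log) lp else exp(lp)
}

#' Commons equilibrium
#'
#' In a monomorphic population at trait `z` the commons converges in
#' every patch to \eqn{\hat n = P(z)/\epsilon} (production balancing
#' decay; movement redistributes nothing at a flat profile).
#'
#' @param z resident trait value.
#' @param p a `commons_model`.
#' @return scalar equilibrium commons level.
#' @export
env_equilibrium <- function(z, p) {
  p$P_fun(z) / p$epsilon
}

#' One-step commons map over the whole lattice
#'
#' Applies the environmental transition in every patch: each patch's
#' stock is decayed, augmented by local production from the patch-average
#' trait, then redistributed by the movement kernel.
#'
#' @param z_field numeric field of patch-average traits.
#' @param n_field numeric field of commons levels.
#' @param p a `commons_model`.
#' @return numeric field of next-generation commons levels.
#' @export
commons_map <- function(z_field, n_field, p) {
  u <- (1 - p$epsilon) * n_field + p$P_fun(z_field)
  group_convolve(u, p$d_kernel$field, p$lattice)
}

#' One-generation effect fields of the commons model
#'
#' Analytic building blocks of extended phenotypic effects:
#' \eqn{\psi_k = P'(z) d_k / N} (a focal trait change adds `P'(z)/N`
#' units of commons, placed by the movement kernel) and
#' \eqn{c_k = (1 - \epsilon) d_k} (surviving commons moves by the same
#' kernel).
#'
#' @param z resident trait value.
#' @param p a `commons_model`.
#' @return an [env_map_derivs()] object.
#' @export
commons_effect_fields <- function(z, p) {
  env_map_derivs(p$P_prime(z) * p$d_kernel$field / p$N,
                 (1 - p$epsilon) * p$d_kernel$field,
                 p$lattice)
}

#' Extended phenotypic effects of the commons model
#'
#' Closed form \eqn{e_{k,t} = (P'(z)/N) (1-\epsilon)^{t-1} q_{k,t}},
#' where \eqn{q_{k,t}} is the random walk of a non-decaying commons unit
#' under the movement kernel ([walk_distribution()]).
#'
#' @param z resident trait value.
#' @param p a `commons_model`.
#' @param t_max largest horizon.
#' @return an `extended_effects` object.
#' @export
commons_extended_effects <- function(z, p, t_max) {
  lat <- p$lattice
  Dh <- as.complex(p$d_kernel$spectrum)
  entries <- lapply(seq_len(t_max), function(t) {
    q <- inverse_transform(Dh^t, lat)
    p$P_prime(z) / p$N * (1 - p$epsilon)^(t - 1) * q
  })
  structure(list(lattice = lat, t_max = as.integer(t_max), entries = entries),
            class = "extended_effects")
}

#' Expected genetic value of a unit of commons
#'
#' `Omega` weighs every future unit of the commons produced in the focal
#' patch by the scaled relatedness of the individuals whose patch it
#' reaches: selection favours producing a common good (`z > 0`) when
#' `Omega > 0` and a common bad (`z < 0`) when `Omega < 0`. Four routes
#' are available and agree within numerical tolerance:
#' \describe{
#'   \item{`closed_form`}{`Omega = epsilon * K * N / P'(z)` with `K` from
#'     the resolvent form ([K_statistic()]); for the Wright-Fisher
#'     fecundity life cycle this equals the explicit resolvent sum
#'     \eqn{\Omega = \frac{\epsilon}{DN-1} \sum_{h \ne 0}
#'     \frac{D(-h) M(h)}{1 - (1-\epsilon) D(-h) M(h)}}.}
#'   \item{`series`}{the truncated double series
#'     \eqn{\sum_t \sum_k \epsilon (1-\epsilon)^{t-1} \kappa_{k,t} q_{k,t}}.}
#'   \item{`covariance_wf`}{Wright-Fisher fecundity only:
#'     \eqn{\frac{\epsilon D^2}{DN-1} \sum_t (1-\epsilon)^{t-1}
#'     \mathrm{cov}(p_t, q_t)}, the covariance between the gene and
#'     commons random walks.}
#'   \item{`weak_dispersal`}{the small-`m`, small-`d` limit
#'     \eqn{\Omega \approx \frac{D-1}{DN-1} \cdot
#'     \frac{\epsilon - m - d}{\epsilon}}, positive for sufficiently
#'     weak dispersal and movement.}
#' }
#'
#' @param p a `commons_model`.
#' @param method one of `"closed_form"`, `"series"`, `"covariance_wf"`,
#'   `"weak_dispersal"`.
#' @param tol relative truncation tolerance for the series routes.
#' @return scalar `Omega`.
#' @export
omega <- function(p, method = c("closed_form", "series", "covariance_wf",
                                "weak_dispersal"), tol = 1e-12) {
  method <- match.arg(method)
  stopifnot(inherits(p, "commons_model"))
  lat <- p$lattice
  check_mixing(p$m_kernel)
  Pp <- p$P_prime(0)
  switch(method,
    closed_form = {
      Psi <- as.complex(Pp * p$d_kernel$spectrum / p$N)
      Ch <- as.complex((1 - p$epsilon) * p$d_kernel$spectrum)
      K <- K_statistic(p$m_kernel, Psi, Ch, p$N, p$lifecycle)
      p$epsilon * K * p$N / Pp
    },
    series = {
      q_spec <- as.complex(p$d_kernel$spectrum)
      total <- 0
      t <- 0L
      repeat {
        t <- t + 1L
        q_t <- inverse_transform(q_spec^t, lat)
        kap <- kappa_general(p$m_kernel, p$N, p$lifecycle, t)
        term <- p$epsilon * (1 - p$epsilon)^(t - 1) * sum(kap * q_t)
        total <- total + term
        # geometric tail bound driven by the decay factor: the remaining
        # terms sum to at most (1 - eps)^t * max|kappa| in absolute value
        bound <- (1 - p$epsilon)^t * max(abs(kap))
        if (bound <= tol * max(abs(total), 1e-300) || t >= 1e5) break
      }
      total
    },
    covariance_wf = {
      lcwf <- p$lifecycle
      if (!(lcwf$s == 0 && lcwf$s_prime == 0 && lcwf$f_prime > 0)) {
        stop("the covariance route requires the Wright-Fisher fecundity life cycle",
             call. = FALSE)
      }
      m_spec <- as.complex(p$m_kernel$spectrum)
      q_spec <- as.complex(p$d_kernel$spectrum)
      total <- 0
      t <- 0L
      repeat {
        t <- t + 1L
        p_t <- inverse_transform(m_spec^t, lat)
        q_t <- inverse_transform(q_spec^t, lat)
        covpq <- mean(p_t * q_t) - mean(p_t) * mean(q_t)
        term <- (1 - p$epsilon)^(t - 1) * covpq
        total <- total + term
        bound <- (1 - p$epsilon)^t / p$epsilon * max(abs(covpq), 1 / lat$D^2)
        if (bound <= tol * max(abs(total), 1e-300) || t >= 1e5) break
      }
      p$epsilon * lat$D^2 / (lat$D * p$N - 1) * total
    },
    weak_dispersal = {
      m <- 1 - p$m_kernel$field[1L]
      d <- 1 - p$d_kernel$field[1L]
      (lat$D - 1) / (lat$D * p$N - 1) * (p$epsilon - m - d) / p$epsilon
    }
  )
}

# explicit Wright-Fisher resolvent sum; used as an independent check of
# the closed_form route
omega_resolvent_wf <- function(p) {
  lat <- p$lattice
  M <- p$m_kernel$spectrum
  Dm <- p$d_kernel$spectrum[lat$neg]   # D(-h)
  terms <- (Dm * M / (1 - (1 - p$epsilon) * Dm * M))[-1L]
  p$epsilon / (lat$D * p$N - 1) * sum(terms)
}

#' Selection gradient of the commons model
#'
#' \eqn{s(z) \propto -C \alpha_C z^{\alpha_C - 1} +
#' \Omega B \alpha_B (P'(z)/\epsilon)(P(z)/\epsilon)^{\alpha_B - 1}}:
#' the marginal cost of trait expression against the commons-mediated
#' return, weighted by the genetic value `Omega` of the commons. At
#' `z = 0` the gradient is proportional to `Omega`.
#'
#' @param z trait value (vectorised).
#' @param p a `commons_model`.
#' @return scalar gradient value(s), up to a positive constant.
#' @export
selection_gradient_commons <- function(z, p) {
  -p$C * p$alpha_C * z^(p$alpha_C - 1) +
    p$omega * p$B * p$alpha_B * (p$P_prime(z) / p$epsilon) *
      (p$P_fun(z) / p$epsilon)^(p$alpha_B - 1)
}

#' Singular trait value
#'
#' For linear production `P(z) = P0 z` the root of the selection
#' gradient is
#' \eqn{z^* = [\,(B/C)(\alpha_B/\alpha_C)(P_0/\epsilon)^{\alpha_B}\,
#' \Omega\,]^{1/(\alpha_C - \alpha_B)}}, taken as the real odd root with
#' `sign(z*) = sign(Omega)` (the exponent denominator is odd whenever
#' `alpha_C` is even and `alpha_B` odd). For nonlinear production the
#' root is located numerically.
#'
#' @param p a `commons_model`.
#' @return scalar singular trait value.
#' @export
singular_strategy <- function(p) {
  om <- if (is.null(p$omega)) omega(p) else p$omega
  if (om == 0) return(0)
  expo <- p$alpha_C - p$alpha_B
  if (p$linear_P) {
    arg <- (p$B / p$C) * (p$alpha_B / p$alpha_C) *
      (p$P0 / p$epsilon)^p$alpha_B * om
    if (expo %% 2 == 0 && arg < 0) {
      stop("no real singular value: even root of a negative argument",
           call. = FALSE)
    }
    return(sign(arg) * abs(arg)^(1 / expo))
  }
  # nonlinear production: bracket and solve s(z) = 0 away from 0
  f <- function(z) selection_gradient_commons(z, p)
  dir <- sign(om)
  lo <- dir * 1e-8; hi <- dir
  while (f(lo) * f(hi) > 0 && abs(hi) < 1e6) hi <- hi * 2
  stats::uniroot(f, sort(c(lo, hi)), tol = 1e-12)$root
}

#' Convergence stability check
#'
#' Verifies that `z_star` is a root of the selection gradient and
#' reports the numerical gradient slope there (central differences);
#' the singular value is convergence stable iff the slope is negative.
#'
#' @param z_star candidate singular trait value.
#' @param p a `commons_model`.
#' @param root_tol tolerance for accepting `z_star` as a root.
#' @return list with elements `stable` (logical) and `slope`.
#' @export
convergence_check <- function(z_star, p, root_tol = 1e-6) {
  g0 <- selection_gradient_commons(z_star, p)
  scale <- abs(p$omega) + abs(p$C * p$alpha_C * z_star^(p$alpha_C - 1)) + 1e-12
  if (abs(g0) > root_tol * scale) {
    stop(sprintf("z_star is not a root of the gradient (s(z*) = %.3g)", g0),
         call. = FALSE)
  }
  h <- 1e-5 * (1 + abs(z_star))
  slope <- (selection_gradient_commons(z_star + h, p) -
            selection_gradient_commons(z_star - h, p)) / (2 * h)
  list(stable = slope < 0, slope = slope)
}
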