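#' Payoff derivatives at the resident point
#'
#' Container for the marginal effects of traits and environment on the
#' focal individual's payoff, all evaluated in the monomorphic resident
#' population at environmental equilibrium: `d_self` is
#' \eqn{\partial\pi/\partial z_\bullet}, `d_z` the field of
#' \eqn{\partial\pi/\partial z_{k,0}} and `d_n` the field of
#' \eqn{\partial\pi/\partial n_{j,0}}. For local payoff models the two
#' fields are supported at displacement 0 only.
#'
#' @param d_self scalar effect of the focal's own trait on its payoff.
#' @param d_z numeric field of trait effects per displacement.
#' @param d_n numeric field of environmental effects per displacement.
#' @param lattice a [patch_lattice()].
#' @return an object of class `payoff_derivs`.
#' @export
payoff_derivs <- function(d_self, d_z, d_n, lattice) {
  check_field(d_z, lattice, "d_z")
  check_field(d_n, lattice, "d_n")
  structure(list(d_self = d_self, d_z = d_z, d_n = d_n, lattice = lattice),
            class = "payoff_derivs")
}

is_local <- function(pd) {
  all(pd$d_z[-1L] == 0) && all(pd$d_n[-1L] == 0)
}

# sum_t sum_k sum_j field1[j - k] * field2[j] * weight[k] as two matrix ops
cross_sum <- function(e_field, w_field, weight_field, lattice, flip = FALSE) {
  # inner[k] = sum_j e[j - k] w[j]   (flip: e[k - j])
  Em <- matrix(e_field[lattice$sub], lattice$D, lattice$D)  # [a, b] = e[a - b]
  inner <- if (flip) as.vector(Em %*% w_field) else as.vector(crossprod(Em, w_field))
  sum(inner * weight_field)
}

#' Selection through the environment, fitness form
#'
#' Assembles the inter-temporal component of the selection gradient in
#' its fitness form: the focal individual's extended phenotypic effects
#' on every patch's environment, times the marginal effect of that
#' environment on the fitness of individuals in each patch, weighted by
#' `N` times their relatedness to the focal, summed over horizons
#' `1..t_max`.
#'
#' @param effects an [extended_effects()] table covering `1..t_max`.
#' @param dw_dn numeric field: marginal effect of the environmental
#'   variable at each displacement on focal fitness.
#' @param relatedness a [relatedness_table()] covering `1..t_max`.
#' @param N adults per patch.
#' @param t_max truncation horizon.
#' @return scalar, with the estimated truncation tail in attribute
#'   `"tail"`.
#' @export
se_fitness_form <- function(effects, dw_dn, relatedness, N, t_max) {
  lat <- effects$lattice
  check_field(dw_dn, lat, "dw_dn")
  if (effects$t_max < t_max || relatedness$t_max < t_max) {
    stop("'effects' and 'relatedness' must cover t = 1..t_max", call. = FALSE)
  }
  terms <- vapply(seq_len(t_max), function(t) {
    cross_sum(eff_at(effects, t), dw_dn, N * rel_at(relatedness, t), lat)
  }, numeric(1L))
  out <- sum(terms)
  attr(out, "tail") <- if (t_max > 1) abs(terms[t_max]) else NA_real_
  out
}

#' Selection gradient, payoff form with non-local interactions
#'
#' The full payoff-form gradient (up to a positive proportionality
#' constant): the focal's effect on its own payoff, plus its effects on
#' the payoffs of contemporaries weighted by same-generation scaled
#' relatedness, plus its environmentally mediated effects on the payoffs
#' of future individuals weighted by `N` times scaled relatedness.
#'
#' @param pd a [payoff_derivs()] object.
#' @param effects an [extended_effects()] table covering `1..t_max`.
#' @param kappa list of scaled-relatedness fields for `t = 0..t_max`
#'   (e.g. from [kappa_general()]).
#' @param N adults per patch.
#' @param t_max truncation horizon.
#' @return scalar gradient (sign and zeros are meaningful; the scale is
#'   only defined up to a positive constant).
#' @export
gradient_payoff_nonlocal <- function(pd, effects, kappa, N, t_max) {
  lat <- pd$lattice
  if (length(kappa) < t_max + 1L) {
    stop("'kappa' must supply fields for t = 0..t_max", call. = FALSE)
  }
  intra <- pd$d_self + sum(kappa[[1L]] * pd$d_z)
  inter <- sum(vapply(seq_len(t_max), function(t) {
    cross_sum(eff_at(effects, t), pd$d_n, N * kappa[[t + 1L]], lat, flip = TRUE)
  }, numeric(1L)))
  intra + inter
}

#' Selection gradient, payoff form with local interactions
#'
#' When payoffs depend only on the focal patch's traits and environment,
#' the gradient collapses to
#' \eqn{\partial\pi/\partial z_\bullet +
#' (\partial\pi/\partial z_{0,0})\,\kappa_{0,0} +
#' (\partial\pi/\partial n_{0,0})\, N K}.
#'
#' @param pd a [payoff_derivs()] object with `d_z`, `d_n` supported at
#'   displacement 0 only.
#' @param K the environmental summary statistic ([K_statistic()]).
#' @param N adults per patch.
#' @param kappa_00 same-generation, same-patch scaled relatedness.
#' @return scalar gradient (up to a positive constant).
#' @export
gradient_payoff_local <- function(pd, K, N, kappa_00) {
  if (!is_local(pd)) {
    stop("payoff derivatives are not local: use gradient_payoff_nonlocal()",
         call. = FALSE)
  }
  pd$d_self + pd$d_z[1L] * kappa_00 + pd$d_n[1L] * N * K
}
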