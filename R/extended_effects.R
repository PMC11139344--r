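#' One-generation environmental effect fields from an environmental map
#'
#' Differentiates a focal-patch environmental transition map numerically
#' (central differences) at a monomorphic resident equilibrium to obtain
#' the two building blocks of extended phenotypic effects:
#' \eqn{\psi_k}, the focal individual's one-generation effect on the
#' environmental variable of the patch at displacement `k` (the map's
#' derivative with respect to the average trait of patch `k`, divided by
#' `N`), and \eqn{c_k}, the one-generation effect of patch `k`'s
#' environmental variable on the focal patch's.
#'
#' @param env_map function `(z_field, n_field) -> scalar` returning the
#'   next value of the focal patch's environmental variable given the
#'   displacement-indexed fields of patch-average traits and current
#'   environmental values; it must be evaluable at slightly perturbed
#'   arguments.
#' @param z resident trait value.
#' @param n_hat equilibrium environmental value: `env_map` applied to
#'   constant fields at `(z, n_hat)` must return `n_hat` (checked).
#' @param N adults per patch.
#' @param lattice a [patch_lattice()].
#' @param step base finite-difference step (scaled by `1 + |z|` or
#'   `1 + |n_hat|`).
#' @param tol tolerance for the fixed-point check.
#' @return an object of class `env_map_derivs`: list with numeric fields
#'   `psi` and `c`.
#' @export
differentiate_env_map <- function(env_map, z, n_hat, N, lattice,
                                  step = 1e-6, tol = 1e-8) {
  zf <- rep(z, lattice$D)
  nf <- rep(n_hat, lattice$D)
  resid <- abs(env_map(zf, nf) - n_hat)
  if (resid > tol * (1 + abs(n_hat))) {
    stop(sprintf("(z, n_hat) is not a fixed point of the map (residual %.3g)",
                 resid), call. = FALSE)
  }
  hz <- step * (1 + abs(z))
  hn <- step * (1 + abs(n_hat))
  psi <- vapply(seq_len(lattice$D), function(k) {
    up <- zf; up[k] <- z + hz
    dn <- zf; dn[k] <- z - hz
    (env_map(up, nf) - env_map(dn, nf)) / (2 * hz) / N
  }, numeric(1L))
  cc <- vapply(seq_len(lattice$D), function(k) {
    up <- nf; up[k] <- n_hat + hn
    dn <- nf; dn[k] <- n_hat - hn
    (env_map(zf, up) - env_map(zf, dn)) / (2 * hn)
  }, numeric(1L))
  env_map_derivs(psi, cc, lattice)
}

#' @rdname differentiate_env_map
#' @param psi,c_field numeric effect fields (both symmetric under
#'   `k -> -k`).
#' @export
env_map_derivs <- function(psi, c_field, lattice) {
  check_field(psi, lattice, "psi")
  check_field(c_field, lattice, "c")
  sym_tol <- 1e-8 * (1 + max(abs(psi), abs(c_field)))
  if (max(abs(psi - psi[lattice$neg])) > sym_tol ||
      max(abs(c_field - c_field[lattice$neg])) > sym_tol) {
    stop("effect fields must be symmetric under k -> -k (spatial homogeneity)",
         call. = FALSE)
  }
  structure(list(psi = psi, c = c_field, lattice = lattice),
            class = "env_map_derivs")
}

#' Extended phenotypic effects
#'
#' The marginal effect \eqn{e_{k,t}} of the focal individual's trait on
#' the environmental state variable of the patch at displacement `k`,
#' `t` generations in the future, computed spectrally as the inverse
#' transform of \eqn{E_t(h) = \Psi(h) C(h)^{t-1}}: the focal's
#' one-generation environmental perturbation (\eqn{\Psi}) propagated for
#' `t - 1` generations by the environment-to-environment dynamics
#' (\eqn{C}). At `t = 1` the effect equals \eqn{\psi_k} itself.
#'
#' @param derivs an [env_map_derivs()] object.
#' @param t_max largest horizon (at least 1).
#' @return an object of class `extended_effects`: list of one numeric
#'   field per `t = 1, ..., t_max`.
#' @export
extended_effects <- function(derivs, t_max) {
  stopifnot(inherits(derivs, "env_map_derivs"))
  if (t_max < 1) stop("'t_max' must be at least 1", call. = FALSE)
  lat <- derivs$lattice
  Psi <- fourier_transform(derivs$psi, lat)
  Ch <- fourier_transform(derivs$c, lat)
  spec <- Psi
  entries <- vector("list", t_max)
  entries[[1L]] <- inverse_transform(spec, lat)
  t <- 1L
  while (t < t_max) {
    spec <- spec * Ch
    t <- t + 1L
    entries[[t]] <- inverse_transform(spec, lat)
  }
  structure(list(lattice = lat, t_max = as.integer(t_max), entries = entries),
            class = "extended_effects")
}

eff_at <- function(effects, t) {
  stopifnot(inherits(effects, "extended_effects"))
  if (t < 1 || t > effects$t_max) {
    stop(sprintf("extended effects cover t = 1..%d, requested t = %d",
                 effects$t_max, t), call. = FALSE)
  }
  effects$entries[[t]]
}

#' @export
print.extended_effects <- function(x, ...) {
  cat(sprintf("extended phenotypic effects on a %s lattice, t = 1..%d\n",
              paste(x$lattice$dims, collapse = " x "), x$t_max))
  invisible(x)
}

#' Extended phenotypic effects with several environmental variables
#'
#' Generalisation to `n_e` coupled environmental state variables: per
#' frequency, the vector of one-generation trait effects is propagated
#' by powers of the coupling matrix \eqn{C(h)} (entry `(i, j)` the
#' transform of the effect of variable `j` on variable `i`), and each
#' component is inverse-transformed. Matrix powers are accumulated by
#' repeated multiplication.
#'
#' @param psi_list list of `n_e` numeric fields: the one-generation
#'   effect of the focal trait on each environmental variable.
#' @param c_matrix `n_e x n_e` list-matrix (or list of rows) of numeric
#'   fields: entry `[i, j]` the one-generation effect of variable `j`
#'   on variable `i` at each displacement.
#' @param t_max largest horizon.
#' @param lattice a [patch_lattice()].
#' @return list of `n_e` `extended_effects` objects, one per variable.
#' @export
extended_effects_multi <- function(psi_list, c_matrix, t_max, lattice) {
  ne <- length(psi_list)
  if (is.list(c_matrix) && !is.matrix(c_matrix)) {
    c_matrix <- matrix(unlist(c_matrix, recursive = FALSE), ne, ne, byrow = TRUE)
  }
  if (!is.matrix(c_matrix) || nrow(c_matrix) != ne || ncol(c_matrix) != ne) {
    stop("'c_matrix' must be an n_e x n_e arrangement of spatial fields",
         call. = FALSE)
  }
  D <- lattice$D
  Psih <- vapply(psi_list, fourier_transform, complex(D), lattice = lattice)
  if (ne == 1L) dim(Psih) <- c(D, 1L)
  Ch <- array(0i, dim = c(ne, ne, D))
  for (i in seq_len(ne)) for (j in seq_len(ne)) {
    Ch[i, j, ] <- fourier_transform(c_matrix[[i, j]], lattice)
  }
  entries <- replicate(ne, vector("list", t_max), simplify = FALSE)
  spec <- t(Psih)                       # ne x D, E_1(h) = Psi(h)
  for (t in seq_len(t_max)) {
    if (t > 1L) {
      for (h in seq_len(D)) spec[, h] <- Ch[, , h] %*% spec[, h]
    }
    for (i in seq_len(ne)) {
      entries[[i]][[t]] <- inverse_transform(spec[i, ], lattice)
    }
  }
  lapply(entries, function(e) {
    structure(list(lattice = lattice, t_max = as.integer(t_max), entries = e),
              class = "extended_effects")
  })
}
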