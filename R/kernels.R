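#' Movement kernels on the patch lattice
#'
#' A kernel is a probability distribution over patch displacements: either
#' the dispersal distribution \eqn{m_k} of offspring of the evolving
#' species, or the movement distribution \eqn{d_k} of a unit of the
#' environmental commons. Kernels are non-negative, sum to one, and are
#' spatially symmetric (\eqn{m_k = m_{-k}}).
#'
#' @name kernels
NULL

new_kernel <- function(field, lattice) {
  spec <- fourier_transform(field, lattice)
  structure(
    list(field = field, lattice = lattice, spectrum = cast_real(spec)),
    class = "dispersal_kernel"
  )
}

#' @export
print.dispersal_kernel <- function(x, ...) {
  cat(sprintf("movement kernel on a %s lattice\n",
              paste(x$lattice$dims, collapse = " x ")))
  cat(sprintf("  stay probability: %.4f   max |spectrum| off origin: %.4f\n",
              x$field[1L], if (x$lattice$D > 1L) max(abs(x$spectrum[-1L])) else NA_real_))
  invisible(x)
}

#' Validate a probability field as a movement kernel
#'
#' Checks the simplex and symmetry invariants: all entries non-negative
#' (violations below `-1e-12` are errors, smaller round-off is clipped to
#' zero and the field renormalised), total mass within `1e-10` of one,
#' and `|m_k - m_{-k}| <= 1e-12` for all displacements.
#'
#' @param field numeric vector of one probability per patch displacement.
#' @param lattice a [patch_lattice()].
#' @return an object of class `dispersal_kernel`.
#' @export
validate_kernel <- function(field, lattice) {
  check_field(field, lattice)
  if (any(field < -1e-12)) {
    stop("kernel invariant violated: negative probability mass", call. = FALSE)
  }
  field[field < 0] <- 0
  s <- sum(field)
  if (abs(s - 1) > 1e-10) {
    stop(sprintf("kernel invariant violated: probabilities sum to %.12f, not 1", s),
         call. = FALSE)
  }
  field <- field / s
  if (max(abs(field - field[lattice$neg])) > 1e-12) {
    stop("kernel invariant violated: field is not symmetric under k -> -k",
         call. = FALSE)
  }
  new_kernel(field, lattice)
}

#' Uniform (panmictic) kernel
#'
#' Every displacement receives probability `1/D`: the randomly mixing
#' population. Its characteristic function is the indicator at `h = 0`,
#' so relatedness between any two individuals is zero under this kernel.
#'
#' @param lattice a [patch_lattice()].
#' @return a `dispersal_kernel`.
#' @export
uniform_kernel <- function(lattice) {
  validate_kernel(rep(1 / lattice$D, lattice$D), lattice)
}

#' Island-model kernel
#'
#' Stay with probability `1 - m`; otherwise move to one of the `D - 1`
#' other patches uniformly at random, irrespective of distance.
#'
#' @param lattice a [patch_lattice()].
#' @param m probability of leaving the natal patch, in (0, 1).
#' @return a `dispersal_kernel`.
#' @export
island_kernel <- function(lattice, m) {
  if (lattice$D < 2L) stop("island kernel needs at least two patches", call. = FALSE)
  if (!is.numeric(m) || length(m) != 1L || m <= 0 || m >= 1) {
    stop("'m' must be a probability strictly between 0 and 1", call. = FALSE)
  }
  field <- rep(m / (lattice$D - 1L), lattice$D)
  field[1L] <- 1 - m
  validate_kernel(field, lattice)
}

#' Minimal-image Manhattan distance of every displacement
#'
#' Distance on the torus uses the shorter wrap-around direction in each
#' dimension, summed over dimensions.
#'
#' @param lattice a [patch_lattice()].
#' @return integer vector of one distance per patch displacement.
#' @export
torus_manhattan <- function(lattice) {
  dm <- sweep(lattice$coords, 2L, lattice$dims, function(k, D) pmin(k, D - k))
  as.integer(rowSums(dm))
}

#' Truncated-binomial distance kernel
#'
#' The kernel used for both species dispersal and commons movement in the
#' worked examples: an individual (or commons unit) stays put with
#' probability `1 - move_prob`; conditional on moving, its minimal-image
#' Manhattan distance r follows a binomial distribution with index
#' `r_max` (the largest distance realisable on the torus) truncated to
#' `1 <= r <= r_max`, with the success probability solved numerically so
#' that the conditional mean distance equals `mean_distance`. The mass at
#' each distance r is spread uniformly over all displacement vectors of
#' minimal-image Manhattan norm r, which makes the kernel exactly
#' symmetric.
#'
#' @param lattice a [patch_lattice()].
#' @param move_prob probability of leaving the natal patch, in \[0, 1\].
#' @param mean_distance desired conditional mean Manhattan distance,
#'   strictly between 1 and the maximum distance on the lattice.
#' @return a `dispersal_kernel`.
#' @export
truncated_binomial_kernel <- function(lattice, move_prob, mean_distance) {
  if (!is.numeric(move_prob) || length(move_prob) != 1L ||
      move_prob < 0 || move_prob > 1) {
    stop("'move_prob' must be a probability in [0, 1]", call. = FALSE)
  }
  dist <- torus_manhattan(lattice)
  r_max <- max(dist)
  if (move_prob == 0) {
    field <- numeric(lattice$D)
    field[1L] <- 1
    return(validate_kernel(field, lattice))
  }
  if (r_max < 1L) stop("lattice has no displacement to move to", call. = FALSE)
  if (!is.numeric(mean_distance) || length(mean_distance) != 1L ||
      mean_distance <= 1 || mean_distance >= r_max) {
    stop(sprintf(paste0("'mean_distance' must lie strictly between 1 and the ",
                        "maximum torus Manhattan distance %d"), r_max),
         call. = FALSE)
  }

  cond_mean <- function(p) {
    pr <- stats::dbinom(seq_len(r_max), r_max, p)
    sum(seq_len(r_max) * pr) / sum(pr)
  }
  p <- stats::uniroot(function(p) cond_mean(p) - mean_distance,
                      interval = c(1e-12, 1 - 1e-12), tol = 1e-14)$root

  pr <- stats::dbinom(seq_len(r_max), r_max, p)
  pr <- pr / sum(pr)                      # truncate away r = 0
  n_r <- tabulate(dist, nbins = r_max)    # vectors at each distance >= 1
  field <- numeric(lattice$D)
  field[1L] <- 1 - move_prob
  field[dist >= 1L] <- move_prob * pr[dist[dist >= 1L]] / n_r[dist[dist >= 1L]]
  validate_kernel(field, lattice)
}

#' Characteristic function of a kernel
#'
#' The Fourier transform of the movement probabilities. For a symmetric
#' kernel the spectrum is real, equals 1 at `h = 0`, and lies in
#' \[-1, 1\] everywhere.
#'
#' @param kernel a `dispersal_kernel`.
#' @return numeric vector of length `D`.
#' @export
kernel_spectrum <- function(kernel) {
  stopifnot(inherits(kernel, "dispersal_kernel"))
  kernel$spectrum
}

# resolve a kernel description (list or kernel) against a lattice
as_kernel <- function(x, lattice) {
  if (inherits(x, "dispersal_kernel")) {
    if (!identical(x$lattice$dims, lattice$dims)) {
      stop("kernel was built on a different lattice", call. = FALSE)
    }
    return(x)
  }
  if (is.numeric(x)) return(validate_kernel(x, lattice))
  if (is.list(x) && !is.null(x$type)) {
    return(switch(
      x$type,
      uniform = uniform_kernel(lattice),
      island = island_kernel(lattice, x$move_prob),
      truncated_binomial = truncated_binomial_kernel(lattice, x$move_prob,
                                                     x$mean_distance),
      custom = validate_kernel(as.numeric(x$values), lattice),
      stop(sprintf("unknown kernel type '%s'", x$type), call. = FALSE)
    ))
  }
  stop("cannot interpret 'x' as a movement kernel", call. = FALSE)
}
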