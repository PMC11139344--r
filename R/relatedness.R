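#' Neutral gene random walk
#'
#' Distribution of the patch occupied by a gene lineage descending from a
#' focal individual `t` generations in the future, under neutrality:
#' \eqn{p_{k,t} = L_k(M^t)}, the inverse transform of the t-th power of
#' the dispersal characteristic function. Equals the t-fold convolution
#' of the dispersal kernel with itself.
#'
#' @param kernel a `dispersal_kernel` (the dispersal distribution
#'   \eqn{m_k}).
#' @param t positive integer number of generations.
#' @return numeric probability field over patch displacements.
#' @export
walk_distribution <- function(kernel, t) {
  stopifnot(inherits(kernel, "dispersal_kernel"))
  if (!is.numeric(t) || length(t) != 1L || t < 1 || t != floor(t)) {
    stop("'t' must be a positive integer", call. = FALSE)
  }
  inverse_transform(as.complex(kernel$spectrum)^t, kernel$lattice)
}

# spectral mixing check shared by the relatedness machinery
check_mixing <- function(kernel) {
  M <- kernel$spectrum
  if (kernel$lattice$D > 1L && max(abs(M[-1L])) >= 1 - 1e-12) {
    stop("kernel is not mixing: |M(h)| = 1 at some nonzero frequency ",
         "(some patches are never reachable); dispersal must connect the lattice",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Wright-Fisher relatedness coefficients
#'
#' Relatedness \eqn{R_{k,t}} between a focal individual and a random
#' individual living in the patch at displacement `k`, `t` generations
#' apart, under a Wright-Fisher life cycle (no adult survival). Computed
#' from the closed form
#' \deqn{R_{k,t} = \frac{1}{DN + M} \sum_{h \ne 0}
#'   \frac{M(h)^t}{1 - M(h)^2} \bar\chi_k(h),}
#' where \eqn{M = \sum_{h \ne 0} M(h)^2 / (1 - M(h)^2)}. The
#' same-generation coefficients are obtained by the identity
#' \eqn{R_{k,0} = R_{k,2}}. Relatedness averages to zero over patches;
#' under limited dispersal it is positive near the focal patch and
#' negative somewhere else.
#'
#' @param kernel a `dispersal_kernel` (must be mixing: \eqn{|M(h)| < 1}
#'   for all \eqn{h \ne 0}).
#' @param N adults per patch.
#' @param t non-negative integer temporal distance.
#' @return numeric field of relatedness coefficients over displacements.
#' @export
relatedness_wf <- function(kernel, N, t) {
  stopifnot(inherits(kernel, "dispersal_kernel"))
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != floor(N)) {
    stop("'N' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t != floor(t)) {
    stop("'t' must be a non-negative integer", call. = FALSE)
  }
  check_mixing(kernel)
  if (t == 0) t <- 2           # same-generation coefficients
  lat <- kernel$lattice
  M <- kernel$spectrum
  if (lat$D == 1L) return(0)
  g <- as.complex(M)^t / (1 - M^2)
  g[1L] <- 0i
  Mconst <- sum(M[-1L]^2 / (1 - M[-1L]^2))
  raw <- as.vector(Conj(lat$chi) %*% g)
  cast_real(raw) / (lat$D * N + Mconst)
}

#' Table of relatedness coefficients over time
#'
#' @param kernel a `dispersal_kernel`.
#' @param N adults per patch.
#' @param t_max largest temporal distance.
#' @return an object of class `relatedness_table`: a list with the
#'   lattice and one relatedness field per `t = 0, ..., t_max`.
#' @export
relatedness_table <- function(kernel, N, t_max) {
  entries <- lapply(0:t_max, function(t) relatedness_wf(kernel, N, t))
  structure(list(lattice = kernel$lattice, N = N, t_max = t_max,
                 entries = entries),
            class = "relatedness_table")
}

# field for temporal distance t (t = 0 is entries[[1]])
rel_at <- function(table, t) {
  stopifnot(inherits(table, "relatedness_table"))
  if (t < 0 || t > table$t_max) {
    stop(sprintf("relatedness table covers t = 0..%d, requested t = %d",
                 table$t_max, t), call. = FALSE)
  }
  table$entries[[t + 1L]]
}

#' @export
print.relatedness_table <- function(x, ...) {
  cat(sprintf("relatedness table on a %s lattice, N = %d, t = 0..%d\n",
              paste(x$lattice$dims, collapse = " x "), x$N, x$t_max))
  cat(sprintf("  R[0,0] = %.6g\n", x$entries[[1L]][1L]))
  invisible(x)
}
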