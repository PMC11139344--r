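#' Finite abelian group of patches
#'
#' Constructs the group \eqn{G = Z_{D_1} \times \dots \times Z_{D_d}} of
#' patch positions on a circular (1D) or toroidal (2D and higher) habitat.
#' Patches are enumerated in lexicographic order of their coordinate
#' vectors, starting at the origin \eqn{(0, \dots, 0)} and finishing at
#' \eqn{(D_1 - 1, \dots, D_d - 1)}. All spatial fields handled by the
#' package are numeric vectors of length `D = prod(dims)` in this order.
#'
#' The constructor precomputes the character table
#' \eqn{\chi_k(h) = \exp(2\pi i \sum_j k_j h_j / D_j)} and the group
#' subtraction table, which makes transforms and convolutions single
#' matrix products. Memory grows as \eqn{D^2}; the intended problem sizes
#' are lattices of at most a few hundred patches.
#'
#' @param dims integer vector of patches per habitat dimension
#'   (\eqn{D_1, \dots, D_d}), each at least 1.
#' @return an object of class `patch_lattice` with elements `dims`, `d`
#'   (number of dimensions), `D` (number of patches), `coords`
#'   (`D x d` integer matrix of patch coordinates), `chi` (the `D x D`
#'   complex character table), `sub` (`D x D` integer table with entry
#'   `[k, j]` the flat index of `k - j`), and `neg` (index permutation
#'   sending each element to its inverse).
#' @examples
#' lat <- patch_lattice(c(3, 3))
#' lat$D
#' @export
patch_lattice <- function(dims) {
  dims <- as.integer(dims)
  if (length(dims) < 1L || any(is.na(dims)) || any(dims < 1L)) {
    stop("'dims' must be a vector of positive integers", call. = FALSE)
  }
  d <- length(dims)
  D <- prod(dims)

  # lexicographic enumeration: the last coordinate varies fastest
  grid <- do.call(expand.grid, rev(lapply(dims, function(n) seq.int(0L, n - 1L))))
  coords <- as.matrix(grid[, rev(seq_len(d)), drop = FALSE])
  dimnames(coords) <- NULL
  storage.mode(coords) <- "integer"

  phase <- coords %*% t(sweep(coords, 2L, dims, "/"))
  chi <- exp(2i * pi * phase)

  # flat-index weights for lexicographic rank
  w <- rev(cumprod(rev(c(dims[-1L], 1L))))

  sub <- matrix(1L, D, D)
  if (D > 1L) {
    idx <- matrix(0L, D, D)
    for (j in seq_len(d)) {
      dj <- outer(coords[, j], coords[, j], "-") %% dims[j]
      idx <- idx + dj * w[j]
    }
    sub <- idx + 1L
  }

  structure(
    list(dims = dims, d = d, D = D, coords = coords, chi = chi,
         sub = sub, neg = sub[1L, ], weights = w),
    class = "patch_lattice"
  )
}

#' @export
print.patch_lattice <- function(x, ...) {
  cat("patch lattice:", paste(x$dims, collapse = " x "),
      sprintf("(%d patches, %dD habitat)\n", x$D, x$d))
  invisible(x)
}

is_lattice <- function(x) inherits(x, "patch_lattice")

check_field <- function(field, lattice, what = "field") {
  if (!is_lattice(lattice)) stop("'lattice' must be a patch_lattice", call. = FALSE)
  if (length(field) != lattice$D) {
    stop(sprintf("%s has length %d but the lattice holds %d patches",
                 what, length(field), lattice$D), call. = FALSE)
  }
  invisible(TRUE)
}

#' Flat index of a patch coordinate vector
#'
#' @param lattice a [patch_lattice()].
#' @param k integer vector of length `d` (or a matrix with `d` columns),
#'   each component `j` in `[0, D_j)`.
#' @return integer index (or vector of indices) into spatial fields.
#' @export
coord_index <- function(lattice, k) {
  if (!is.matrix(k)) k <- matrix(k, nrow = 1L)
  if (ncol(k) != lattice$d) {
    stop("coordinate vectors must have one component per habitat dimension",
         call. = FALSE)
  }
  bad <- sweep(k, 2L, lattice$dims, function(a, b) a < 0 | a >= b | a != floor(a))
  if (any(bad)) stop("coordinates out of range for this lattice", call. = FALSE)
  as.integer(k %*% lattice$weights) + 1L
}

#' Character of the patch group
#'
#' Evaluates \eqn{\chi_k(h) = \exp(2\pi i \sum_j k_j h_j / D_j)}, the
#' character of the finite abelian group of patches at displacement `k`
#' and frequency `h`. Characters have modulus one and are symmetric in
#' their two arguments.
#'
#' @inheritParams coord_index
#' @param h integer coordinate vector, like `k`.
#' @return a complex scalar of modulus 1.
#' @export
character_fn <- function(lattice, k, h) {
  ik <- coord_index(lattice, k)
  ih <- coord_index(lattice, h)
  lattice$chi[ik, ih]
}

#' Fourier transform of a spatial field
#'
#' Computes \eqn{F(h) = \sum_k f_k \chi_k(h)} over all frequencies
#' \eqn{h \in G}. This follows the population-genetics sign convention:
#' the forward transform uses the character \eqn{\chi} (positive
#' exponent), so that the transform of a probability kernel is its
#' characteristic function; [inverse_transform()] uses the conjugate.
#' The value at `h = 0` is the plain sum of the field.
#'
#' @param field numeric (or complex) vector of one value per patch.
#' @param lattice a [patch_lattice()].
#' @return complex vector of length `D`, the spectrum over all `h`.
#' @export
fourier_transform <- function(field, lattice) {
  check_field(field, lattice)
  as.vector(lattice$chi %*% field)
}

#' Inverse Fourier transform
#'
#' Recovers \eqn{f_k = L_k(F) = (1/D) \sum_h F(h) \bar\chi_k(h)}. When
#' `real = TRUE` (the default) the result of a spectrum arising from a
#' real symmetric field is cast to real: the imaginary residue must not
#' exceed `1e-9 * (1 + max|Re|)`, otherwise an error is raised.
#'
#' @param spectrum complex vector of length `D`.
#' @param lattice a [patch_lattice()].
#' @param real logical; cast the result to a real field (with residue
#'   check) or return the raw complex vector.
#' @return numeric (or complex) vector of one value per patch.
#' @export
inverse_transform <- function(spectrum, lattice, real = TRUE) {
  check_field(spectrum, lattice, "spectrum")
  out <- as.vector(Conj(lattice$chi) %*% spectrum) / lattice$D
  if (!real) return(out)
  cast_real(out)
}

# drop a numerically negligible imaginary part, error otherwise
cast_real <- function(x, tol = 1e-9) {
  if (is.complex(x)) {
    lim <- tol * (1 + max(abs(Re(x))))
    if (max(abs(Im(x))) > lim) {
      stop("result has a non-negligible imaginary part; ",
           "input spectrum does not correspond to a real field", call. = FALSE)
    }
    x <- Re(x)
  }
  x
}

#' Group convolution of two spatial fields
#'
#' Direct summation \eqn{(f * g)_k = \sum_j f_j g_{k-j}} with subtraction
#' in the patch group. This is the reference (oracle) implementation used
#' to validate spectral shortcuts: the transform of a convolution equals
#' the pointwise product of the transforms.
#'
#' @param f,g numeric vectors of one value per patch.
#' @param lattice a [patch_lattice()].
#' @return numeric vector of one value per patch.
#' @export
group_convolve <- function(f, g, lattice) {
  check_field(f, lattice, "f")
  check_field(g, lattice, "g")
  gm <- matrix(g[lattice$sub], lattice$D, lattice$D)
  as.vector(gm %*% f)
}
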