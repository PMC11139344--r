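# Shared fixtures and independent oracles used across the suite.

# small mixing kernel on a 1D lattice of 9 patches
toy_lattice <- function() patch_lattice(9)
toy_kernel <- function(lat = toy_lattice()) truncated_binomial_kernel(lat, 0.6, 1.6)

# direct double-loop Fourier transform (independent of the matrix path)
ft_direct <- function(field, lat) {
  vapply(seq_len(lat$D), function(h) {
    sum(field * exp(2i * pi * as.vector(lat$coords %*%
                                          (lat$coords[h, ] / lat$dims))))
  }, complex(1))
}

# analytic competition coefficients for the survival-fecundity fitness
# function, obtained by hand differentiation (independent of the
# numeric-central-difference implementation path)
lambda_analytic <- function(kernel, N, lc) {
  mm <- group_convolve(kernel$field, kernel$field, kernel$lattice)
  s <- lc$s; sp <- lc$s_prime; f <- lc$f; fp <- lc$f_prime
  den <- sp * (1 - kernel$field[1L] / N) + (1 - s) * (fp / f) * (1 - mm[1L] / N)
  lam <- (sp * kernel$field + (1 - s) * (fp / f) * mm) / den
  lam[1L] <- (sp * kernel$field[1L] + (1 - s) * (fp / f) * mm[1L]) *
    (N - 1) / N / den
  lam
}

# K for the Wright-Fisher fecundity life cycle, direct resolvent sum
K_wf_direct <- function(m_kernel, psi_spectrum, c_spectrum, N) {
  lat <- m_kernel$lattice
  M <- m_kernel$spectrum
  Psim <- psi_spectrum[lat$neg]
  Cm <- c_spectrum[lat$neg]
  terms <- (M * Psim / (1 - Cm * M))[-1L]
  Re(sum(terms)) / (lat$D * N - 1)
}

# truncated double series K = sum_t sum_k e_{k,t} kappa_{k,t}
K_series <- function(m_kernel, derivs, N, lc, t_max = 400, tol = 1e-12) {
  eff <- extended_effects(derivs, t_max)
  total <- 0
  for (t in seq_len(t_max)) {
    kap <- kappa_general(m_kernel, N, lc, t)
    term <- sum(eff$entries[[t]] * kap)
    total <- total + term
    if (t > 5 && abs(term) < tol * max(abs(total), 1e-12)) break
  }
  total
}

expect_field_equal <- function(a, b, tol) {
  expect_lt(max(abs(a - b)), tol)
}
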