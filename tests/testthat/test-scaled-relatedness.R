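test_that("Wright-Fisher scaled relatedness has its closed-form structure", {
  lat <- toy_lattice()
  ker <- toy_kernel(lat)
  N <- 5
  # same generation: a uniform negative constant
  k0 <- kappa_wf(ker, N, 0)
  expect_field_equal(k0, rep(-1 / (lat$D * N - 1), lat$D), 1e-15)
  # uniform dispersal: no structure at any future time
  u <- uniform_kernel(lat)
  for (t in 1:3) expect_lt(max(abs(kappa_wf(u, N, t))), 1e-13)
  # sign follows the gene walk's excess over the uniform distribution
  for (t in 1:4) {
    p <- walk_distribution(ker, t)
    expect_equal(sign(kappa_wf(ker, N, t)), sign(p - 1 / lat$D))
  }
})

test_that("the general closed form reduces to Wright-Fisher and is symmetric", {
  ker <- toy_kernel()
  N <- 5
  for (t in c(0, 1, 3, 7)) {
    expect_field_equal(kappa_general(ker, N, lifecycle_wf(), t),
                       kappa_wf(ker, N, t), 1e-12)
    kg <- kappa_general(ker, N, lifecycle_survival(0.6), t)
    expect_field_equal(kg, kg[ker$lattice$neg], 1e-12)
  }
})

test_that("high adult survival steepens the decay of genetic value in space", {
  lat <- patch_lattice(31)
  ker <- truncated_binomial_kernel(lat, 0.3, 1.55)
  k_low <- kappa_general(ker, 20, lifecycle(0, 1, 1, 0), 1)
  k_high <- kappa_general(ker, 20, lifecycle_survival(0.9), 1)
  # relative to the focal-patch value, the adjacent patch carries less
  # genetic value when baseline survival is high
  expect_lt(k_high[2L] / k_high[1L], k_low[2L] / k_low[1L])
})

test_that("numeric competition coefficients match hand differentiation", {
  lat <- toy_lattice()
  ker <- toy_kernel(lat)
  N <- 5
  for (lc in list(lifecycle_wf(), lifecycle(0.4, 1, 1, 0),
                  lifecycle(0.3, 0.7, 2, 1.5))) {
    lam <- lambda_from_fitness(ker, N, lc)
    expect_field_equal(lam, lambda_analytic(ker, N, lc), 1e-6)
    expect_field_equal(lam, lam[lat$neg], 1e-9)
  }
  # exchangeability under uniform dispersal: one value off the origin
  lam_u <- lambda_from_fitness(uniform_kernel(lat), N, lifecycle_wf())
  expect_lt(diff(range(lam_u[-1L])), 1e-9)
})

test_that("the definitional route reproduces the closed forms", {
  lat <- toy_lattice()
  ker <- toy_kernel(lat)
  N <- 5
  rt <- relatedness_table(ker, N, 6)
  # Wright-Fisher: definition + numeric competition = closed form
  lam <- lambda_from_fitness(ker, N, lifecycle_wf())
  for (t in c(0, 1, 2, 5)) {
    expect_field_equal(kappa_from_definition(lam, rt, N, t),
                       kappa_wf(ker, N, t), 1e-8)
  }
  # life cycles without adult survival (the domain where the neutral
  # Wright-Fisher relatedness applies), with survival and fecundity
  # payoff effects of varying strength
  for (lc in list(lifecycle(0, 1, 1, 0), lifecycle(0, 0.5, 1, 1),
                  lifecycle(0, 2, 3, 0.5))) {
    lam <- lambda_from_fitness(ker, N, lc)
    for (t in c(0, 1, 4)) {
      expect_field_equal(kappa_from_definition(lam, rt, N, t),
                         kappa_general(ker, N, lc, t), 1e-8)
    }
  }
  # with zero competition, scaled relatedness is plain relatedness
  zero <- numeric(lat$D)
  for (t in c(1, 3)) {
    expect_field_equal(kappa_from_definition(zero, rt, N, t),
                       ibdsel:::rel_at(rt, t), 1e-14)
  }
  # uniform kernel: the same-generation branch still yields the
  # Wright-Fisher constant
  u <- uniform_kernel(lat)
  rtu <- relatedness_table(u, N, 2)
  lamu <- lambda_from_fitness(u, N, lifecycle_wf())
  expect_field_equal(kappa_from_definition(lamu, rtu, N, 0),
                     rep(-1 / (lat$D * N - 1), lat$D), 1e-10)
})

test_that("larger lattices preserve the definitional-closed agreement", {
  for (dims in list(81, c(9, 9))) {
    lat <- patch_lattice(dims)
    ker <- truncated_binomial_kernel(lat, 0.7, 1.8)
    N <- 4
    rt <- relatedness_table(ker, N, 3)
    lam <- lambda_from_fitness(ker, N, lifecycle_wf())
    for (t in c(0, 2)) {
      expect_field_equal(kappa_from_definition(lam, rt, N, t),
                         kappa_wf(ker, N, t), 1e-8)
    }
  }
})

test_that("same-generation scaled relatedness is never positive under
           Wright-Fisher", {
  for (ker in list(toy_kernel(), uniform_kernel(patch_lattice(12)),
                   truncated_binomial_kernel(patch_lattice(c(7, 7)), 0.9, 3))) {
    expect_lte(max(kappa_wf(ker, 10, 0)), 0)
  }
})

test_that("the environmental summary statistic K agrees across routes", {
  lat <- toy_lattice()
  ker <- toy_kernel(lat)
  dker <- truncated_binomial_kernel(lat, 0.9, 2.5)
  N <- 5
  eps <- 0.4
  psi <- 3 * dker$field / N
  cf <- (1 - eps) * dker$field
  Psi <- fourier_transform(psi, lat)
  Ch <- fourier_transform(cf, lat)
  # zero perturbation, zero selection through the environment
  expect_equal(K_statistic(ker, Psi * 0, Ch, N, lifecycle_wf()), 0)
  # Wright-Fisher specialisation equals the general resolvent
  K <- K_statistic(ker, Psi, Ch, N, lifecycle_wf())
  expect_equal(K, K_wf_direct(ker, Psi, Ch, N), tolerance = 1e-10)
  # truncated double series over extended effects and scaled relatedness
  derivs <- env_map_derivs(psi, cf, lat)
  expect_equal(K, K_series(ker, derivs, N, lifecycle_wf()), tolerance = 1e-8)
  # the series agreement extends to survival and mixed life cycles
  for (lc in list(lifecycle_survival(0.5), lifecycle(0.3, 0.7, 2, 1.5))) {
    expect_equal(K_statistic(ker, Psi, Ch, N, lc),
                 K_series(ker, derivs, N, lc), tolerance = 1e-8)
  }
  # an amplifying environmental feedback makes the resolvent diverge
  amplifying <- rep(10 + 0i, lat$D)   # spectrum of 10x self-feedback
  expect_error(K_statistic(ker, Psi, amplifying, N, lifecycle_wf()),
               "divergent")
})
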