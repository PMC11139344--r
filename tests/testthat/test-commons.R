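make_model <- function(lat = patch_lattice(9), N = 5,
                       m = c(0.6, 1.6), d = c(0.9, 2.5),
                       epsilon = 0.5, P0 = N, lifecycle = "wf_fecundity",
                       ...) {
  commons_model(lat, N,
                truncated_binomial_kernel(lat, m[1L], m[2L]),
                truncated_binomial_kernel(lat, d[1L], d[2L]),
                B = 2, alpha_B = 1, C = 1, alpha_C = 4,
                epsilon = epsilon, P0 = P0, lifecycle = lifecycle, ...)
}

test_that("the payoff function has its exponential-family identities", {
  mod <- make_model()
  expect_equal(payoff_commons(0, 0, mod), 1)
  expect_equal(payoff_commons(0, 0.5, mod), exp(1))   # B = 2, alpha_B = 1
  # any trait expression away from zero is individually costly
  for (z in c(-0.5, 0.2, 1)) expect_lt(payoff_commons(z, 0, mod), 1)
  expect_true(payoff_commons(3, -10, mod) > 0)
  expect_equal(payoff_commons(0.3, 0.2, mod, log = TRUE),
               log(payoff_commons(0.3, 0.2, mod)))
})

test_that("the commons equilibrium balances production against decay", {
  lat <- patch_lattice(9)
  mod <- make_model(lat, N = 50, P0 = 50, epsilon = 0.5)
  expect_equal(env_equilibrium(0, mod), 0)
  expect_equal(env_equilibrium(0.1, mod), 10)     # P = N z, N = 50, eps = 0.5
  expect_equal(sign(env_equilibrium(-0.3, mod)), -1)
  # iterating the map from an empty commons converges to the equilibrium
  # in every patch
  z <- 0.1
  n <- numeric(lat$D)
  for (i in 1:200) n <- commons_map(rep(z, lat$D), n, mod)
  expect_field_equal(n, rep(env_equilibrium(z, mod), lat$D), 1e-10)
})

test_that("analytic commons effect fields match numeric differentiation", {
  mod <- make_model()
  z <- 0.2
  derivs <- commons_effect_fields(z, mod)
  env_map <- function(z_field, n_field) {
    sum(mod$d_kernel$field * ((1 - mod$epsilon) * n_field + mod$P_fun(z_field)))
  }
  num <- differentiate_env_map(env_map, z, env_equilibrium(z, mod), mod$N,
                               mod$lattice)
  expect_field_equal(derivs$psi, num$psi, 1e-6)
  expect_field_equal(derivs$c, num$c, 1e-6)
  # full decay leaves no environmental feedback
  mod1 <- make_model(epsilon = 1)
  expect_field_equal(commons_effect_fields(0, mod1)$c,
                     numeric(mod1$lattice$D), 1e-14)
})

test_that("commons extended effects equal the generic spectral machinery", {
  lat <- patch_lattice(31)
  mod <- commons_model(lat, 20,
                       truncated_binomial_kernel(lat, 0.3, 1.55),
                       truncated_binomial_kernel(lat, 0.6, 1.55),
                       B = 2, alpha_B = 1, C = 1, alpha_C = 4,
                       epsilon = 0.2, P0 = 20)
  eff <- commons_extended_effects(0, mod, 10)
  # first horizon: production spread by one round of movement
  expect_field_equal(eff$entries[[1L]],
                     mod$P_prime(0) * mod$d_kernel$field / mod$N, 1e-12)
  # cross-route: generic propagation of (psi, c)
  gen <- extended_effects(commons_effect_fields(0, mod), 10)
  for (t in 1:10) expect_field_equal(eff$entries[[t]], gen$entries[[t]], 1e-10)
  # instant decay: nothing persists past the first generation
  mod1 <- make_model(epsilon = 1)
  eff1 <- commons_extended_effects(0, mod1, 3)
  for (t in 2:3) expect_lt(max(abs(eff1$entries[[t]])), 1e-14)
})

test_that("all Omega routes agree and panmixia has zero genetic value", {
  mod <- make_model()
  om <- omega(mod)
  expect_equal(omega(mod, "series"), om, tolerance = 1e-8)
  expect_equal(omega(mod, "covariance_wf"), om, tolerance = 1e-8)
  expect_equal(ibdsel:::omega_resolvent_wf(mod), om, tolerance = 1e-12)
  # identity with the environmental summary statistic
  Psi <- as.complex(mod$P_prime(0) * mod$d_kernel$spectrum / mod$N)
  Ch <- as.complex((1 - mod$epsilon) * mod$d_kernel$spectrum)
  K <- K_statistic(mod$m_kernel, Psi, Ch, mod$N, mod$lifecycle)
  expect_equal(mod$epsilon * K * mod$N / mod$P_prime(0), om, tolerance = 1e-10)
  # uniform dispersal and movement: every off-origin term vanishes
  lat <- patch_lattice(8)
  mod_u <- commons_model(lat, 5, uniform_kernel(lat), uniform_kernel(lat),
                         B = 2, alpha_B = 1, C = 1, alpha_C = 4,
                         epsilon = 0.5, P0 = 5)
  expect_equal(mod_u$omega, 0, tolerance = 1e-14)
  expect_equal(mod_u$z_star, 0)
  # route agreement for a survival life cycle (no covariance route there)
  modS <- make_model(lifecycle = lifecycle_survival(0.6))
  expect_equal(omega(modS, "series"), modS$omega, tolerance = 1e-8)
  expect_error(omega(modS, "covariance_wf"), "Wright-Fisher")
})

test_that("the weak-dispersal limit approximates the closed form", {
  lat <- patch_lattice(c(13, 13))
  mod <- commons_model(lat, 50,
                       truncated_binomial_kernel(lat, 0.01, 1.54),
                       truncated_binomial_kernel(lat, 0.01, 8),
                       B = 2, alpha_B = 1, C = 1, alpha_C = 4,
                       epsilon = 0.5, P0 = 50)
  closed <- mod$omega
  limit <- omega(mod, "weak_dispersal")
  expect_gt(closed, 0)
  expect_lt(abs(closed - limit) / abs(closed), 0.05)
})

test_that("the commons gradient matches the generic payoff-form gradient", {
  mod <- make_model()
  z <- 0.15
  n_hat <- env_equilibrium(z, mod)
  pi_res <- payoff_commons(z, n_hat, mod)
  lat <- mod$lattice
  dz0 <- numeric(lat$D)
  dn0 <- numeric(lat$D)
  dn0[1L] <- pi_res * mod$B * mod$alpha_B * n_hat^(mod$alpha_B - 1)
  d_self <- pi_res * (-mod$C * mod$alpha_C * z^(mod$alpha_C - 1))
  pd <- payoff_derivs(d_self, dz0, dn0, lat)
  Psi <- as.complex(mod$P_prime(z) * mod$d_kernel$spectrum / mod$N)
  Ch <- as.complex((1 - mod$epsilon) * mod$d_kernel$spectrum)
  K <- K_statistic(mod$m_kernel, Psi, Ch, mod$N, mod$lifecycle)
  generic <- gradient_payoff_local(pd, K, mod$N, kappa_wf(mod$m_kernel, mod$N, 0)[1L])
  # the closed-form gradient carries the same zeros and sign: it equals
  # the generic assembly divided by the (positive) resident payoff
  expect_equal(generic / pi_res, selection_gradient_commons(z, mod),
               tolerance = 1e-8)
  # at z = 0 the gradient is proportional to Omega (alpha_B = 1 here)
  expect_equal(selection_gradient_commons(0, mod),
               mod$omega * mod$B * mod$P_prime(0) / mod$epsilon,
               tolerance = 1e-12)
})

test_that("the singular strategy is the gradient root and scales as expected", {
  mod <- make_model()
  # closed form vs numeric root finding
  dir <- sign(mod$omega)
  root <- stats::uniroot(function(z) selection_gradient_commons(z, mod),
                         interval = sort(c(dir * 1e-6, dir * 10)),
                         tol = 1e-14)$root
  expect_equal(mod$z_star, root, tolerance = 1e-8)
  expect_equal(sign(mod$z_star), sign(mod$omega))
  # |z*| grows with benefit-to-cost ratio and with production slope
  mod_bigB <- commons_model(mod$lattice, mod$N, mod$m_kernel, mod$d_kernel,
                            B = 4, alpha_B = 1, C = 1, alpha_C = 4,
                            epsilon = 0.5, P0 = 5)
  mod_bigP <- commons_model(mod$lattice, mod$N, mod$m_kernel, mod$d_kernel,
                            B = 2, alpha_B = 1, C = 1, alpha_C = 4,
                            epsilon = 0.5, P0 = 10)
  expect_gt(abs(mod_bigB$z_star), abs(mod$z_star))
  expect_gt(abs(mod_bigP$z_star), abs(mod$z_star))
})

test_that("singular strategies of this payoff family are convergence stable", {
  for (mod in list(make_model(),
                   make_model(m = c(0.9, 3), d = c(1.0, 3.5)),
                   make_model(lifecycle = lifecycle_survival(0.5)))) {
    expect_true(mod$convergence_stable)
    cc <- convergence_check(mod$z_star, mod)
    expect_lt(cc$slope, 0)
    # slope sign is stable under a halved differentiation step
    h <- 1e-5 * (1 + abs(mod$z_star)) / 2
    slope2 <- (selection_gradient_commons(mod$z_star + h, mod) -
               selection_gradient_commons(mod$z_star - h, mod)) / (2 * h)
    expect_equal(sign(slope2), sign(cc$slope))
  }
  mod <- make_model()
  if (mod$omega > 0) {
    expect_gt(selection_gradient_commons(0, mod), 0)  # z = 0 repels upward
  } else {
    expect_lt(selection_gradient_commons(0, mod), 0)
  }
  expect_error(convergence_check(mod$z_star + 0.5, mod), "not a root")
})

test_that("parameter invariants are enforced at construction", {
  lat <- patch_lattice(9)
  m <- truncated_binomial_kernel(lat, 0.6, 1.6)
  expect_error(commons_model(lat, 5, m, m, B = 2, alpha_B = 1, C = 1,
                             alpha_C = 3, epsilon = 0.5, P0 = 5),
               "even")
  expect_error(commons_model(lat, 5, m, m, B = 2, alpha_B = 2, C = 1,
                             alpha_C = 4, epsilon = 0.5, P0 = 5),
               "odd")
  expect_error(commons_model(lat, 5, m, m, B = 2, alpha_B = 3, C = 1,
                             alpha_C = 2, epsilon = 0.5, P0 = 5),
               "alpha_C")
  expect_error(commons_model(lat, 5, m, m, B = 2, alpha_B = 1, C = 1,
                             alpha_C = 4, epsilon = 0, P0 = 5),
               "epsilon")
  expect_error(commons_model(lat, 5, m, m, B = -1, alpha_B = 1, C = 1,
                             alpha_C = 4, epsilon = 0.5, P0 = 5),
               "positive")
})
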