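sim_model <- function() {
  lat <- patch_lattice(c(5, 5))
  commons_model(lat, 10,
                truncated_binomial_kernel(lat, 0.3, 1.5),
                truncated_binomial_kernel(lat, 0.9, 2.5),
                B = 2, alpha_B = 1, C = 1, alpha_C = 4,
                epsilon = 0.5, P0 = 10)
}

test_that("population initialisation is deterministic and census-exact", {
  mod <- sim_model()
  st <- init_population(mod, init_trait = 0)
  expect_true(all(st$traits == 0))
  expect_true(all(st$env == 0))
  expect_equal(dim(st$traits), c(10, 25))
  st2 <- init_population(mod)   # defaults to the singular value
  expect_true(all(st2$traits == mod$z_star))
  expect_field_equal(st2$env, rep(env_equilibrium(mod$z_star, mod), 25), 1e-14)
})

test_that("a demographic step conserves the census and follows the
           deterministic commons map", {
  mod <- sim_model()
  set.seed(99)
  st <- init_population(mod, init_trait = 0.1, init_env = 0)
  for (i in 1:30) {
    st <- step_wf(st, mod, mutation_prob = 0)
    expect_equal(dim(st$traits), c(10, 25))
    expect_true(all(is.finite(st$env)))
  }
  # without mutation a monomorphic population stays monomorphic and its
  # commons tracks the deterministic lattice map exactly
  expect_true(all(st$traits == 0.1))
  n_det <- numeric(25)
  for (i in 1:30) n_det <- commons_map(rep(0.1, 25), n_det, mod)
  expect_field_equal(st$env, n_det, 1e-12)
  # and converges to the predicted equilibrium
  for (i in 1:300) st <- step_wf(st, mod, mutation_prob = 0)
  expect_field_equal(st$env, rep(env_equilibrium(0.1, mod), 25), 1e-8)
})

test_that("recruitment realises the survival-fecundity fitness expectation", {
  # two-patch configuration with patch-homogeneous payoffs: the expected
  # number of recruits descending from one parent, computed from the
  # sampling scheme, must equal the fitness function
  lat <- patch_lattice(2)
  N <- 4
  mod <- commons_model(lat, N,
                       validate_kernel(c(0.7, 0.3), lat),
                       validate_kernel(c(0.8, 0.2), lat),
                       B = 2, alpha_B = 1, C = 1, alpha_C = 4,
                       epsilon = 0.5, P0 = 4)
  st <- init_population(mod, init_trait = 0, init_env = 0)
  st$traits[, 1L] <- 0.05   # patch 0 expresses, patch 1 does not
  st$env <- c(0.3, -0.1)
  pay <- matrix(payoff_commons(st$traits, rep(st$env, each = N), mod), N, 2)
  fec <- pay                            # identity fecundity
  probs <- ibdsel:::source_probs(mod, colSums(fec))
  # expected recruits of an individual in patch j: over destinations k,
  # N slots times P(source = j) times its fecundity share within j
  for (j in 1:2) {
    expected <- sum(N * probs[, j] * fec[1L, j] / sum(fec[, j]))
    # fitness function sees displacement-indexed average payoffs
    pi_field <- c(mean(pay[, j]), mean(pay[, 3 - j]))
    w <- fitness_sf(pay[1L, j], pi_field, mod$m_kernel, N, mod$lifecycle)
    expect_equal(expected, w, tolerance = 1e-12)
  }
})

test_that("runs are reproducible and summarised correctly", {
  mod <- sim_model()
  s1 <- run_simulation(mod, generations = 40, seed = 5)
  s2 <- run_simulation(mod, generations = 40, seed = 5)
  expect_identical(s1$trajectory, s2$trajectory)
  s3 <- run_simulation(mod, generations = 0, seed = 5)
  expect_equal(nrow(s3$trajectory), 1L)
  expect_equal(s3$trajectory$mean_trait, mod$z_star)
  # simulate() generic dispatches to the runner
  s4 <- simulate(mod, nsim = 1, seed = 5, generations = 40)
  expect_identical(s4$trajectory, s1$trajectory)

  traj <- c(rep(1.5, 10))
  expect_equal(estimate_equilibrium(traj), c(mean = 1.5, sd = 0))
  expect_equal(estimate_equilibrium(traj, burn_in = 4)[["mean"]], 1.5)
  expect_error(estimate_equilibrium(traj, burn_in = 10), "empty")
})

test_that("a short run stays at the predicted singular value", {
  mod <- sim_model()
  sim <- run_simulation(mod, generations = 300, burn_in = 100, seed = 123)
  est <- estimate_equilibrium(sim)
  # initialised at z*, the population should not drift away by more than
  # a few mutational standard deviations in a short run
  expect_lt(abs(est[["mean"]] - mod$z_star), 0.05)
  # mean commons tracks the equilibrium of the realised mean trait
  tail_env <- utils::tail(sim$trajectory$mean_env, 1)
  expect_lt(abs(tail_env - env_equilibrium(est[["mean"]], mod)) /
              max(abs(mod$n_hat), 1), 0.05)
})

test_that("degenerate fecundity states are rejected", {
  mod <- sim_model()
  st <- init_population(mod, init_trait = 0, init_env = -1e6)
  # payoffs underflow to zero in every patch: no parent can be drawn
  expect_error(step_wf(st, mod), "degenerate")
})
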