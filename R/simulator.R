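#' Initialise a simulated population
#'
#' All `N * D` individuals start at `init_trait`; the commons starts at
#' the corresponding monomorphic equilibrium (`"equilibrium"`, the
#' default) or at a supplied level, identical in every patch.
#'
#' @param p a `commons_model`.
#' @param init_trait starting trait value for every individual (default
#'   the model's predicted singular value).
#' @param init_env `"equilibrium"` or a numeric commons level.
#' @return an object of class `population_state`: list with `traits`
#'   (an `N x D` matrix), `env` (length-`D` vector) and `generation`.
#' @export
init_population <- function(p, init_trait = p$z_star, init_env = "equilibrium") {
  env0 <- if (identical(init_env, "equilibrium")) {
    env_equilibrium(init_trait, p)
  } else {
    as.numeric(init_env)
  }
  structure(
    list(traits = matrix(init_trait, nrow = p$N, ncol = p$lattice$D),
         env = rep(env0, p$lattice$D),
         generation = 0L),
    class = "population_state"
  )
}

# probability that a recruit filling a slot in patch k descends from
# source patch j: proportional to m_{k-j} * F_j with F_j the summed
# fecundity in patch j; rows index destination patches
source_probs <- function(p, fec_total) {
  lat <- p$lattice
  m <- p$m_kernel$field
  W <- matrix(m[lat$sub], lat$D, lat$D)   # W[k, j] = m_{k-j}
  raw <- W * rep(fec_total, each = lat$D)
  rs <- rowSums(raw)
  if (any(rs <= 0)) stop("degenerate state: no fecundity reaches some patch",
                         call. = FALSE)
  raw / rs
}

#' Advance the population by one Wright-Fisher demographic time step
#'
#' One generation in cyclic order: (1) each adult's payoff is computed
#' from its own trait and the local commons; (2) fecundity is the
#' life-cycle fecundity function of payoff (identity for the
#' Wright-Fisher fecundity model); (3) the commons is updated in every
#' patch from the parental patch-mean traits and current stocks;
#' (4) every one of the `N` slots per patch is filled independently by an
#' offspring whose source patch is drawn with probability proportional
#' to dispersal times total source fecundity, and whose parent within
#' the source patch is drawn proportionally to individual fecundity;
#' (5) each offspring mutates with probability `mutation_prob` by a
#' Gaussian deviation of standard deviation `mutation_sd`. The census
#' returns to exactly `N` adults per patch.
#'
#' @param state a `population_state`.
#' @param p a `commons_model`.
#' @param mutation_prob per-offspring mutation probability.
#' @param mutation_sd standard deviation of the mutational step.
#' @return the next `population_state`.
#' @export
step_wf <- function(state, p, mutation_prob = 1e-4, mutation_sd = 1e-2) {
  lat <- p$lattice
  N <- p$N
  D <- lat$D
  lp <- p$B * rep(state$env, each = N)^p$alpha_B - p$C * state$traits^p$alpha_C
  fec <- matrix(p$lifecycle$f_fun(exp(lp)), N, D)
  if (!all(is.finite(fec)) || all(fec <= 0)) {
    stop("degenerate state: fecundities are not finite and positive", call. = FALSE)
  }
  fec_total <- colSums(fec)

  env_next <- commons_map(colMeans(state$traits), state$env, p)

  probs <- source_probs(p, fec_total)
  # counts[j, k]: recruits of patch k drawn from source patch j
  counts <- vapply(seq_len(D), function(k) {
    stats::rmultinom(1L, N, probs[k, ])[, 1L]
  }, integer(D))
  need <- rowSums(counts)                  # offspring needed per source patch
  traits_next <- matrix(0, N, D)
  pool <- vector("list", D)
  for (j in seq_len(D)) {
    if (need[j] > 0L) {
      idx <- sample.int(N, need[j], replace = TRUE, prob = fec[, j])
      pool[[j]] <- state$traits[idx, j]
    }
  }
  used <- integer(D)
  for (k in seq_len(D)) {
    z <- numeric(N)
    pos <- 0L
    for (j in which(counts[, k] > 0L)) {
      nk <- counts[j, k]
      z[(pos + 1L):(pos + nk)] <- pool[[j]][(used[j] + 1L):(used[j] + nk)]
      used[j] <- used[j] + nk
      pos <- pos + nk
    }
    traits_next[, k] <- z
  }

  mut <- stats::runif(N * D) < mutation_prob
  if (any(mut)) {
    traits_next[mut] <- traits_next[mut] +
      stats::rnorm(sum(mut), mean = 0, sd = mutation_sd)
  }

  structure(list(traits = traits_next, env = env_next,
                 generation = state$generation + 1L),
            class = "population_state")
}

#' Run an individual-based simulation
#'
#' Evolves the population for a fixed number of Wright-Fisher
#' generations, recording per-generation summaries of the trait and the
#' commons. Runs are reproducible given `seed`.
#'
#' @param p a `commons_model`.
#' @param generations number of demographic time steps.
#' @param burn_in generations discarded by [estimate_equilibrium()]
#'   (must be smaller than `generations`).
#' @param mutation_prob per-offspring mutation probability.
#' @param mutation_sd standard deviation of mutational steps.
#' @param init_trait starting trait value (default the analytic
#'   singular value, so the run probes whether the population stays
#'   there).
#' @param init_env `"equilibrium"` or a numeric commons level.
#' @param seed integer RNG seed.
#' @return an object of class `commons_sim`: list with `trajectory`
#'   (data frame of `generation`, `mean_trait`, `sd_trait`, `mean_env`),
#'   the model, and the run settings.
#' @export
run_simulation <- function(p, generations, burn_in = 0L,
                           mutation_prob = 1e-4, mutation_sd = 1e-2,
                           init_trait = p$z_star, init_env = "equilibrium",
                           seed = 1L) {
  stopifnot(inherits(p, "commons_model"))
  if (burn_in >= generations && generations > 0) {
    stop("'burn_in' must be smaller than 'generations'", call. = FALSE)
  }
  set.seed(as.integer(seed))
  state <- init_population(p, init_trait = init_trait, init_env = init_env)
  n_rec <- generations + 1L
  traj <- data.frame(generation = integer(n_rec), mean_trait = numeric(n_rec),
                     sd_trait = numeric(n_rec), mean_env = numeric(n_rec))
  record <- function(i, st) {
    traj$generation[i] <<- st$generation
    traj$mean_trait[i] <<- mean(st$traits)
    traj$sd_trait[i] <<- stats::sd(as.vector(st$traits))
    traj$mean_env[i] <<- mean(st$env)
  }
  record(1L, state)
  if (generations > 0) {
    for (g in seq_len(generations)) {
      state <- step_wf(state, p, mutation_prob = mutation_prob,
                       mutation_sd = mutation_sd)
      record(g + 1L, state)
    }
  }
  structure(
    list(trajectory = traj, model = p, generations = generations,
         burn_in = burn_in, mutation_prob = mutation_prob,
         mutation_sd = mutation_sd, init_trait = init_trait, seed = seed,
         final_state = state),
    class = "commons_sim"
  )
}

#' Simulate from a lasting-commons model
#'
#' Method for [stats::simulate()]: runs the individual-based
#' Wright-Fisher simulator for this model. See [run_simulation()] for
#' the arguments and return value; `nsim > 1` returns a list of runs
#' with seeds `seed, seed + 1, ...`.
#'
#' @param object a `commons_model`.
#' @param nsim number of independent runs.
#' @param seed integer RNG seed for the first run.
#' @param ... passed to [run_simulation()].
#' @return a `commons_sim` (or list of them when `nsim > 1`).
#' @export
simulate.commons_model <- function(object, nsim = 1, seed = 1L, ...) {
  runs <- lapply(seq_len(nsim) - 1L, function(i) {
    run_simulation(object, seed = as.integer(seed) + i, ...)
  })
  if (nsim == 1) runs[[1L]] else runs
}

#' @export
print.commons_sim <- function(x, ...) {
  est <- estimate_equilibrium(x)
  cat(sprintf("individual-based run: %d generations on a %s lattice (seed %d)\n",
              x$generations, paste(x$model$lattice$dims, collapse = " x "),
              x$seed))
  cat(sprintf("  post-burn-in mean trait %.5g (sd %.3g); analytic z* = %.5g\n",
              est["mean"], est["sd"], x$model$z_star))
  invisible(x)
}

#' @export
plot.commons_sim <- function(x, ...) {
  tr <- x$trajectory
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  graphics::plot(tr$generation, tr$mean_trait, type = "l",
                 xlab = "generation", ylab = "mean trait", ...)
  graphics::abline(h = x$model$z_star, lty = 2)
  graphics::plot(tr$generation, tr$mean_env, type = "l",
                 xlab = "generation", ylab = "mean commons", ...)
  graphics::abline(h = x$model$n_hat, lty = 2)
  invisible(x)
}

#' Post-burn-in equilibrium estimate
#'
#' Mean and standard deviation of the population-mean trait over the
#' generations after the burn-in window.
#'
#' @param sim a `commons_sim` (or a numeric vector of per-generation
#'   mean traits).
#' @param burn_in generations to discard (defaults to the run's own
#'   setting).
#' @return named numeric vector `c(mean, sd)`.
#' @export
estimate_equilibrium <- function(sim, burn_in = NULL) {
  if (inherits(sim, "commons_sim")) {
    if (is.null(burn_in)) burn_in <- sim$burn_in
    series <- sim$trajectory$mean_trait[sim$trajectory$generation > burn_in]
  } else {
    if (is.null(burn_in)) burn_in <- 0L
    series <- sim[seq_along(sim) > burn_in]
  }
  if (length(series) == 0L) stop("empty post-burn-in window", call. = FALSE)
  c(mean = mean(series), sd = stats::sd(series))
}
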