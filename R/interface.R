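#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration describing a lattice, kernels,
#' payoff and commons parameters, life cycle, and (optionally)
#' simulation settings; validates every field and returns the resolved
#' configuration together with the constructed model objects. Missing
#' required fields are reported by name.
#'
#' Recognised blocks: `lattice: {dims}`, `patch_size`,
#' `dispersal: {type, move_prob, mean_distance, values}`,
#' `commons_movement: {...}` (same schema),
#' `payoff: {B, alpha_B, C, alpha_C}`,
#' `environment: {epsilon, production_slope}`,
#' `lifecycle:` a preset name or `{s, s_prime, f, f_prime}`, and
#' `simulation: {generations, burn_in, mutation_prob, mutation_sd,
#' init_trait, seed}`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a list with elements `config` (the raw parsed list),
#'   `lattice`, `m_kernel`, `d_kernel`, `N`, `lifecycle`, and, when the
#'   payoff/environment blocks are present, `model` (a
#'   [commons_model()]) and `simulation` settings.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- function(name, block = cfg) {
    if (is.null(block[[name]])) {
      stop(sprintf("config is missing required field '%s'", name), call. = FALSE)
    }
    block[[name]]
  }
  lattice <- patch_lattice(need("dims", need("lattice")))
  N <- need("patch_size")
  m_kernel <- as_kernel(need("dispersal"), lattice)
  out <- list(config = cfg, lattice = lattice, N = N, m_kernel = m_kernel)
  out$lifecycle <- as_lifecycle(if (is.null(cfg$lifecycle)) "wf_fecundity"
                                else cfg$lifecycle)
  if (!is.null(cfg$commons_movement)) {
    out$d_kernel <- as_kernel(cfg$commons_movement, lattice)
  }
  if (!is.null(cfg$payoff)) {
    pay <- cfg$payoff
    env <- need("environment")
    out$model <- commons_model(
      lattice = lattice, N = N,
      m_kernel = m_kernel, d_kernel = need("commons_movement"),
      B = need("B", pay), alpha_B = need("alpha_B", pay),
      C = need("C", pay), alpha_C = need("alpha_C", pay),
      epsilon = need("epsilon", env),
      P0 = need("production_slope", env),
      lifecycle = out$lifecycle
    )
  }
  if (!is.null(cfg$simulation)) {
    sim <- cfg$simulation
    out$simulation <- list(
      generations = need("generations", sim),
      burn_in = if (is.null(sim$burn_in)) 0L else sim$burn_in,
      mutation_prob = if (is.null(sim$mutation_prob)) 1e-4 else sim$mutation_prob,
      mutation_sd = if (is.null(sim$mutation_sd)) 1e-2 else sim$mutation_sd,
      init_trait = if (is.null(sim$init_trait)) "zstar" else sim$init_trait,
      seed = if (is.null(sim$seed)) 1L else sim$seed
    )
    if (out$simulation$burn_in >= out$simulation$generations) {
      stop("config field 'simulation.burn_in' must be below 'simulation.generations'",
           call. = FALSE)
    }
  }
  out
}

#' Write spatial fields to a long CSV table
#'
#' One row per (temporal index, displacement), with coordinate columns
#' `k1..kd`, a `t` column, and a `value` column, in lexicographic
#' `(t, k)` order.
#'
#' @param fields list of numeric fields, one per temporal index.
#' @param lattice a [patch_lattice()].
#' @param path output file path.
#' @param t_values temporal indices labelling the fields (default
#'   `0, 1, ...` or `1, 2, ...` matching common usage is up to the
#'   caller; defaults to `seq_along(fields) - 1`).
#' @return the path, invisibly.
#' @export
write_field_table <- function(fields, lattice, path,
                              t_values = seq_along(fields) - 1L) {
  stopifnot(length(fields) == length(t_values))
  coord_cols <- as.data.frame(lattice$coords)
  names(coord_cols) <- paste0("k", seq_len(lattice$d))
  rows <- lapply(seq_along(fields), function(i) {
    check_field(fields[[i]], lattice)
    # %.17g keeps doubles exact across the write/read round trip
    cbind(coord_cols, t = t_values[i],
          value = sprintf("%.17g", as.numeric(fields[[i]])))
  })
  tab <- do.call(rbind, rows)
  if (length(rows) == 0L) {
    tab <- cbind(coord_cols[0, , drop = FALSE], t = integer(0), value = numeric(0))
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a field table written by [write_field_table()]
#'
#' @param path CSV path.
#' @param lattice a [patch_lattice()] the table must match.
#' @return list of numeric fields, named by their `t` values.
#' @export
read_field_table <- function(path, lattice) {
  tab <- utils::read.csv(path)
  kcols <- paste0("k", seq_len(lattice$d))
  if (!all(c(kcols, "t", "value") %in% names(tab))) {
    stop("field table lacks the expected k/t/value columns", call. = FALSE)
  }
  split_vals <- split(tab, tab$t)
  out <- lapply(split_vals, function(df) {
    idx <- coord_index(lattice, as.matrix(df[kcols]))
    v <- numeric(lattice$D)
    v[idx] <- df$value
    v
  })
  names(out) <- names(split_vals)
  out
}

#' Bundled example configurations
#'
#' Copies the package's preset configuration files into a directory:
#' a 1D toy lattice (`toy_1d.yaml`), the short- and long-range 1D
#' settings (`short_range_1d.yaml`, `long_range_1d.yaml`, 51 patches of
#' 20), the short-range 2D setting (`short_range_2d.yaml`, 13 x 13), the
#' full 2D commons model with asymmetric commons movement
#' (`commons_spite_2d.yaml`), and a reduced 7 x 7 simulation
#' configuration (`sim_small_2d.yaml`).
#'
#' @param dir destination directory (created if needed).
#' @return character vector of the copied file paths.
#' @export
make_fixtures <- function(dir = tempdir()) {
  src <- system.file("extdata", package = "ibdsel")
  files <- list.files(src, pattern = "\\.yaml$", full.names = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dest <- file.path(dir, basename(files))
  file.copy(files, dest, overwrite = TRUE)
  dest
}

# ---- command-line driver ---------------------------------------------------

cli_manifest <- function(command, cfg_path, out, seed, extra = list()) {
  c(list(command = command, config = cfg_path, out = out, seed = seed,
         package_version = as.character(utils::packageVersion("ibdsel")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    extra)
}

#' Command-line driver
#'
#' Backs the `ibdsel.R` script shipped in `inst/scripts/`: subcommands
#' `relatedness`, `kappa`, `extended-effects`, `omega`, `zstar`,
#' `gradient` and `simulate`, each taking `--config`, `--out` and
#' (where relevant) `--seed` and `--t-max`. Field results are written as
#' long CSV, scalar summaries as JSON, and every run writes a manifest
#' (`<out>.manifest.json`) echoing the resolved parameters.
#'
#' @param args character vector of command-line arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return invisibly, the path(s) written.
#' @export
run_cli <- function(args) {
  if (length(args) < 1L) {
    stop("usage: ibdsel.R <relatedness|kappa|extended-effects|omega|zstar|",
         "gradient|simulate> --config FILE --out FILE [--seed N] [--t-max N]",
         call. = FALSE)
  }
  command <- args[[1L]]
  opt <- list(seed = 1L, t_max = 10L)
  rest <- args[-1L]
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    key <- gsub("-", "_", key)
    if (i + 1L > length(rest)) stop(sprintf("missing value for --%s", key),
                                    call. = FALSE)
    opt[[key]] <- rest[i + 1L]
    i <- i + 2L
  }
  if (is.null(opt$config)) stop("--config is required", call. = FALSE)
  if (is.null(opt$out)) stop("--out is required", call. = FALSE)
  opt$seed <- as.integer(opt$seed)
  opt$t_max <- as.integer(opt$t_max)
  cfg <- load_config(opt$config)
  lat <- cfg$lattice
  paths <- character(0)

  write_json_summary <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    path
  }

  if (command == "relatedness") {
    tab <- relatedness_table(cfg$m_kernel, cfg$N, opt$t_max)
    paths <- write_field_table(tab$entries, lat, opt$out, t_values = 0:opt$t_max)
  } else if (command == "kappa") {
    fields <- lapply(0:opt$t_max, function(t) {
      kappa_general(cfg$m_kernel, cfg$N, cfg$lifecycle, t)
    })
    paths <- write_field_table(fields, lat, opt$out, t_values = 0:opt$t_max)
  } else if (command == "extended-effects") {
    mod <- cfg$model
    if (is.null(mod)) stop("this subcommand needs payoff/environment blocks",
                           call. = FALSE)
    eff <- commons_extended_effects(mod$z_star, mod, opt$t_max)
    paths <- write_field_table(eff$entries, lat, opt$out,
                               t_values = seq_len(opt$t_max))
  } else if (command %in% c("omega", "zstar", "gradient")) {
    mod <- cfg$model
    if (is.null(mod)) stop("this subcommand needs payoff/environment blocks",
                           call. = FALSE)
    summary_obj <- list(
      omega = mod$omega, method = "closed_form", z_star = mod$z_star,
      n_hat = mod$n_hat, stable = mod$convergence_stable,
      slope = mod$gradient_slope
    )
    if (command == "gradient") {
      summary_obj$gradient_at_zero <- selection_gradient_commons(0, mod)
    }
    paths <- write_json_summary(summary_obj, opt$out)
  } else if (command == "simulate") {
    mod <- cfg$model
    sim_cfg <- cfg$simulation
    if (is.null(mod) || is.null(sim_cfg)) {
      stop("'simulate' needs payoff, environment and simulation blocks",
           call. = FALSE)
    }
    init <- sim_cfg$init_trait
    if (identical(init, "zstar")) init <- mod$z_star
    sim <- run_simulation(
      mod, generations = sim_cfg$generations, burn_in = sim_cfg$burn_in,
      mutation_prob = sim_cfg$mutation_prob, mutation_sd = sim_cfg$mutation_sd,
      init_trait = as.numeric(init), seed = opt$seed
    )
    utils::write.csv(sim$trajectory, opt$out, row.names = FALSE)
    est <- estimate_equilibrium(sim)
    write_json_summary(
      list(mean_trait = est[["mean"]], sd_trait = est[["sd"]],
           z_star = mod$z_star, omega = mod$omega, seed = opt$seed),
      paste0(opt$out, ".summary.json"))
    paths <- opt$out
  } else {
    stop(sprintf("unknown subcommand '%s'", command), call. = FALSE)
  }

  write_json_summary(cli_manifest(command, opt$config, opt$out, opt$seed,
                                  extra = list(t_max = opt$t_max,
                                               resolved = cfg$config)),
                     paste0(opt$out, ".manifest.json"))
  invisible(paths)
}
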