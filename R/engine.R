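#' Run one simulation realization
#'
#' Iterates `n_steps` Monte Carlo iterations, each a physical move (SPMC or
#' VMMC) followed by a drive-biased state switch of a different particle, and
#' samples the total energy every `bin` iterations (one sweep). The targets
#' are randomised and the initial positions/states drawn uniformly at the
#' start of the run from the configuration seed, so a fixed seed reproduces
#' the trajectory bit for bit. The first sampled sweep whose energy reaches
#' the assembled threshold sets the first-assembly time `t_fas` (reported in
#' MC steps, a multiple of `bin`).
#'
#' @param config A [sim_config()].
#' @param targets Optional [target_set()]; randomised from the seed when
#'   `NULL`.
#' @param init Optional initial [lattice_state()]; random when `NULL`.
#' @param halt_on_assembly Stop sampling after the first assembly (default
#'   `TRUE`; the forecasting layer truncates there anyway).
#' @param record_cluster_sizes Also record the largest connected cluster per
#'   sweep.
#' @return An object of class `assembly_run`: the sweep-sampled trajectory
#'   tibble plus run metadata (`t_fas`, threshold, final state, config).
#' @examples
#' cfg <- sim_config(dynamics = "SPMC", n_steps = 1e5, bin = 500, seed = 7)
#' run <- simulate_assembly(cfg)
#' tidy(run)
#' @export
simulate_assembly <- function(config, targets = NULL, init = NULL,
                              halt_on_assembly = TRUE,
                              record_cluster_sizes = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  params <- interaction_params(config$js, config$jw, config$mode)
  seeded <- with_seed(config$seed, {
    ts <- if (is.null(targets))
      random_target_set(config$n_particles, config$n_targets)
    else targets
    st <- if (is.null(init))
      random_state(ts, params, config$lattice)
    else init
    list(targets = ts, init = st)
  })
  targets <- seeded$targets
  init <- seeded$init
  threshold <- assembly_threshold(config$n_particles, config$js)
  ma <- model_args(targets, params, config$lattice)
  # a system with no bonds to form (threshold 0) has no assembly event
  detect_at <- if (threshold < 0) threshold else -Inf
  res <- do.call(.cpp_run, c(ma, state_args(init), list(
    n_steps = as.double(config$n_steps), n_mc = as.double(config$bin),
    vmmc = config$dynamics == "VMMC", dmu = config$dmu,
    threshold = detect_at, halt = halt_on_assembly,
    record_cluster = record_cluster_sizes, seed = as.double(config$seed)
  )))
  n_sw <- length(res$energies)
  trajectory <- tibble::tibble(
    sweep = seq_len(n_sw),
    mc_step = seq_len(n_sw) * config$bin,
    energy = res$energies
  )
  if (record_cluster_sizes) trajectory$max_cluster_size <- res$max_cluster
  final_state <- NULL
  if (config$n_particles > 0) {
    final_state <- structure(
      list(lattice = config$lattice, n_particles = config$n_particles,
           positions = cbind(res$r, res$c), states = res$s + 1L,
           energy = res$energy),
      class = "lattice_state"
    )
  }
  structure(
    list(trajectory = trajectory, t_fas = res$t_fas,
         assembled = !is.na(res$t_fas), threshold = threshold,
         config = config, targets = targets, final_state = final_state,
         energy_drift = abs(res$energy - res$energy_check)),
    class = "assembly_run"
  )
}

#' @export
print.assembly_run <- function(x, ...) {
  cat(sprintf(
    "<assembly_run> %s/%s seed %d: %d sweeps, %s\n",
    x$config$dynamics, x$config$mode, x$config$seed, nrow(x$trajectory),
    if (x$assembled) sprintf("assembled at MC step %g", x$t_fas)
    else "not assembled"
  ))
  invisible(x)
}

#' Run an ensemble of independent realizations
#'
#' Realization `k` uses seed `base_seed + k - 1` (a counter-based scheme, so
#' ensembles are reproducible and order-independent) and re-randomises its
#' targets and initial condition. Runs that never assemble carry `t_fas = NA`
#' and are excluded from the median/quartile summaries.
#'
#' @inheritParams simulate_assembly
#' @param n_realizations Number of independent runs.
#' @param base_seed Seed of realization 1; defaults to `config$seed`.
#' @return An `assembly_ensemble`: a tibble with columns `realization`,
#'   `sweep`, `mc_step`, `energy` (and optionally `max_cluster_size`) carrying
#'   the per-run table as `attr(, "runs")` and the configuration as
#'   `attr(, "config")`.
#' @export
simulate_ensemble <- function(config, n_realizations, base_seed = config$seed,
                              halt_on_assembly = TRUE,
                              record_cluster_sizes = FALSE) {
  stopifnot(n_realizations >= 1)
  runs <- purrr::map(seq_len(n_realizations), function(k) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + k - 1L)
    simulate_assembly(cfg, halt_on_assembly = halt_on_assembly,
                      record_cluster_sizes = record_cluster_sizes)
  })
  traj <- purrr::map2_dfr(runs, seq_along(runs), function(r, k) {
    dplyr::mutate(r$trajectory, realization = k, .before = 1L)
  })
  run_tbl <- tibble::tibble(
    realization = seq_len(n_realizations),
    seed = as.integer(base_seed + seq_len(n_realizations) - 1L),
    t_fas = purrr::map_dbl(runs, "t_fas"),
    assembled = purrr::map_lgl(runs, "assembled")
  )
  new_assembly_ensemble(traj, run_tbl, config)
}

new_assembly_ensemble <- function(trajectories, runs, config) {
  structure(
    trajectories,
    runs = runs,
    config = config,
    class = c("assembly_ensemble", class(tibble::tibble()))
  )
}

#' Per-run metadata of an ensemble
#'
#' @param x An `assembly_ensemble`.
#' @return A tibble with `realization`, `seed`, `t_fas`, `assembled`.
#' @export
ensemble_runs <- function(x) {
  r <- attr(x, "runs")
  if (is.null(r)) stop("not an assembly_ensemble: missing runs attribute")
  r
}

#' Configuration of an ensemble
#'
#' @param x An `assembly_ensemble`.
#' @return The [sim_config()] (or config-like list) the ensemble was run with.
#' @export
ensemble_config <- function(x) {
  cfg <- attr(x, "config")
  if (is.null(cfg)) stop("not an assembly_ensemble: missing config attribute")
  cfg
}

#' First-assembly-time summary of an ensemble
#'
#' Median and first/third quartiles of `t_fas` over the assembled runs (the
#' whisker convention of the study's box summaries).
#'
#' @param x An `assembly_ensemble`.
#' @return A one-row tibble.
#' @export
tfas_summary <- function(x) {
  runs <- ensemble_runs(x)
  tf <- runs$t_fas[runs$assembled]
  tibble::tibble(
    n_realizations = nrow(runs),
    n_assembled = sum(runs$assembled),
    median_t_fas = if (length(tf)) stats::median(tf) else NA_real_,
    q1_t_fas = if (length(tf)) unname(stats::quantile(tf, 0.25)) else NA_real_,
    q3_t_fas = if (length(tf)) unname(stats::quantile(tf, 0.75)) else NA_real_
  )
}

#' Microstate census under the simulated dynamics
#'
#' Runs the full two-sub-step dynamics from `init` and counts the microstate
#' (all particle sites and internal states) visited after every iteration.
#' Intended for small systems where the stationary distribution can be
#' enumerated exactly and compared against the empirical occupation.
#'
#' @param init Initial [lattice_state()].
#' @param targets A [target_set()].
#' @param params An [interaction_params()].
#' @param n_iter Number of counted iterations.
#' @param dynamics `"SPMC"` or `"VMMC"`.
#' @param dmu Drive magnitude.
#' @param burn_in Iterations discarded before counting.
#' @param freeze_positions Skip the physical move (state switches only).
#' @param seed Integer seed.
#' @return A tibble with columns `site_1..site_N` (0-based lattice sites),
#'   `state_1..state_N` and `count`, one row per visited microstate.
#' @export
state_census <- function(init, targets, params, n_iter,
                         dynamics = c("SPMC", "VMMC"), dmu = 0, burn_in = 0,
                         freeze_positions = FALSE, seed = 1) {
  dynamics <- match.arg(dynamics)
  ma <- model_args(targets, params, init$lattice)
  counts <- do.call(.cpp_census, c(ma, state_args(init), list(
    n_iter = as.double(n_iter), burn_in = as.double(burn_in),
    vmmc = dynamics == "VMMC", dmu = dmu,
    freeze_positions = freeze_positions, seed = as.double(seed)
  )))
  n <- init$n_particles
  base <- init$lattice^2 * targets$n_targets
  idx <- which(counts > 0) - 1
  dec <- matrix(0L, length(idx), 2L * n)
  rem <- idx
  for (i in rev(seq_len(n))) {
    code <- rem %% base
    rem <- rem %/% base
    dec[, i] <- as.integer(code %/% targets$n_targets)        # site
    dec[, n + i] <- as.integer(code %% targets$n_targets) + 1L # state
  }
  out <- tibble::as_tibble(as.data.frame(dec))
  names(out) <- c(paste0("site_", seq_len(n)), paste0("state_", seq_len(n)))
  out$count <- counts[idx + 1]
  out
}
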