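#' Synthetic labelled trajectory ensemble
#'
#' Generates piecewise-constant-plus-noise energy trajectories with known
#' changepoints and known first-assembly times, exercising every stage of the
#' stochastic landscape method without running the simulator. Each trajectory
#' descends through `n_segments` plateaus; the plateau level `e` maps
#' monotonically to the remaining time to assembly via
#' `remaining(e) = base_remaining * growth^(e / |level_step|)`, so the log
#' remaining time is (up to rounding and a per-trajectory level jitter) an
#' exact affine function of the segment mean — the deterministic fixture a
#' landscape must recover. With `noise_sd = 0` the changepoints are exactly
#' recoverable.
#'
#' @param n_trajectories Number of trajectories.
#' @param n_segments Plateaus per trajectory.
#' @param noise_sd Gaussian noise added to the plateau level.
#' @param level_step Plateau level decrement (negative; plateau `k` sits at
#'   `level_step * k`, scaled by the per-trajectory jitter).
#' @param base_remaining Remaining time (samples) at level 0.
#' @param growth Geometric factor of the level-to-remaining-time map.
#' @param level_jitter Log-normal sd of the per-trajectory level multiplier
#'   (0 makes all trajectories identical).
#' @param seed Optional integer seed.
#' @return An `assembly_ensemble` (binning factor 1, all runs assembled) with
#'   the true changepoints attached as `attr(, "truth")`.
#' @export
slm_synthetic_ensemble <- function(n_trajectories, n_segments = 6,
                                   noise_sd = 0.5, level_step = -10,
                                   base_remaining = 2000, growth = 2,
                                   level_jitter = 0.1, seed = NULL) {
  stopifnot(n_trajectories >= 1, n_segments >= 1, level_step < 0, growth > 1)
  with_seed(seed, {
    per_run <- purrr::map(seq_len(n_trajectories), function(i) {
      a <- exp(stats::rnorm(1, 0, level_jitter))
      k <- seq_len(n_segments)
      levels <- level_step * k * a
      remaining <- base_remaining * growth^(levels / abs(level_step))
      durations <- pmax(round(-diff(c(remaining, 0))), 4)
      # re-derive the realized remaining times after rounding
      remaining <- rev(cumsum(rev(durations)))
      t_fas <- remaining[1L]
      starts <- cumsum(c(1, durations[-n_segments]))
      energy <- rep(levels, durations) + stats::rnorm(t_fas, 0, noise_sd)
      list(
        trajectory = tibble::tibble(
          realization = i, sweep = seq_len(t_fas), mc_step = seq_len(t_fas),
          energy = energy
        ),
        run = tibble::tibble(realization = i, seed = NA_integer_,
                             t_fas = t_fas, assembled = TRUE),
        truth = tibble::tibble(realization = i, segment = k, start = starts,
                               level = levels, remaining = remaining)
      )
    })
    cfg <- list(n_particles = NA_integer_, lattice = NA_integer_,
                n_targets = NA_integer_, js = NA_real_, jw = NA_real_,
                dmu = NA_real_, dynamics = "synthetic", mode = "synthetic",
                n_steps = NA_real_, bin = 1, seed = seed %||% NA_integer_)
    out <- new_assembly_ensemble(
      purrr::map_dfr(per_run, "trajectory"),
      purrr::map_dfr(per_run, "run"),
      cfg
    )
    attr(out, "truth") <- purrr::map_dfr(per_run, "truth")
    out
  })
}
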