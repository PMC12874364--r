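#' Survivor-average energy trajectory
#'
#' Mean energy per sweep over the trajectories whose first assembly has not
#' yet occurred before that sweep: a trajectory contributes up to and
#' including its own assembly sweep and is dropped afterwards. The series
#' ends when no survivors remain.
#'
#' @param ensemble An `assembly_ensemble`; non-assembled runs are removed and
#'   assembled runs truncated first.
#' @return A tibble with `sweep`, `e_avg`, `n_survivors`.
#' @export
survivor_average <- function(ensemble) {
  prep <- slm_truncate(ensemble)
  runs <- ensemble_runs(prep)
  cfg <- ensemble_config(prep)
  fas_sweep <- stats::setNames(runs$t_fas / cfg$bin, runs$realization)
  tibble::as_tibble(prep) |>
    dplyr::filter(.data$sweep <= fas_sweep[as.character(.data$realization)]) |>
    dplyr::summarise(e_avg = mean(.data$energy), n_survivors = dplyr::n(),
                     .by = "sweep") |>
    dplyr::arrange(.data$sweep)
}

#' Per-trajectory RMSD from the survivor-average trajectory
#'
#' Root-mean-square deviation of each assembled energy trajectory from the
#' ensemble's survivor-average trajectory, taken over the sweeps up to that
#' trajectory's own first-assembly time. Where the survivor average is
#' undefined (no survivors remain) its last defined value is carried forward;
#' the number of carried sweeps is reported.
#'
#' @param ensemble An `assembly_ensemble`.
#' @param e_avg Optional precomputed [survivor_average()] table.
#' @return A tibble with `realization`, `t_fas`, `rmsd`, `n_carried`.
#' @export
trajectory_rmsd <- function(ensemble, e_avg = NULL) {
  prep <- slm_truncate(ensemble)
  runs <- ensemble_runs(prep)
  cfg <- ensemble_config(prep)
  if (is.null(e_avg)) e_avg <- survivor_average(prep)
  avg <- rep(NA_real_, max(runs$t_fas) / cfg$bin)
  avg[e_avg$sweep] <- e_avg$e_avg
  # carry the last defined value forward
  n_defined <- max(e_avg$sweep)
  if (n_defined < length(avg))
    avg[(n_defined + 1):length(avg)] <- avg[n_defined]
  traj <- tibble::as_tibble(prep)
  purrr::map_dfr(runs$realization, function(k) {
    tf_sweep <- runs$t_fas[runs$realization == k] / cfg$bin
    y <- traj$energy[traj$realization == k]
    ref <- avg[seq_len(tf_sweep)]
    tibble::tibble(
      realization = k,
      t_fas = runs$t_fas[runs$realization == k],
      rmsd = sqrt(mean((y - ref)^2)),
      n_carried = max(0L, as.integer(tf_sweep) - n_defined)
    )
  })
}

#' Spread of first-assembly times
#'
#' Sample standard deviation of `t_fas` over the assembled runs.
#'
#' @param ensemble An `assembly_ensemble` (or a numeric vector of
#'   first-assembly times).
#' @return sigma(T_FAS) in MC steps.
#' @export
tfas_spread <- function(ensemble) {
  tf <- if (is.numeric(ensemble)) ensemble else {
    runs <- ensemble_runs(ensemble)
    runs$t_fas[runs$assembled]
  }
  if (length(tf) < 2)
    stop("need at least 2 assembled trajectories for a spread")
  stats::sd(tf)
}

#' Fit the first-assembly-time distribution
#'
#' Maximum-likelihood log-normal fit (via fitdistrplus) alongside a kernel
#' density estimate (Gaussian kernel, nrd0 bandwidth), both reported only up
#' to the highest observed value — no extrapolation beyond the data.
#'
#' @param tfas Positive numeric vector of first-assembly times (>= 5 values).
#' @return An object of class `tfas_fit` with elements `meanlog`, `sdlog`,
#'   `kde` (a tibble `t`, `density`), `n`, `degenerate`.
#' @export
fit_tfas <- function(tfas) {
  tfas <- tfas[!is.na(tfas)]
  if (length(tfas) < 5) stop("need at least 5 first-assembly times")
  if (any(tfas <= 0)) stop("first-assembly times must be positive")
  degenerate <- stats::sd(tfas) == 0
  if (degenerate) {
    meanlog <- log(tfas[1]); sdlog <- 0
    kde <- tibble::tibble(t = tfas[1], density = Inf)
  } else {
    fit <- fitdistrplus::fitdist(tfas, "lnorm")
    meanlog <- unname(fit$estimate["meanlog"])
    sdlog <- unname(fit$estimate["sdlog"])
    d <- stats::density(tfas, from = min(tfas), to = max(tfas))
    kde <- tibble::tibble(t = d$x, density = d$y)
  }
  structure(
    list(meanlog = meanlog, sdlog = sdlog, kde = kde, n = length(tfas),
         degenerate = degenerate, t_max = max(tfas), t_min = min(tfas)),
    class = "tfas_fit"
  )
}

#' @export
print.tfas_fit <- function(x, ...) {
  cat(sprintf(
    "<tfas_fit> n = %d, log-normal meanlog = %.4g, sdlog = %.4g%s\n",
    x$n, x$meanlog, x$sdlog, if (x$degenerate) " (degenerate)" else ""
  ))
  invisible(x)
}

#' Predictability versus inverse variability
#'
#' Pearson correlation (and regression line) between the landscape-derived
#' predictability metric R of several simulation configurations and the
#' inverse of a variability metric (RMSD or sigma(T_FAS)) of the same
#' configurations: high trajectory variability should go with low
#' predictability, so the correlation with the inverse metric is expected to
#' be positive.
#'
#' @param r Vector of Pearson R values, one per configuration (length >= 3).
#' @param variability Matching vector of variability values (inverted before
#'   correlating).
#' @return A one-row tibble with `pearson_r`, `slope`, `intercept`, `n`
#'   (`pearson_r` is `NA` when either side has zero variance).
#' @export
predictability_correlation <- function(r, variability) {
  ok <- is.finite(r) & is.finite(variability) & variability != 0
  r <- r[ok]; v <- 1 / variability[ok]
  if (length(r) < 3) stop("need at least 3 paired configurations")
  if (stats::sd(r) == 0 || stats::sd(v) == 0) {
    return(tibble::tibble(pearson_r = NA_real_, slope = NA_real_,
                          intercept = NA_real_, n = length(r)))
  }
  fit <- stats::lm(r ~ v)
  tibble::tibble(
    pearson_r = stats::cor(r, v),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n = length(r)
  )
}
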