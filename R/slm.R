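#' Prepare trajectories for the stochastic landscape method
#'
#' Keeps only realizations that assembled and truncates each at its
#' first-assembly sweep; trajectories without an assembly event carry no
#' remaining-time label and are excluded from the analysis.
#'
#' @param ensemble An `assembly_ensemble`.
#' @return The filtered, truncated `assembly_ensemble`.
#' @export
slm_truncate <- function(ensemble) {
  runs <- ensemble_runs(ensemble)
  cfg <- ensemble_config(ensemble)
  keep <- runs[runs$assembled, ]
  if (!nrow(keep))
    stop("no assembled trajectories: every run lacks a first-assembly event")
  cutoff <- stats::setNames(keep$t_fas / cfg$bin, keep$realization)
  traj <- tibble::as_tibble(ensemble) |>
    dplyr::filter(.data$realization %in% keep$realization) |>
    dplyr::filter(.data$sweep <= cutoff[as.character(.data$realization)])
  new_assembly_ensemble(traj, keep, cfg)
}

#' Segment an ensemble and label each segment
#'
#' Runs [segment_series()] on every (truncated) energy trajectory and labels
#' each segment with its remaining time to first assembly: the difference
#' between the first-assembly MC step and the segment's onset step, stored
#' both raw and as `log_remaining = log10(remaining)`.
#'
#' @param ensemble A prepared `assembly_ensemble` (see [slm_truncate()]);
#'   unprepared ensembles are truncated first.
#' @inheritParams segment_series
#' @return A tibble of labelled segments: `realization`, `segment`, `start`,
#'   `end`, `n`, `mean`, `sd`, `trend`, `onset`, `remaining`, `log_remaining`,
#'   `t_fas`.
#' @export
slm_segments <- function(ensemble, min_size = 3, penalty = NULL,
                         pen_scale = 6, backend = NULL) {
  prep <- slm_truncate(ensemble)
  runs <- ensemble_runs(prep)
  cfg <- ensemble_config(prep)
  traj <- tibble::as_tibble(prep)
  purrr::map_dfr(runs$realization, function(k) {
    y <- traj$energy[traj$realization == k]
    if (length(y) < 2) return(NULL)
    tf <- runs$t_fas[runs$realization == k]
    segment_series(y, min_size = min_size, penalty = penalty,
                   pen_scale = pen_scale, backend = backend) |>
      dplyr::mutate(
        realization = k, .before = 1L
      ) |>
      dplyr::mutate(
        onset = .data$start * cfg$bin,
        remaining = tf - .data$onset,
        log_remaining = log10(.data$remaining),
        t_fas = tf
      ) |>
      dplyr::filter(.data$remaining > 0)
  })
}

# Core landscape fit (no bias correction): standardise the coordinates on the
# training segments, partition each standardised axis into n_cells fixed-width
# cells, and store the per-cell median log10 remaining time.
fit_landscape_core <- function(segments, n_cells) {
  co <- as.matrix(segments[, c("mean", "sd", "trend")])
  center <- colMeans(co)
  scale <- apply(co, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  z <- sweep(sweep(co, 2, center), 2, scale, "/")
  ax_min <- apply(z, 2, min)
  ax_max <- apply(z, 2, max)
  width <- (ax_max - ax_min) / n_cells
  width[width == 0] <- 1
  idx <- cell_index(z, ax_min, width, n_cells)
  cells <- tibble::tibble(
    c1 = idx[, 1], c2 = idx[, 2], c3 = idx[, 3],
    value = segments$log_remaining
  ) |>
    dplyr::summarise(value = stats::median(.data$value), n = dplyr::n(),
                     .by = c("c1", "c2", "c3"))
  list(center = center, scale = scale, axis_min = ax_min, axis_max = ax_max,
       width = width, n_cells = n_cells, cells = cells,
       global_median = stats::median(segments$log_remaining))
}

cell_index <- function(z, ax_min, width, n_cells) {
  idx <- sweep(sweep(z, 2, ax_min), 2, width, "/")
  idx <- floor(idx) + 1
  idx[] <- pmin(pmax(idx, 1), n_cells)
  storage.mode(idx) <- "integer"
  idx
}

# Raw (uncorrected) landscape prediction for a segment table.
predict_raw <- function(core, segments) {
  co <- as.matrix(segments[, c("mean", "sd", "trend")])
  z <- sweep(sweep(co, 2, core$center), 2, core$scale, "/")
  idx <- cell_index(z, core$axis_min, core$width, core$n_cells)
  cells <- core$cells
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  ckey <- paste(cells$c1, cells$c2, cells$c3)
  hit <- match(key, ckey)
  out <- cells$value[hit]
  miss <- which(is.na(hit))
  if (length(miss)) {
    # nearest non-empty cell by centre distance in standardised units
    centers <- cbind(
      core$axis_min[1] + (cells$c1 - 0.5) * core$width[1],
      core$axis_min[2] + (cells$c2 - 0.5) * core$width[2],
      core$axis_min[3] + (cells$c3 - 0.5) * core$width[3]
    )
    qcent <- cbind(
      core$axis_min[1] + (idx[miss, 1] - 0.5) * core$width[1],
      core$axis_min[2] + (idx[miss, 2] - 0.5) * core$width[2],
      core$axis_min[3] + (idx[miss, 3] - 0.5) * core$width[3]
    )
    for (q in seq_along(miss)) {
      d2 <- colSums((t(centers) - qcent[q, ])^2)
      out[miss[q]] <- cells$value[which.min(d2)]
    }
  }
  out[!is.finite(out)] <- core$global_median
  out
}

#' Fit a stochastic landscape
#'
#' Builds the predictive map from labelled training segments: coordinates are
#' standardised on the training set, each standardised axis is partitioned
#' into `n_cells` fixed-width cells, and each populated cell stores the median
#' `log10` remaining time of its training segments. Queries falling in empty
#' cells fall back to the nearest populated cell, then to the global median.
#' A per-bin additive bias correction is estimated by `bias_reps` random
#' train/cross-validation splits of the training segments: raw log predictions
#' on the held-out part are binned (width `bin_width`), the median signed
#' error `Y - Yhat` is recorded per bin, and the corrections are averaged
#' across repetitions.
#'
#' @param segments Labelled segments from [slm_segments()].
#' @param n_cells Cells per standardised axis (default 8, coarse enough for
#'   a few hundred training trajectories).
#' @param bias_reps Number of bias-correction repetitions (default 10).
#' @param bin_width Width of the log10 prediction bins (default 0.5).
#' @param cv_fraction Fraction of segments held out per bias repetition.
#' @param seed Optional integer seed for the bias-correction splits.
#' @return An object of class `slm_landscape`.
#' @export
slm_landscape <- function(segments, n_cells = 8, bias_reps = 10,
                          bin_width = 0.5, cv_fraction = 0.2, seed = NULL) {
  if (!nrow(segments)) stop("no labelled segments to fit on")
  core <- fit_landscape_core(segments, n_cells)
  bias <- slm_bias_correction(segments, n_cells = n_cells,
                              bias_reps = bias_reps, bin_width = bin_width,
                              cv_fraction = cv_fraction, seed = seed)
  tf <- dplyr::distinct(segments, .data$realization, .data$t_fas)$t_fas
  structure(
    c(core, list(
      bias = bias, bin_width = bin_width,
      baseline = log10(stats::median(tf)),
      n_segments = nrow(segments)
    )),
    class = "slm_landscape"
  )
}

#' Bias-correction vector
#'
#' The per-bin additive correction described in [slm_landscape()], exposed for
#' inspection: repeated random splits of the training segments, a refit on
#' each training part, binned median signed errors on the held-out part,
#' averaged across repetitions. Bins never populated get correction 0.
#'
#' @inheritParams slm_landscape
#' @return A tibble with `bin` (index: floor(prediction / bin_width)),
#'   `correction`, `n_reps`.
#' @export
slm_bias_correction <- function(segments, n_cells = 8, bias_reps = 10,
                                bin_width = 0.5, cv_fraction = 0.2,
                                seed = NULL) {
  n <- nrow(segments)
  if (n < 5) {
    return(tibble::tibble(bin = integer(), correction = double(),
                          n_reps = integer()))
  }
  with_seed(seed, {
    per_rep <- purrr::map_dfr(seq_len(bias_reps), function(rep) {
      cv <- sample.int(n, max(1L, round(cv_fraction * n)))
      train <- segments[-cv, , drop = FALSE]
      test <- segments[cv, , drop = FALSE]
      if (!nrow(train)) return(NULL)
      core <- fit_landscape_core(train, n_cells)
      pred <- predict_raw(core, test)
      tibble::tibble(
        bin = as.integer(floor(pred / bin_width)),
        err = test$log_remaining - pred
      ) |>
        dplyr::summarise(med = stats::median(.data$err), .by = "bin")
    })
    if (!nrow(per_rep)) {
      return(tibble::tibble(bin = integer(), correction = double(),
                            n_reps = integer()))
    }
    dplyr::summarise(per_rep, correction = mean(.data$med),
                     n_reps = dplyr::n(), .by = "bin") |>
      dplyr::arrange(.data$bin)
  })
}

#' @export
print.slm_landscape <- function(x, ...) {
  cat(sprintf(
    "<slm_landscape> %d training segments, %d^3 cells (%d populated), baseline log10 T_FAS = %.3f\n",
    x$n_segments, x$n_cells, nrow(x$cells), x$baseline
  ))
  invisible(x)
}

#' Predict remaining time to first assembly
#'
#' Applies a fitted landscape to new labelled segments: raw prediction
#' `y_raw`, bias-corrected prediction `y_bc = y_raw + correction(bin(y_raw))`,
#' and the naive baseline `y_baseline` (the log10 median first-assembly time
#' of the training set, a constant). All values are log10 MC steps. The
#' attached summary holds the Pearson correlation between actual and
#' bias-corrected values and per-bin median absolute errors for the landscape
#' and the baseline.
#'
#' @param object An `slm_landscape`.
#' @param segments Labelled segments (from [slm_segments()]).
#' @param ... Unused.
#' @return An `slm_prediction`: a tibble with one row per segment and
#'   attributes `r`, `bin_errors`.
#' @export
predict.slm_landscape <- function(object, segments, ...) {
  y_raw <- predict_raw(object, segments)
  bin <- as.integer(floor(y_raw / object$bin_width))
  corr <- object$bias$correction[match(bin, object$bias$bin)]
  corr[is.na(corr)] <- 0
  out <- tibble::tibble(
    realization = segments$realization,
    segment = segments$segment,
    y = segments$log_remaining,
    y_raw = y_raw,
    y_bc = y_raw + corr,
    y_baseline = object$baseline
  )
  r <- NA_real_
  ok <- is.finite(out$y) & is.finite(out$y_bc)
  if (sum(ok) >= 2 && stats::sd(out$y[ok]) > 0 && stats::sd(out$y_bc[ok]) > 0)
    r <- stats::cor(out$y[ok], out$y_bc[ok])
  bin_errors <- out |>
    dplyr::mutate(bin = as.integer(floor(.data$y_bc / object$bin_width))) |>
    dplyr::summarise(
      n = dplyr::n(),
      err_slm = stats::median(abs(.data$y - .data$y_bc)),
      err_baseline = stats::median(abs(.data$y - .data$y_baseline)),
      .by = "bin"
    ) |>
    dplyr::arrange(.data$bin)
  structure(out, r = r, bin_errors = bin_errors, baseline = object$baseline,
            class = c("slm_prediction", class(tibble::tibble())))
}

#' Pearson correlation of a prediction
#'
#' @param x An `slm_prediction`.
#' @return The Pearson R between actual and bias-corrected log10 remaining
#'   times (`NA` when undefined, e.g. a single test segment).
#' @export
prediction_r <- function(x) {
  r <- attr(x, "r")
  if (is.null(r)) stop("not an slm_prediction")
  r
}

#' Per-bin prediction errors
#'
#' @param x An `slm_prediction`.
#' @return A tibble with `bin`, `n`, `err_slm`, `err_baseline` (median
#'   absolute errors of the bias-corrected landscape and the constant
#'   median baseline per log10 prediction bin).
#' @export
prediction_bin_errors <- function(x) {
  be <- attr(x, "bin_errors")
  if (is.null(be)) stop("not an slm_prediction")
  be
}

#' End-to-end landscape evaluation of one simulation configuration
#'
#' The full pipeline on one ensemble: truncate at first assembly, segment,
#' split the assembled trajectories into training and held-out test sets
#' (default 80/20, the study's 640/160 split scaled to the ensemble size),
#' fit the landscape with bias correction on the training segments, and
#' predict the held-out segments.
#'
#' @param ensemble An `assembly_ensemble`.
#' @param test_fraction Fraction of assembled trajectories held out.
#' @param n_cells,bias_reps,bin_width Landscape settings, see
#'   [slm_landscape()].
#' @param min_size,penalty,pen_scale Segmentation settings, see
#'   [segment_series()].
#' @param seed Optional integer seed (split + bias correction).
#' @param shuffle_labels Permute the remaining-time labels across segments
#'   before fitting and testing (a permutation null for the correlation).
#' @return An `slm_prediction` with the fitted landscape attached as
#'   `attr(, "landscape")`.
#' @export
slm_evaluate <- function(ensemble, test_fraction = 0.2, n_cells = 8,
                         bias_reps = 10, bin_width = 0.5, min_size = 3,
                         penalty = NULL, pen_scale = 6, seed = NULL,
                         shuffle_labels = FALSE) {
  prep <- slm_truncate(ensemble)
  runs <- ensemble_runs(prep)
  n <- nrow(runs)
  n_test <- max(1L, round(test_fraction * n))
  if (n - n_test < 1L)
    stop(sprintf("insufficient assembled trajectories: %d available, need at least %d",
                 n, n_test + 1L))
  segs <- slm_segments(prep, min_size = min_size, penalty = penalty,
                       pen_scale = pen_scale)
  with_seed(seed, {
    if (shuffle_labels) {
      perm <- sample.int(nrow(segs))
      segs$remaining <- segs$remaining[perm]
      segs$log_remaining <- segs$log_remaining[perm]
    }
    test_ids <- sample(runs$realization, n_test)
    train_segs <- segs[!segs$realization %in% test_ids, , drop = FALSE]
    test_segs <- segs[segs$realization %in% test_ids, , drop = FALSE]
    if (!nrow(train_segs) || !nrow(test_segs))
      stop("train/test split left one side empty")
    land <- slm_landscape(train_segs, n_cells = n_cells, bias_reps = bias_reps,
                          bin_width = bin_width)
    pred <- predict(land, test_segs)
    attr(pred, "landscape") <- land
    pred
  })
}
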