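#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @export
tidy.assembly_run <- function(x, ...) x$trajectory

#' @export
glance.assembly_run <- function(x, ...) {
  tibble::tibble(
    dynamics = x$config$dynamics, mode = x$config$mode,
    dmu = x$config$dmu, js = x$config$js, seed = x$config$seed,
    n_sweeps = nrow(x$trajectory), assembled = x$assembled,
    t_fas = x$t_fas, threshold = x$threshold,
    final_energy = x$final_state$energy
  )
}

#' @export
glance.assembly_ensemble <- function(x, ...) {
  cfg <- ensemble_config(x)
  dplyr::bind_cols(
    tibble::tibble(dynamics = cfg$dynamics, mode = cfg$mode, dmu = cfg$dmu),
    tfas_summary(x)
  )
}

#' @export
tidy.slm_landscape <- function(x, ...) x$cells

#' @export
glance.slm_landscape <- function(x, ...) {
  tibble::tibble(
    n_segments = x$n_segments, n_cells_axis = x$n_cells,
    n_cells_populated = nrow(x$cells), global_median = x$global_median,
    baseline_log10_tfas = x$baseline, n_bias_bins = nrow(x$bias)
  )
}

#' @export
tidy.slm_prediction <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.slm_prediction <- function(x, ...) {
  be <- prediction_bin_errors(x)
  tibble::tibble(
    n_segments = nrow(x),
    pearson_r = prediction_r(x),
    median_abs_err_slm = stats::median(abs(x$y - x$y_bc)),
    median_abs_err_baseline = stats::median(abs(x$y - x$y_baseline)),
    n_bins = nrow(be)
  )
}

#' @export
tidy.tfas_fit <- function(x, ...) {
  tibble::tibble(
    term = c("meanlog", "sdlog"),
    estimate = c(x$meanlog, x$sdlog)
  )
}

#' @export
glance.tfas_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, meanlog = x$meanlog, sdlog = x$sdlog,
    median_t_fas = exp(x$meanlog), degenerate = x$degenerate
  )
}
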