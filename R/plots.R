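#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot one energy trajectory
#'
#' Sampled energy versus MC step with the assembled-energy threshold marked.
#'
#' @param object An `assembly_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.assembly_run <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$mc_step, y = .data$energy)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "MC step", y = "Energy (kT)",
                  title = sprintf("%s/%s, dmu = %g", object$config$dynamics,
                                  object$config$mode, object$config$dmu)) +
    ggplot2::theme_minimal()
}

#' Plot an ensemble of energy trajectories
#'
#' Spaghetti plot of all realizations with the per-sweep median overlaid.
#'
#' @param object An `assembly_ensemble`.
#' @param alpha Line transparency for individual runs.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.assembly_ensemble <- function(object, alpha = 0.25, ...) {
  df <- tibble::as_tibble(object)
  med <- dplyr::summarise(df, energy = stats::median(.data$energy),
                          .by = "mc_step")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mc_step, y = .data$energy)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$realization),
                       alpha = alpha, colour = "grey40") +
    ggplot2::geom_line(data = med, colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "MC step", y = "Energy (kT)") +
    ggplot2::theme_minimal()
}

#' Plot predicted versus actual remaining times
#'
#' Raw (grey) and bias-corrected (black) log10 predictions against the
#' measured log10 remaining time, with the identity line.
#'
#' @param object An `slm_prediction`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.slm_prediction <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$y_raw), colour = "grey60",
                        size = 1) +
    ggplot2::geom_point(ggplot2::aes(x = .data$y_bc), colour = "black",
                        size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "red") +
    ggplot2::labs(
      x = "Predicted log10 remaining time",
      y = "Measured log10 remaining time",
      title = sprintf("Pearson R = %.3f", prediction_r(object))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a first-assembly-time distribution fit
#'
#' Histogram of the observed times with the kernel density estimate and the
#' log-normal fit overlaid, truncated at the highest observed value.
#'
#' @param object A `tfas_fit`.
#' @param tfas Optional raw values to histogram underneath the fits.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tfas_fit <- function(object, tfas = NULL, ...) {
  grid <- tibble::tibble(
    t = seq(object$t_min, object$t_max, length.out = 256)
  )
  grid$lnorm <- stats::dlnorm(grid$t, object$meanlog, object$sdlog)
  p <- ggplot2::ggplot()
  if (!is.null(tfas)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(t = tfas),
      ggplot2::aes(x = .data$t, y = ggplot2::after_stat(density)),
      bins = 30, fill = "grey85", colour = "grey60"
    )
  }
  p +
    ggplot2::geom_line(data = object$kde,
                       ggplot2::aes(x = .data$t, y = .data$density),
                       colour = "steelblue") +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$t, y = .data$lnorm),
                       colour = "firebrick", linetype = "dashed") +
    ggplot2::labs(x = "First-assembly time (MC steps)", y = "Density") +
    ggplot2::theme_minimal()
}
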