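#' Piecewise-linear trend segmentation
#'
#' Splits a series into contiguous, non-overlapping segments with distinct
#' statistical properties, each fitted with a linear trend. The built-in
#' backend is an exact penalized piecewise-linear least-squares fit solved by
#' dynamic programming (cost = per-segment SSE around the segment's own linear
#' fit + `penalty` per segment), which places no limit on the number of trend
#' change points. The default penalty is BIC-style,
#' `pen_scale * sigma^2 * log(n)`, with `sigma` estimated robustly from second
#' differences so that level shifts and slope changes do not inflate it. Any
#' alternative backend can be substituted through `backend`, a function
#' mapping a numeric series to 1-based segment start indices.
#'
#' @param y Numeric series (length >= 2).
#' @param min_size Minimum segment length in samples (>= 2 so that every
#'   segment supports a mean, a standard deviation and a slope).
#' @param penalty Per-segment penalty; estimated from the data when `NULL`.
#' @param pen_scale Multiplier of the BIC-style default penalty.
#' @param backend Optional replacement changepoint engine:
#'   `function(y, penalty, min_size) -> integer starts`.
#' @return A tibble with one row per segment: `segment`, `start`, `end`, `n`,
#'   and the stochastic coordinates `mean`, `sd`, `trend` (slope per sample).
#' @examples
#' y <- c(seq(50, 1, length.out = 50), rep(1, 50))
#' segment_series(y)
#' @export
segment_series <- function(y, min_size = 3, penalty = NULL, pen_scale = 6,
                           backend = NULL) {
  n <- length(y)
  if (n < 2) stop("series must have length >= 2")
  if (is.null(penalty)) {
    d2 <- diff(y, differences = 2)
    sigma <- if (length(d2) >= 3) stats::mad(d2) / sqrt(6) else 0
    sigma2 <- max(sigma^2, 1e-10 * max(stats::var(y), 0), 1e-12)
    penalty <- pen_scale * sigma2 * log(n)
  }
  starts <- if (is.null(backend)) {
    .cpp_segment_dp(as.double(y), penalty, as.integer(min_size)) + 1L
  } else {
    as.integer(backend(y, penalty, min_size))
  }
  ends <- c(starts[-1L] - 1L, n)
  purrr::map2_dfr(starts, ends, function(a, b) {
    co <- segment_coordinates(y[a:b])
    tibble::tibble(start = a, end = b, n = b - a + 1L,
                   mean = co[["mean"]], sd = co[["sd"]], trend = co[["trend"]])
  }) |>
    dplyr::mutate(segment = dplyr::row_number(), .before = 1L)
}

#' Stochastic coordinates of a segment
#'
#' Arithmetic mean, sample standard deviation and least-squares slope (per
#' sample) of the values inside one segment.
#'
#' @param values Numeric vector of at least 2 samples.
#' @return A named numeric vector `c(mean, sd, trend)`.
#' @export
segment_coordinates <- function(values) {
  n <- length(values)
  if (n < 2) stop("a segment needs at least 2 samples")
  x <- seq_len(n)
  sxx <- sum((x - mean(x))^2)
  c(mean = mean(values),
    sd = stats::sd(values),
    trend = sum((x - mean(x)) * (values - mean(values))) / sxx)
}
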