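#' First and second discrete derivatives of a time series
#'
#' Forward finite differences scaled by the sampling rate, so that derivative
#' features are interpretable as rates per second regardless of the camera
#' frame rate.
#'
#' @param series numeric vector, length `T >= 3`.
#' @param fps sampling rate in frames per second (default 1, i.e. unit step).
#' @return list with `d1` (length `T - 1`) and `d2` (length `T - 2`).
#' @export
#' @examples
#' derivatives(c(0, 1, 4, 9, 16))  # t^2: d2 constant 2
derivatives <- function(series, fps = 1) {
  series <- as.numeric(series)
  if (length(series) < 3)
    stop_arg("derivatives() needs a series of length >= 3, got %d",
             length(series))
  if (!is.numeric(fps) || fps <= 0) stop_arg("fps must be positive")
  d1 <- diff(series) * fps
  d2 <- diff(d1) * fps
  list(d1 = d1, d2 = d2)
}

#' Names of the 16 per-level descriptor statistics
#'
#' @return character vector of length 16, in the fixed descriptor order.
#' @export
stat_names <- function() {
  c("mean", "median", "sd", "min", "max", "range", "iqr", "p10", "p90",
    "reltmax", "reltmin", "rms", "mad", "area", "slope", "nlocmax")
}

#' Summary statistics of one time series
#'
#' Computes the fixed 16-statistic block used by the facial activity
#' descriptor: mean, median, standard deviation, minimum, maximum, range,
#' interquartile range, 10th and 90th percentiles, relative time of maximum
#' and of minimum (first occurrence, as `argmax/(T-1)`), root mean square,
#' mean absolute deviation from the mean, normalised trapezoidal area
#' (`trapz/(T-1)`), least-squares linear slope (per frame), and the count of
#' strict local maxima. Time-position statistics are defined as 0 for a
#' single-frame series.
#'
#' @param series numeric vector, length >= 1.
#' @return named numeric vector of length 16, in `stat_names()` order.
#' @export
#' @examples
#' series_stats(c(0, 1, 0))
series_stats <- function(series) {
  x <- as.numeric(series)
  n <- length(x)
  if (n == 0) stop_arg("series_stats() needs a non-empty series")
  if (anyNA(x)) stop_arg("series contains missing values")
  mu <- mean(x)
  qs <- if (n == 1) rep(x, 4) else quantile(x, c(0.25, 0.75, 0.10, 0.90),
                                            names = FALSE, type = 7)
  sdev <- if (n == 1) 0 else sd(x)
  reltmax <- if (n == 1) 0 else (which.max(x) - 1) / (n - 1)
  reltmin <- if (n == 1) 0 else (which.min(x) - 1) / (n - 1)
  area <- if (n == 1) x else sum((x[-1] + x[-n]) / 2) / (n - 1)
  slope <- if (n == 1) 0 else {
    t0 <- seq_len(n) - mean(seq_len(n))
    sum(t0 * (x - mu)) / sum(t0^2)
  }
  nlocmax <- if (n < 3) 0 else
    sum(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n])
  out <- c(mu, median(x), sdev, min(x), max(x), max(x) - min(x),
           qs[2] - qs[1], qs[3], qs[4], reltmax, reltmin,
           sqrt(mean(x^2)), mean(abs(x - mu)), area, slope, nlocmax)
  names(out) <- stat_names()
  out
}

#' Facial activity descriptor of one action-unit time series
#'
#' The 48-dimensional descriptor summarising a single AU intensity series:
#' the series is smoothed, its first and second forward-difference
#' derivatives are taken, and the 16 statistics of [series_stats()] are
#' computed at each of the three levels (series, first derivative, second
#' derivative) and concatenated. Smoothing is applied once, before
#' differentiation, so level-1/2 statistics describe the smoothed signal's
#' dynamics.
#'
#' @param series numeric vector, length >= 3.
#' @param fps frames per second used to scale the derivatives.
#' @param smooth_window odd moving-average window in frames (default 5);
#'   1 disables smoothing.
#' @return named numeric vector of length 48 (`L0_*`, `L1_*`, `L2_*`).
#' @seealso [sample_features()] for the full 17-AU, 816-component vector.
#' @export
fad_descriptor <- function(series, fps = 1, smooth_window = 5) {
  x <- smooth_series(series, smooth_window)
  if (length(x) < 3) stop_arg("fad_descriptor() needs >= 3 frames")
  d <- derivatives(x, fps)
  out <- c(series_stats(x), series_stats(d$d1), series_stats(d$d2))
  names(out) <- paste0(rep(c("L0", "L1", "L2"), each = 16), "_", names(out))
  out
}

#' Full feature vector of a sample: 17 AUs x 48 statistics
#'
#' Applies [fad_descriptor()] to each of the 17 canonical AU rows of a
#' sample and concatenates the results in canonical AU order, yielding the
#' 816-component vector used by the random-forest classifier.
#'
#' @param sample an `au_sample` (see [generate_sample()]) or a bare 17-row
#'   numeric matrix of AU intensities.
#' @param fps frames per second; taken from the sample when available.
#' @param smooth_window smoothing window passed to [fad_descriptor()].
#' @return named numeric vector of length 816 (`AU01_L0_mean`, ...).
#' @export
sample_features <- function(sample, fps = NULL, smooth_window = 5) {
  series <- if (is.matrix(sample)) sample else sample$series
  fps <- fps %||% (if (is.matrix(sample)) 1 else sample$fps)
  if (!is.matrix(series) || nrow(series) != length(au_names()))
    stop_arg("sample series must be a %d-row AU matrix, got %s rows",
             length(au_names()),
             if (is.matrix(series)) nrow(series) else "non-matrix")
  blocks <- lapply(seq_len(nrow(series)), function(i)
    fad_descriptor(series[i, ], fps = fps, smooth_window = smooth_window))
  out <- unlist(blocks, use.names = FALSE)
  names(out) <- as.vector(t(outer(au_names(), names(blocks[[1]]),
                                  paste, sep = "_")))
  out
}

#' Feature matrix for a whole dataset
#'
#' @param dataset a `pain_dataset` from [generate_dataset()] or
#'   [read_dataset()].
#' @param smooth_window smoothing window passed to [fad_descriptor()].
#' @return numeric matrix, one row per sample (rownames = sample ids),
#'   816 named columns.
#' @export
dataset_features <- function(dataset, smooth_window = 5) {
  feats <- t(vapply(dataset$samples,
                    function(s) sample_features(s, smooth_window = smooth_window),
                    numeric(17 * 48)))
  rownames(feats) <- vapply(dataset$samples, `[[`, "", "sample_id")
  feats
}
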