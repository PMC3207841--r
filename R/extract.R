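# From tracked region to mean-temperature time series and stimulus windows.

#' Upper trimmed mean of a pixel sample
#'
#' Mean of the warmest `ceiling(N * fraction)` of `N` temperature values.
#' With the default `fraction = 0.5` this is the upper 50% trimmed mean: a
#' robust region statistic that discards the cooler half of the tracked
#' block, i.e. the border pixels that slip in and out of the region as the
#' tracker wobbles by a pixel or two, and keeps the warm perfused core.
#' Which of several equal-valued boundary pixels is included is irrelevant
#' to the result.
#'
#' @param pixels numeric vector of temperatures, K (non-empty).
#' @param fraction fraction retained, in `(0, 1]`.
#' @return trimmed mean, K.
#' @examples
#' trimmed_mean_upper(c(1, 2, 3, 4))  # 3.5
#' @export
trimmed_mean_upper <- function(pixels, fraction = 0.5) {
  if (length(pixels) == 0) pt_stop("trimmed_mean_upper: empty input")
  if (fraction <= 0 || fraction > 1)
    pt_stop("trimmed_mean_upper: fraction must be in (0, 1]")
  k <- ceiling(length(pixels) * fraction)
  mean(sort(pixels, decreasing = TRUE)[seq_len(k)])
}

#' Mean-temperature time series
#'
#' @param values temperatures, K, one per frame.
#' @param fs sampling rate, Hz.
#' @param side region label.
#' @param filtered has the series been low-pass filtered?
#' @return object of class `temperature_series`.
#' @export
temperature_series <- function(values, fs, side = "left", filtered = FALSE) {
  if (any(!is.finite(values)))
    pt_stop("temperature_series values must be finite")
  structure(list(values = as.numeric(values), fs = fs, side = side,
                 filtered = filtered),
            class = "temperature_series")
}

#' @export
print.temperature_series <- function(x, ...) {
  cat(sprintf("<temperature_series> side %s, %d samples @ %g Hz, %s (%.4f-%.4f K)\n",
              x$side, length(x$values), x$fs,
              if (x$filtered) "filtered" else "raw",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Extract the mean-temperature series from a tracked region
#'
#' For every tracked frame, takes the upper trimmed mean of the pixels
#' inside that frame's ROI, yielding the region's raw (unfiltered)
#' mean-temperature time series. `fraction = 1` gives the plain
#' (untrimmed) mean, available for diagnostics only.
#'
#' @param stack a [thermal_stack()].
#' @param track a non-failed [region_track()].
#' @param fraction passed to [trimmed_mean_upper()].
#' @return a [temperature_series()] of length
#'   `n_frames - start_frame + 1`.
#' @export
series_from_track <- function(stack, track, fraction = 0.5) {
  if (isTRUE(track$failed))
    stop(errorCondition(
      sprintf("cannot extract series: tracking failed at frame %d",
              track$failure_frame),
      failure_frame = track$failure_frame,
      class = c("periotherm_track_failure", "error", "condition")))
  n <- n_frames(stack)
  idx <- track$start_frame:n
  vals <- vapply(idx, function(f) {
    p <- track$pos[f, ]
    trimmed_mean_upper(block_at(stack$data[, , f], p[1], p[2],
                                track$height, track$width), fraction)
  }, numeric(1))
  temperature_series(vals, stack$fs, side = track$side, filtered = FALSE)
}

# internal: second-order Butterworth coefficients, bilinear design
butter_coeffs <- function(order = 2, cutoff = 2, fs = 15) {
  if (cutoff >= fs / 2)
    pt_stop("lowpass: cutoff must be below the Nyquist frequency")
  signal::butter(order, cutoff / (fs / 2))
}

#' Low-pass filter a temperature series
#'
#' Causal single-pass digital Butterworth filter (bilinear design; the
#' magnitude response at the cut-off frequency is -3 dB, and the DC gain
#' is exactly 1). The startup transient is suppressed by initialising the
#' filter at the steady state of the first sample: the deviation
#' `x - x[1]` is filtered from rest and `x[1]` is added back, which leaves
#' a constant series exactly unchanged.
#'
#' @param x a [temperature_series()] or a bare numeric vector.
#' @param fs sampling rate, Hz (taken from the series object if omitted).
#' @param order filter order.
#' @param cutoff cut-off frequency, Hz; must be below Nyquist.
#' @param ... unused.
#' @return same type as `x`, filtered.
#' @examples
#' lowpass(rep(300, 50), fs = 15)[1]  # 300, unchanged
#' @export
lowpass <- function(x, ...) UseMethod("lowpass")

#' @rdname lowpass
#' @export
lowpass.numeric <- function(x, fs, order = 2, cutoff = 2, ...) {
  bf <- butter_coeffs(order, cutoff, fs)
  x[1] + as.numeric(signal::filter(bf, x - x[1]))
}

#' @rdname lowpass
#' @export
lowpass.temperature_series <- function(x, fs = x$fs, order = 2, cutoff = 2,
                                       ...) {
  out <- x
  out$values <- lowpass.numeric(x$values, fs, order, cutoff)
  out$filtered <- TRUE
  out
}

#' Magnitude response of the low-pass filter
#'
#' Evaluates the designed filter's transfer function magnitude at given
#' frequencies.
#'
#' @param f frequencies, Hz.
#' @param fs sampling rate, Hz.
#' @param order,cutoff filter design parameters.
#' @return `|H(f)|`, same length as `f`.
#' @examples
#' 20 * log10(lowpass_gain(2, 15))  # -3.01 dB at the cut-off
#' @export
lowpass_gain <- function(f, fs = 15, order = 2, cutoff = 2) {
  bf <- butter_coeffs(order, cutoff, fs)
  vapply(f, function(fi) {
    w <- 2 * pi * fi / fs
    z <- exp(-1i * w * seq(0, length(bf$b) - 1))
    Mod(sum(bf$b * z) / sum(bf$a * z))
  }, numeric(1))
}

#' Cut pre- and post-stimulus windows from a series
#'
#' Extracts the two analysis windows abutting the stimulus: the pre window
#' covers `[t_stim - width, t_stim]` and the post window
#' `[t_stim, t_stim + width]`, both inclusive of their endpoints, so at
#' 15 Hz a 2 s window holds 31 samples and the sample nearest `t_stim`
#' belongs to both windows' shared boundary.
#'
#' @param series a [temperature_series()] (or numeric vector with `fs`
#'   supplied).
#' @param t_stim stimulus time, s; both windows must fit inside the series.
#' @param width window width, s.
#' @param fs sampling rate, Hz; defaults to the series' own.
#' @return A `window_pair`: list with `pre` and `post` sample vectors (K),
#'   `t_stim`, `n_samples` per window, and the 1-based index ranges
#'   `pre_idx`, `post_idx` (the sample at index `i` has time
#'   `(i - 1) / fs`).
#' @examples
#' s <- temperature_series(rep(307.5, 450), fs = 15)
#' wp <- extract_windows(s, t_stim = 15)
#' wp$pre_idx; wp$post_idx  # 196..226 and 226..256 (1-based)
#' @export
extract_windows <- function(series, t_stim, width = 2, fs = NULL) {
  if (inherits(series, "temperature_series")) {
    values <- series$values
    if (is.null(fs)) fs <- series$fs
  } else {
    values <- as.numeric(series)
    if (is.null(fs)) pt_stop("extract_windows: fs required for bare vectors")
  }
  if (is.na(t_stim)) pt_stop("extract_windows: t_stim is missing")
  nwin <- as.integer(round(width * fs))
  i_stim <- as.integer(round(t_stim * fs)) + 1L
  if (i_stim - nwin < 1 || i_stim + nwin > length(values))
    pt_stop("extract_windows: stimulus too close to the trial edge ",
            "(need ", width, " s on both sides)")
  structure(list(
    pre = values[(i_stim - nwin):i_stim],
    post = values[i_stim:(i_stim + nwin)],
    t_stim = t_stim, n_samples = nwin + 1L, i_stim = i_stim,
    pre_idx = c(i_stim - nwin, i_stim),
    post_idx = c(i_stim, i_stim + nwin)
  ), class = "window_pair")
}
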