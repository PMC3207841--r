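# Per-window summary statistics, entropy, and the two distributional tests.

#' Summary statistics of a stimulus window
#'
#' Range, mean, and the biased (1/n) central-moment variance, skewness
#' `m3 / m2^1.5` and Pearson kurtosis `m4 / m2^2` (normal = 3) of a window
#' of temperature samples. Constant windows have range and variance 0 and
#' undefined (NA) skewness and kurtosis, flagged via `degenerate`.
#'
#' @param window numeric vector of temperatures, K; at least 4 samples.
#' @return list of class `window_stats` with fields `range`, `mean`,
#'   `variance`, `skewness`, `kurtosis`, `degenerate`.
#' @examples
#' s <- summary_stats(c(1, 2, 3, 4, 5))
#' s$variance  # 2
#' s$kurtosis  # 1.7
#' @export
summary_stats <- function(window) {
  n <- length(window)
  if (n < 4) pt_stop("summary_stats: need at least 4 samples")
  m <- mean(window)
  d <- window - m
  m2 <- mean(d^2)
  if (m2 == 0) {
    return(structure(list(range = 0, mean = m, variance = 0,
                          skewness = NA_real_, kurtosis = NA_real_,
                          degenerate = TRUE), class = "window_stats"))
  }
  structure(list(
    range = max(window) - min(window), mean = m, variance = m2,
    skewness = mean(d^3) / m2^1.5, kurtosis = mean(d^4) / m2^2,
    degenerate = FALSE
  ), class = "window_stats")
}

#' Histogram Shannon entropy of a window
#'
#' Entropy of the empirical distribution over `n_bins` equal-width bins
#' spanning the window's own minimum and maximum (final bin closed, so the
#' maximum is counted). Bin counts are normalised by the number of samples
#' and `H = -sum(p_i * log2(p_i))` over occupied bins, in bits; `0 log 0`
#' is taken as 0. A constant window has entropy 0; a window whose samples
#' all land in distinct bins attains the maximum `log2(n)`.
#'
#' @param window numeric vector; at least 2 samples.
#' @param n_bins number of histogram bins.
#' @return entropy in bits.
#' @examples
#' shannon_entropy(rep(300, 31))        # 0
#' shannon_entropy(seq_len(31))         # log2(31) = 4.954
#' @export
shannon_entropy <- function(window, n_bins = 1000) {
  n <- length(window)
  if (n < 2) pt_stop("shannon_entropy: need at least 2 samples")
  mn <- min(window); mx <- max(window)
  if (mx == mn) return(0)
  idx <- pmin(1L + floor((window - mn) / (mx - mn) * n_bins), n_bins)
  p <- tabulate(idx, n_bins) / n
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' All six window measures
#'
#' Convenience wrapper returning the five summary statistics of
#' [summary_stats()] plus the [shannon_entropy()] of a window, as a
#' one-row data frame — the per-window row of the study table.
#'
#' @inheritParams shannon_entropy
#' @return one-row data.frame with columns `range`, `mean`, `variance`,
#'   `skewness`, `kurtosis`, `entropy`.
#' @export
window_stats <- function(window, n_bins = 1000) {
  s <- summary_stats(window)
  data.frame(range = s$range, mean = s$mean, variance = s$variance,
             skewness = s$skewness, kurtosis = s$kurtosis,
             entropy = shannon_entropy(window, n_bins))
}

#' Chi-squared goodness-of-fit test of normality
#'
#' Bins the sample into `k` bins chosen equiprobable under the fitted
#' normal (mean and sd estimated from the sample), with `k` the largest
#' count keeping the expected bin count at least `min_expected`; the
#' statistic is `sum((O - E)^2 / E)` on `k - 3` degrees of freedom (two
#' parameters estimated plus the usual constraint).
#'
#' @param window numeric vector; at least 20 samples.
#' @param alpha significance level.
#' @param min_expected minimum expected count per bin.
#' @return list with `statistic`, `df`, `n_bins`, `p`, `reject`,
#'   `degenerate` (zero-variance windows are rejected with the flag set).
#' @export
chi2_normality <- function(window, alpha = 0.05, min_expected = 5) {
  n <- length(window)
  if (n < 20) pt_stop("chi2_normality: need at least 20 samples")
  m <- mean(window); s <- sd(window)
  if (s == 0)
    return(list(statistic = NA_real_, df = NA_integer_, n_bins = NA_integer_,
                p = 0, reject = TRUE, degenerate = TRUE))
  k <- max(4L, floor(n / min_expected))
  br <- qnorm(seq_len(k - 1) / k, m, s)
  obs <- tabulate(findInterval(window, br) + 1L, k)
  expd <- n / k
  x2 <- sum((obs - expd)^2 / expd)
  df <- k - 3L
  p <- pchisq(x2, df, lower.tail = FALSE)
  list(statistic = x2, df = df, n_bins = k, p = p, reject = p < alpha,
       degenerate = FALSE)
}

#' Wald-Wolfowitz runs test for stationarity
#'
#' Dichotomises the series about its median (values equal to the median
#' are dropped), counts runs, and compares the count with its null
#' distribution via the normal approximation, two-sided. A trending
#' (non-stationary) series produces few runs; an oscillating one too many.
#'
#' @param series numeric vector (a full-trial mean-temperature series);
#'   at least 20 samples.
#' @param alpha significance level.
#' @return list with `n_runs`, `n_above`, `n_below`, `z`, `p`,
#'   `nonstationary` (`p < alpha`), `indeterminate` (`TRUE`, with
#'   `nonstationary = NA`, when either side of the median has fewer than
#'   2 values).
#' @examples
#' runs_test(seq_len(100))$nonstationary  # TRUE: a ramp has 2 runs
#' @export
runs_test <- function(series, alpha = 0.05) {
  if (inherits(series, "temperature_series")) series <- series$values
  if (length(series) < 20) pt_stop("runs_test: need at least 20 samples")
  med <- median(series)
  x <- series[series != med]
  above <- x > med
  n1 <- sum(above); n2 <- sum(!above)
  if (n1 < 2 || n2 < 2)
    return(list(n_runs = NA_integer_, n_above = n1, n_below = n2,
                z = NA_real_, p = NA_real_, nonstationary = NA,
                indeterminate = TRUE))
  r <- length(rle(above)$lengths)
  nn <- n1 + n2
  mu <- 2 * n1 * n2 / nn + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - nn) / (nn^2 * (nn - 1))
  z <- (r - mu) / sqrt(v)
  p <- 2 * pnorm(-abs(z))
  list(n_runs = r, n_above = n1, n_below = n2, z = z, p = p,
       nonstationary = p < alpha, indeterminate = FALSE)
}
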