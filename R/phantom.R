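#' Configuration for the synthetic thermal phantom
#'
#' Describes the simulated scene and the stochastic processes of a synthetic
#' thermal-video trial: a cool background, a warmer elliptical "face"
#' plateau, and two isotropic Gaussian hot spots standing in for the inner
#' canthi of the periorbital regions. The defaults reproduce the study
#' conditions the pipeline targets: 15 Hz radiometric video, 30 s trials,
#' canthus peak temperature near 307.5 K, stimulus-locked effect onset at
#' 300 ms. The default frame geometry is a scaled-down phantom (120 x 160
#' pixels, canthus sigma 3 px); the full 640 x 480 study resolution is
#' available by overriding `frame_rows`, `frame_cols`, `canthus_sigma` and
#' `canthus_centers` together.
#'
#' @param frame_rows,frame_cols frame dimensions in pixels.
#' @param fs_video video sampling rate, Hz.
#' @param trial_duration trial length, seconds (must allow a non-empty
#'   stimulus window, i.e. exceed 9 s).
#' @param background_temp,face_temp,canthus_peak_temp scene temperatures in
#'   Kelvin; must satisfy `canthus_peak_temp > face_temp > background_temp`
#'   and all lie in \[270, 330\] K.
#' @param canthus_sigma Gaussian hot-spot scale, pixels.
#' @param canthus_centers 2 x 2 matrix of (row, col) hot-spot centres,
#'   one row per side (left then right, by column position); `NULL` derives
#'   symmetric positions from the frame size.
#' @param noise_sd additive i.i.d. Gaussian sensor noise, K per pixel.
#' @param drift_amplitude rms of the slow baseline drift process, K.
#' @param drift_timescale drift correlation timescale, seconds.
#' @param jitter_sd standard deviation of the integer random-walk head
#'   jitter, pixels per frame.
#' @param startle_jerk_amplitude displacement magnitude of the sudden
#'   startle movement, pixels.
#' @param startle_prob probability that a stimulus trial contains a formal
#'   startle movement; default is the observed rate 94/534.
#' @param effect_delta injected post-stimulus temperature change, K
#'   (default 0: the null model).
#' @param effect_latency delay between stimulus and effect onset, seconds.
#' @param effect_ramp_duration time for the injected effect to ramp from 0
#'   to `effect_delta`, seconds.
#' @param series_noise_sd standard deviation of the frame-to-frame
#'   fluctuation of the extracted mean-temperature series (used by the
#'   series-level simulation path), K. The default 0.0327 K yields a
#'   2 Hz-low-passed marginal variance of 3e-4 K^2.
#' @param participant_sd between-participant baseline temperature sd, K.
#' @param seed optional integer seed stored with the configuration.
#'
#' @return An object of class `phantom_config` (a validated named list,
#'   including the derived face-ellipse geometry).
#' @examples
#' cfg <- phantom_config()
#' fr <- make_frame(cfg, noise = FALSE)
#' fr[cfg$canthus_centers[1, 1], cfg$canthus_centers[1, 2]]  # 307.5 K
#' @export
phantom_config <- function(frame_rows = 120L, frame_cols = 160L,
                           fs_video = 15, trial_duration = 30,
                           background_temp = 295, face_temp = 305.5,
                           canthus_peak_temp = 307.5, canthus_sigma = 3,
                           canthus_centers = NULL,
                           noise_sd = 0.03, drift_amplitude = 0.05,
                           drift_timescale = 10, jitter_sd = 0.5,
                           startle_jerk_amplitude = 5,
                           startle_prob = 94 / 534,
                           effect_delta = 0, effect_latency = 0.3,
                           effect_ramp_duration = 1,
                           series_noise_sd = 0.0327,
                           participant_sd = 0.3,
                           seed = NULL) {
  if (is.null(canthus_centers)) {
    canthus_centers <- rbind(
      c(round(0.43 * frame_rows), round(0.425 * frame_cols)),
      c(round(0.43 * frame_rows), round(0.575 * frame_cols))
    )
  }
  canthus_centers <- matrix(as.numeric(canthus_centers), nrow = 2)
  cfg <- structure(list(
    frame_rows = as.integer(frame_rows), frame_cols = as.integer(frame_cols),
    fs_video = fs_video, trial_duration = trial_duration,
    background_temp = background_temp, face_temp = face_temp,
    canthus_peak_temp = canthus_peak_temp, canthus_sigma = canthus_sigma,
    canthus_centers = canthus_centers,
    noise_sd = noise_sd, drift_amplitude = drift_amplitude,
    drift_timescale = drift_timescale, jitter_sd = jitter_sd,
    startle_jerk_amplitude = startle_jerk_amplitude,
    startle_prob = startle_prob,
    effect_delta = effect_delta, effect_latency = effect_latency,
    effect_ramp_duration = effect_ramp_duration,
    series_noise_sd = series_noise_sd,
    participant_sd = participant_sd,
    # derived face-ellipse geometry (centre and semi-axes in pixels)
    face_center = c((frame_rows + 1) / 2, (frame_cols + 1) / 2),
    face_semiaxes = c(0.42 * frame_rows, 0.30 * frame_cols),
    seed = seed
  ), class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  temps <- c(cfg$background_temp, cfg$face_temp, cfg$canthus_peak_temp)
  if (!(cfg$canthus_peak_temp > cfg$face_temp &&
        cfg$face_temp > cfg$background_temp))
    pt_stop("invalid phantom config: need canthus_peak_temp > face_temp > ",
            "background_temp", class = "periotherm_config_error")
  if (any(temps < 270) || any(temps > 330))
    pt_stop("invalid phantom config: temperatures must lie in [270, 330] K",
            class = "periotherm_config_error")
  if (cfg$noise_sd < 0 || cfg$drift_amplitude < 0)
    pt_stop("invalid phantom config: noise_sd and drift_amplitude must be >= 0",
            class = "periotherm_config_error")
  if (cfg$fs_video <= 0)
    pt_stop("invalid phantom config: fs_video must be > 0",
            class = "periotherm_config_error")
  if (cfg$trial_duration < 10)
    pt_stop("invalid phantom config: trial_duration must be >= 10 s ",
            "(stimulus window must be non-empty)",
            class = "periotherm_config_error")
  if (cfg$startle_prob < 0 || cfg$startle_prob > 1)
    pt_stop("invalid phantom config: startle_prob must be in [0, 1]",
            class = "periotherm_config_error")
  if (!is.matrix(cfg$canthus_centers) || !all(dim(cfg$canthus_centers) == 2))
    pt_stop("invalid phantom config: canthus_centers must be a 2x2 matrix",
            class = "periotherm_config_error")
  invisible(cfg)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("<phantom_config>\n")
  cat(sprintf("  frame: %d x %d px @ %g Hz, trial %g s\n",
              x$frame_rows, x$frame_cols, x$fs_video, x$trial_duration))
  cat(sprintf("  temperatures: background %g K, face %g K, canthus peak %g K\n",
              x$background_temp, x$face_temp, x$canthus_peak_temp))
  cat(sprintf("  noise %g K, drift rms %g K (timescale %g s), jitter sd %g px\n",
              x$noise_sd, x$drift_amplitude, x$drift_timescale, x$jitter_sd))
  cat(sprintf("  effect: delta %g K, latency %g s; startle jerk %g px (p = %.3f)\n",
              x$effect_delta, x$effect_latency, x$startle_jerk_amplitude,
              x$startle_prob))
  invisible(x)
}

#' Draw a random stimulus-presentation time
#'
#' The stimulus time is uniform over the admissible window: no earlier than
#' two seconds into the trial and no later than seven seconds before its
#' end, so the draw is on `[2, trial_duration - 7]`.
#'
#' @param trial_duration trial length in seconds; must exceed 9 s, else the
#'   window is empty and an invalid-config error is raised.
#' @return Stimulus time in seconds (uses the current RNG state).
#' @examples
#' set.seed(1)
#' schedule_stimulus_time(30)  # in [2, 23]
#' @export
schedule_stimulus_time <- function(trial_duration) {
  if (trial_duration <= 9)
    pt_stop("trial_duration must exceed 9 s for a non-empty stimulus window",
            class = "periotherm_config_error")
  runif(1, 2, trial_duration - 7)
}

#' Render one synthetic thermal frame
#'
#' Builds a frame as background + elliptical face plateau + two isotropic
#' Gaussian hot spots centred at `canthus_centers + offset`, with hot-spot
#' peak temperature `canthus_peak_temp + drift_value + effect_value`,
#' optionally adding i.i.d. Gaussian sensor noise of sd `noise_sd`. All
#' arithmetic is in Kelvin, double precision.
#'
#' If the offset brings either hot-spot centre within `canthus_sigma`
#' pixels of the frame border (or outside it), the frame is still produced
#' but carries the attribute `off_frame = TRUE`.
#'
#' @param config a [phantom_config()].
#' @param t frame time in seconds (metadata only; temporal structure enters
#'   through `drift_value` and `effect_value`).
#' @param offset integer `(row, col)` displacement of both hot spots.
#' @param drift_value slow baseline drift at this frame, K.
#' @param effect_value injected stimulus effect at this frame, K.
#' @param noise logical; add sensor noise (uses the current RNG state).
#' @return `frame_rows x frame_cols` numeric matrix of temperatures (K),
#'   with attribute `off_frame`.
#' @export
make_frame <- function(config, t = 0, offset = c(0, 0),
                       drift_value = 0, effect_value = 0, noise = TRUE) {
  nr <- config$frame_rows; nc <- config$frame_cols
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  fc <- config$face_center; ax <- config$face_semiaxes
  inside <- ((rr - fc[1]) / ax[1])^2 + ((cc - fc[2]) / ax[2])^2 <= 1
  frame <- matrix(config$background_temp, nr, nc)
  frame[inside] <- config$face_temp
  amp <- config$canthus_peak_temp + drift_value + effect_value -
    config$face_temp
  sig2 <- 2 * config$canthus_sigma^2
  off_frame <- FALSE
  for (i in 1:2) {
    ctr <- config$canthus_centers[i, ] + offset
    if (ctr[1] < 1 + config$canthus_sigma || ctr[1] > nr - config$canthus_sigma ||
        ctr[2] < 1 + config$canthus_sigma || ctr[2] > nc - config$canthus_sigma)
      off_frame <- TRUE
    frame <- frame + amp * exp(-((rr - ctr[1])^2 + (cc - ctr[2])^2) / sig2)
  }
  if (noise && config$noise_sd > 0)
    frame <- frame + matrix(rnorm(nr * nc, 0, config$noise_sd), nr, nc)
  attr(frame, "off_frame") <- off_frame
  frame
}

#' Smooth non-stationary baseline drift process
#'
#' White Gaussian noise low-pass filtered at `1/timescale` Hz, then centred
#' and rescaled so its rms equals `amplitude`. This is the simplest process
#' with smooth, slowly wandering sample paths that makes a full-trial runs
#' test reject stationarity, emulating the non-stationarity of real
#' periorbital temperature records.
#'
#' @param n number of samples.
#' @param fs sampling rate, Hz.
#' @param amplitude target rms, K (0 gives the zero vector).
#' @param timescale correlation timescale, s.
#' @return numeric vector of length `n` (uses the current RNG state).
#' @export
drift_process <- function(n, fs, amplitude, timescale = 10) {
  if (amplitude <= 0) return(numeric(n))
  cutoff <- 1 / timescale
  burn <- ceiling(5 * timescale * fs)
  w <- rnorm(n + burn)
  bf <- signal::butter(2, cutoff / (fs / 2))
  d <- as.numeric(signal::filter(bf, w))
  d <- d[(burn + 1):(burn + n)]
  d <- d - mean(d)
  s <- sqrt(mean(d^2))
  if (s == 0) return(numeric(n))
  d * amplitude / s
}

#' Stimulus-effect ramp
#'
#' Unit ramp describing the injected temperature effect: 0 until
#' `t_stim + latency`, rising linearly to 1 over `ramp_duration`, then 1.
#' Multiplied by `effect_delta` it gives the injected effect time course;
#' its mean over a window is the closed-form "ramp factor" relating an
#' injected `effect_delta` to the expected post-stimulus mean shift.
#'
#' @param t vector of times, s.
#' @param t_stim stimulus time, s (`NA` gives all zeros).
#' @param latency onset delay, s.
#' @param ramp_duration rise time, s (0 gives a step at onset).
#' @return numeric vector in \[0, 1\], same length as `t`.
#' @export
effect_ramp <- function(t, t_stim, latency = 0.3, ramp_duration = 1) {
  if (is.na(t_stim)) return(numeric(length(t)))
  if (ramp_duration <= 0) return(as.numeric(t >= t_stim + latency))
  pmin(pmax((t - t_stim - latency) / ramp_duration, 0), 1)
}

# internal: deterministic per-unit substream seed below 2^31, so any
# participant/session/trial is re-creatable in isolation from the study seed
derive_seed <- function(seed, participant = 0, session = 0, trial = 0) {
  m <- 2147483647
  x <- seed %% m
  x <- (x * 48271) %% m
  x <- (x + participant * 1000003 + session * 10007 + trial * 101) %% m
  x <- (x * 48271) %% m
  as.integer(x)
}
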