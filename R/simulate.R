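#' Thermal frame stack
#'
#' Thin container for a time-ordered stack of temperature frames: a
#' `rows x cols x n_frames` numeric array of Kelvin values plus the video
#' sampling rate.
#'
#' @param data 3-d numeric array `(row, col, frame)` of temperatures, K.
#' @param fs video sampling rate, Hz.
#' @return object of class `thermal_stack`.
#' @export
thermal_stack <- function(data, fs) {
  if (length(dim(data)) != 3L)
    pt_stop("thermal_stack data must be a rows x cols x frames array")
  structure(list(data = data, fs = fs), class = "thermal_stack")
}

#' @export
print.thermal_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<thermal_stack> %d x %d px, %d frames @ %g Hz (%.4g-%.4g K)\n",
              d[1], d[2], d[3], x$fs, min(x$data), max(x$data)))
  invisible(x)
}

n_frames <- function(stack) dim(stack$data)[3]

#' Simulate one thermal-video trial
#'
#' Generates a single trial with the statistical structure the analysis
#' assumes: integer-pixel random-walk head jitter; for stimulus trials, a
#' randomly scheduled stimulus time and (with probability `startle_prob`) a
#' sudden startle jerk within 3 s of the stimulus; a smooth non-stationary
#' baseline drift; and an injected temperature effect ramping from 0 to
#' `effect_delta` starting `effect_latency` seconds after the stimulus
#' (identically 0 for non-stimulus trials and under the default null
#' configuration).
#'
#' Two rendering paths are available. `render = "frames"` produces the full
#' synthetic video as a [thermal_stack()] for the tracking and extraction
#' stages. `render = "series"` skips frame rendering and directly produces
#' the per-side mean-temperature series the extraction stage would deliver,
#' modelled as canthus peak + participant offset + drift + effect +
#' i.i.d. Gaussian fluctuation of sd `series_noise_sd` (drift and effect
#' shared between sides, fluctuation independent); this path makes
#' study-scale statistical simulation tractable.
#'
#' @param config a [phantom_config()].
#' @param stimulus_flag logical; does the trial contain the auditory
#'   stimulus?
#' @param participant_offset participant-specific baseline temperature
#'   shift, K (applied to face and canthus temperatures).
#' @param seed optional integer; when given, seeds the RNG for a fully
#'   reproducible trial.
#' @param render `"frames"` for full video, `"series"` for the direct
#'   series-level model.
#' @param participant_id,session_index,trial_index metadata stored in the
#'   record.
#' @return A `trial_record`: list with the trial metadata (`stimulus_flag`,
#'   `t_stim`, indices), the rendered `stack` or `series`
#'   (`list(left, right)` of [temperature_series()]), the 1 Hz `ambient`
#'   stream, and `ground_truth` (per-frame integer offsets, startle
#'   occurrence/jerk frame, drift vector, effect time course, first
#'   off-frame frame if any).
#' @examples
#' cfg <- phantom_config(trial_duration = 10, noise_sd = 0)
#' tr <- simulate_trial(cfg, stimulus_flag = FALSE, seed = 1)
#' tr$ground_truth$startle_occurred
#' @export
simulate_trial <- function(config, stimulus_flag,
                           participant_offset = 0, seed = NULL,
                           render = c("frames", "series"),
                           participant_id = 1L, session_index = 1L,
                           trial_index = 1L) {
  render <- match.arg(render)
  validate_phantom_config(config)
  if (!is.null(seed)) set.seed(seed)
  fs <- config$fs_video
  n <- round(config$trial_duration * fs)
  t <- (seq_len(n) - 1) / fs

  t_stim <- if (isTRUE(stimulus_flag))
    schedule_stimulus_time(config$trial_duration) else NA_real_

  # integer random-walk jitter, plus a sustained jerk on startle trials
  steps <- matrix(round(rnorm(2 * (n - 1), 0, config$jitter_sd)), n - 1, 2)
  offsets <- rbind(c(0, 0), cbind(cumsum(steps[, 1]), cumsum(steps[, 2])))
  startle_occurred <- isTRUE(stimulus_flag) &&
    runif(1) < config$startle_prob
  jerk_frame <- NA_integer_; jerk_vec <- c(0, 0)
  if (startle_occurred && config$startle_jerk_amplitude > 0) {
    tj <- runif(1, t_stim, t_stim + 3)
    jerk_frame <- which(t >= tj)[1]
    ang <- runif(1, 0, 2 * pi)
    jerk_vec <- round(config$startle_jerk_amplitude * c(cos(ang), sin(ang)))
    if (all(jerk_vec == 0))
      jerk_vec <- c(max(1, round(config$startle_jerk_amplitude)), 0)
    idx <- jerk_frame:n
    offsets[idx, ] <- sweep(offsets[idx, , drop = FALSE], 2, jerk_vec, "+")
  }

  drift <- drift_process(n, fs, config$drift_amplitude,
                         config$drift_timescale)
  effect <- config$effect_delta *
    effect_ramp(t, t_stim, config$effect_latency, config$effect_ramp_duration)

  ambient <- ambient_stream(config)

  cfg <- config
  cfg$face_temp <- config$face_temp + participant_offset
  cfg$canthus_peak_temp <- config$canthus_peak_temp + participant_offset

  off_frame_first <- first_off_frame(cfg, offsets)

  rec <- structure(list(
    participant_id = participant_id, session_index = session_index,
    trial_index = trial_index,
    stimulus_flag = isTRUE(stimulus_flag), t_stim = t_stim,
    stack = NULL, series = NULL, stack_ref = NULL, ambient = ambient,
    usable_flag = NA,
    ground_truth = list(
      offsets = offsets, startle_occurred = startle_occurred,
      jerk_frame = jerk_frame, jerk_vec = jerk_vec,
      drift = drift, effect = effect,
      effect_delta = config$effect_delta,
      participant_offset = participant_offset,
      off_frame_first = off_frame_first
    )
  ), class = "trial_record")

  if (render == "frames") {
    stack <- array(NA_real_, c(cfg$frame_rows, cfg$frame_cols, n))
    for (i in seq_len(n)) {
      stack[, , i] <- make_frame(cfg, t[i], offsets[i, ], drift[i],
                                 effect[i], noise = TRUE)
    }
    rec$stack <- thermal_stack(stack, fs)
  } else {
    base <- cfg$canthus_peak_temp + drift + effect
    rec$series <- list(
      left = temperature_series(
        base + rnorm(n, 0, config$series_noise_sd), fs, side = "left"),
      right = temperature_series(
        base + rnorm(n, 0, config$series_noise_sd), fs, side = "right")
    )
  }
  rec
}

# internal: first frame index at which either hot-spot centre comes within
# canthus_sigma of the frame border, NA if none
first_off_frame <- function(config, offsets) {
  sig <- config$canthus_sigma
  for (i in 1:2) {
    ctr <- config$canthus_centers[i, ]
    r <- ctr[1] + offsets[, 1]; c <- ctr[2] + offsets[, 2]
    bad <- r < 1 + sig | r > config$frame_rows - sig |
      c < 1 + sig | c > config$frame_cols - sig
    if (any(bad)) return(which(bad)[1])
  }
  NA_integer_
}

#' Ambient temperature and airspeed stream
#'
#' 1 Hz record of ambient temperature and airspeed near the participant,
#' emulating an ultrasonic anemometer: slowly varying AR(1) temperature
#' around the background value and small positive airspeeds.
#'
#' @param config a [phantom_config()].
#' @return data.frame with columns `timestamp_s`, `ambient_K`,
#'   `airspeed_mps` (uses the current RNG state).
#' @export
ambient_stream <- function(config) {
  nsec <- max(1L, floor(config$trial_duration))
  ts <- seq_len(nsec) - 1
  e <- rnorm(nsec, 0, 0.005)
  a <- numeric(nsec)
  for (i in seq_len(nsec)) a[i] <- if (i == 1) e[1] else 0.98 * a[i - 1] + e[i]
  data.frame(
    timestamp_s = ts,
    ambient_K = config$background_temp + a,
    airspeed_mps = abs(0.05 + rnorm(nsec, 0, 0.01))
  )
}

#' Simulate a whole study
#'
#' Generates trials for `n_participants` participants, each completing
#' `n_sessions` sessions of `n_trials` trials. Exactly half the trials of
#' every session contain the stimulus, with stimulus and non-stimulus
#' trials randomly interleaved. Each participant receives a Gaussian
#' baseline temperature offset (sd `participant_sd`) drawn once and applied
#' to all of that participant's trials.
#'
#' Reproducibility: from the single study `seed`, per-participant,
#' per-session and per-trial substream seeds are derived deterministically
#' from the indices, so identical seeds give identical studies and any
#' trial can be regenerated in isolation.
#'
#' @param config a [phantom_config()].
#' @param n_participants,n_sessions,n_trials study shape; `n_trials` must
#'   be even (half stimulus).
#' @param seed integer study seed; `NULL` draws one from the current RNG.
#' @param render passed to [simulate_trial()].
#' @param out_dir optional directory: with `render = "frames"`, each
#'   trial's stack is written with [write_trial()] and dropped from memory
#'   (`stack_ref` records the path).
#' @return list of `trial_record`s with attributes `config` and `seed`.
#' @examples
#' cfg <- phantom_config()
#' st <- simulate_study(cfg, n_participants = 1, n_sessions = 1,
#'                      n_trials = 2, seed = 7, render = "series")
#' sum(vapply(st, function(tr) tr$stimulus_flag, logical(1)))  # 1
#' @export
simulate_study <- function(config, n_participants = 11, n_sessions = 10,
                           n_trials = 10, seed = NULL,
                           render = c("series", "frames"),
                           out_dir = NULL) {
  render <- match.arg(render)
  validate_phantom_config(config)
  if (n_trials %% 2 != 0)
    pt_stop("n_trials must be even: half the trials carry the stimulus",
            class = "periotherm_config_error")
  if (is.null(seed)) seed <- sample.int(2147483646L, 1)
  trials <- vector("list", n_participants * n_sessions * n_trials)
  k <- 0L
  for (p in seq_len(n_participants)) {
    set.seed(derive_seed(seed, p, 0, 0))
    poff <- rnorm(1, 0, config$participant_sd)
    for (s in seq_len(n_sessions)) {
      set.seed(derive_seed(seed, p, s, 0))
      flags <- sample(rep(c(TRUE, FALSE), n_trials / 2))
      for (tr in seq_len(n_trials)) {
        k <- k + 1L
        rec <- simulate_trial(config, flags[tr], participant_offset = poff,
                              seed = derive_seed(seed, p, s, tr),
                              render = render,
                              participant_id = p, session_index = s,
                              trial_index = tr)
        if (!is.null(out_dir) && render == "frames") {
          d <- file.path(out_dir, sprintf("p%02d_s%02d_t%02d", p, s, tr))
          write_trial(rec, d)
          rec$stack_ref <- d
          rec$stack <- NULL
        }
        trials[[k]] <- rec
      }
    }
  }
  attr(trials, "config") <- config
  attr(trials, "seed") <- seed
  trials
}
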