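# Automated stand-in for the visual identification of trials with a
# formal startle response (sudden movement within 3 s of the stimulus).

#' Frame-to-frame motion energy
#'
#' Mean squared temperature difference between consecutive frames. Pure
#' sensor noise of sd sigma yields a flat profile near `2 * sigma^2`;
#' sudden movement produces a sharp peak at the jerk frame. Invariant to
#' adding a constant temperature offset to every frame.
#'
#' @param stack a [thermal_stack()] with at least 2 frames.
#' @return object of class `motion_energy_series`: list with `values`
#'   (length `n_frames - 1`, K^2; element `i` spans frames `i` to `i + 1`)
#'   and `fs`.
#' @export
motion_energy <- function(stack) {
  n <- n_frames(stack)
  if (n < 2) pt_stop("motion_energy: need at least 2 frames")
  vals <- vapply(seq_len(n - 1), function(i)
    mean((stack$data[, , i + 1] - stack$data[, , i])^2), numeric(1))
  structure(list(values = vals, fs = stack$fs),
            class = "motion_energy_series")
}

#' Detect a visible formal startle response
#'
#' Automates the visual criterion "sudden movement within 3 s of the
#' stimulus": the trial is flagged when the maximum motion energy inside
#' `(t_stim, t_stim + window]` exceeds the median plus `z_threshold`
#' robust scale units of the pre-stimulus motion energy. The robust scale
#' is the MAD floored at the median itself: under integer-pixel head
#' jitter the motion-energy distribution is a discrete mixture of a noise
#' floor and a few spike levels, on which a bare MAD can collapse to the
#' noise spread (flagging every ordinary jitter step) — the floor keeps
#' the threshold a multiple of the typical jitter energy, so only
#' movements well beyond the trial's ordinary motion are flagged. The
#' default of 6 units is deliberately conservative, mirroring
#' conservative visual identification.
#'
#' @param stack a [thermal_stack()] or a precomputed
#'   [motion_energy()] series.
#' @param t_stim stimulus time, s; must be present (stimulus trials only)
#'   and leave `window` seconds before the trial end.
#' @param window detection window after the stimulus, s.
#' @param z_threshold robust z-score threshold.
#' @return `TRUE` if a startle movement is detected.
#' @export
detect_formal_startle <- function(stack, t_stim, window = 3,
                                  z_threshold = 6) {
  if (is.na(t_stim))
    pt_stop("detect_formal_startle: not a stimulus trial (t_stim missing)")
  me <- if (inherits(stack, "motion_energy_series")) stack
        else motion_energy(stack)
  fs <- me$fs
  # pair i spans frames i..i+1; assign it the later frame's time i / fs
  t <- seq_along(me$values) / fs
  if (t_stim + window > max(t))
    pt_stop("detect_formal_startle: detection window extends past trial end")
  pre <- me$values[t <= t_stim]
  post <- me$values[t > t_stim & t <= t_stim + window]
  if (length(pre) < 5 || length(post) < 1)
    pt_stop("detect_formal_startle: too few motion-energy samples")
  med <- median(pre)
  thr <- med + z_threshold * max(stats::mad(pre), med)
  max(post) > thr
}

#' Flag a trial unusable from its two region tracks
#'
#' A trial is unusable when either periorbital region could not be tracked
#' to the end of the trial.
#'
#' @param track_left,track_right [region_track()] objects.
#' @return `TRUE` if the trial is unusable.
#' @export
flag_unusable <- function(track_left, track_right) {
  isTRUE(track_left$failed) || isTRUE(track_right$failed)
}
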