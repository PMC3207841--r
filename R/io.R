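# On-disk formats: multi-page 32-bit float TIFF for frame stacks (pixel
# values affinely mapped to [0,1] over a recorded Kelvin range, since TIFF
# float pages are stored on [0,1]); JSON sidecar for trial metadata and
# ground truth; plain CSV for the ambient stream.

#' Write a frame stack as a multi-page float TIFF
#'
#' Temperatures are mapped affinely from `t_range` Kelvin onto `[0, 1]` and
#' stored as one 32-bit float page per frame. The mapping preserves
#' temperatures to ~2e-8 K over the default range, far below the 0.1 mK
#' resolution of the source data; `t_range` must be recorded (it is stored
#' in the trial sidecar by [write_trial()]) to invert the mapping.
#'
#' @param stack a [thermal_stack()].
#' @param path output file path.
#' @param t_range Kelvin range mapped onto `[0, 1]`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, t_range = c(270, 330)) {
  d <- dim(stack$data)
  if (min(stack$data) < t_range[1] || max(stack$data) > t_range[2])
    pt_stop("stack temperatures outside t_range [", t_range[1], ", ",
            t_range[2], "] K")
  span <- diff(t_range)
  pages <- lapply(seq_len(d[3]), function(i)
    (stack$data[, , i] - t_range[1]) / span)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE,
                  compression = "none")
  invisible(path)
}

#' Read a frame stack written by [write_stack()]
#'
#' @param path TIFF file path.
#' @param fs video sampling rate, Hz.
#' @param t_range Kelvin range used when writing.
#' @return a [thermal_stack()].
#' @export
read_stack <- function(path, fs, t_range = c(270, 330)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(NA_real_, c(d[1], d[2], length(pages)))
  span <- diff(t_range)
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]] * span + t_range[1]
  thermal_stack(arr, fs)
}

#' Write a trial record to a directory
#'
#' Writes `stack.tiff` (if frames are present), `trial.json` (metadata and
#' ground truth) and `ambient.csv`.
#'
#' @param trial a `trial_record` from [simulate_trial()].
#' @param dir output directory (created if needed).
#' @param t_range Kelvin range for the TIFF mapping.
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir, t_range = c(270, 330)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    participant_id = trial$participant_id,
    session_index = trial$session_index,
    trial_index = trial$trial_index,
    stimulus_flag = trial$stimulus_flag,
    t_stim = trial$t_stim,
    fs = if (!is.null(trial$stack)) trial$stack$fs else NA,
    t_range = t_range,
    ground_truth = trial$ground_truth
  )
  jsonlite::write_json(meta, file.path(dir, "trial.json"),
                       auto_unbox = TRUE, digits = I(17), na = "null",
                       matrix = "rowmajor")
  utils::write.csv(trial$ambient, file.path(dir, "ambient.csv"),
                   row.names = FALSE)
  if (!is.null(trial$stack))
    write_stack(trial$stack, file.path(dir, "stack.tiff"), t_range)
  invisible(dir)
}

#' Read a trial record written by [write_trial()]
#'
#' @param dir trial directory.
#' @return a `trial_record` (without the `series` field; the stack is
#'   reloaded if `stack.tiff` is present).
#' @export
read_trial <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "trial.json"),
                              simplifyVector = TRUE)
  gt <- meta$ground_truth
  gt$offsets <- matrix(as.numeric(gt$offsets), ncol = 2)
  rec <- structure(list(
    participant_id = meta$participant_id,
    session_index = meta$session_index,
    trial_index = meta$trial_index,
    stimulus_flag = isTRUE(meta$stimulus_flag),
    t_stim = if (is.null(meta$t_stim)) NA_real_ else meta$t_stim,
    stack = NULL, series = NULL, stack_ref = dir,
    ambient = utils::read.csv(file.path(dir, "ambient.csv")),
    usable_flag = NA,
    ground_truth = gt
  ), class = "trial_record")
  tf <- file.path(dir, "stack.tiff")
  if (file.exists(tf))
    rec$stack <- read_stack(tf, meta$fs, as.numeric(meta$t_range))
  rec
}
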