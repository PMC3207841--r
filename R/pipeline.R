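# Study-level orchestration: simulate -> track -> extract -> detect ->
# stats, with per-trial quarantine, accounting, ANOVAs and the report.

#' Study configuration
#'
#' Bundles the phantom configuration, the study shape and every analysis
#' parameter of the pipeline into one serialisable object.
#'
#' @param phantom a [phantom_config()].
#' @param n_participants,n_sessions,n_trials study shape (`n_trials` even).
#' @param window_width pre/post window width, s.
#' @param n_bins entropy histogram bins.
#' @param alpha significance level used throughout.
#' @param max_step cross-search initial step, px.
#' @param roi_height,roi_width tracking ROI extent, px (centred on each
#'   canthus).
#' @param fail_mult,fail_window,fail_k tracking failure rule (see
#'   [track_region()]).
#' @param z_threshold startle-detector robust z threshold.
#' @param render `"series"` (direct series-level simulation; fast,
#'   study-scale) or `"frames"` (full video through tracking and
#'   extraction).
#' @param seed study seed.
#' @param out_dir optional output directory for [write_study_outputs()]
#'   and frame storage.
#' @return object of class `study_config`.
#' @export
study_config <- function(phantom = phantom_config(),
                         n_participants = 11, n_sessions = 10,
                         n_trials = 10,
                         window_width = 2, n_bins = 1000, alpha = 0.05,
                         max_step = 8, roi_height = 11, roi_width = 15,
                         fail_mult = 25, fail_window = 15, fail_k = 5,
                         z_threshold = 6,
                         render = c("series", "frames"),
                         seed = NULL, out_dir = NULL) {
  render <- match.arg(render)
  validate_phantom_config(phantom)
  if (n_trials %% 2 != 0)
    pt_stop("n_trials must be even", class = "periotherm_config_error")
  structure(list(
    phantom = phantom, n_participants = n_participants,
    n_sessions = n_sessions, n_trials = n_trials,
    window_width = window_width, n_bins = n_bins, alpha = alpha,
    max_step = max_step, roi_height = as.integer(roi_height),
    roi_width = as.integer(roi_width), fail_mult = fail_mult,
    fail_window = as.integer(fail_window), fail_k = as.integer(fail_k),
    z_threshold = z_threshold, render = render, seed = seed,
    out_dir = out_dir
  ), class = "study_config")
}

# fields of phantom_config that are derived, not free parameters
.phantom_derived <- c("face_center", "face_semiaxes")

#' Serialise / restore a study configuration as JSON
#'
#' The round trip is lossless: numbers are written at full precision and
#' the phantom configuration is rebuilt through [phantom_config()].
#'
#' @param config a [study_config()].
#' @param path optional file to write to / read from.
#' @return `config_to_json`: the JSON string (invisibly if written to
#'   `path`); `config_from_json`: the restored [study_config()].
#' @export
config_to_json <- function(config, path = NULL) {
  li <- unclass(config)
  li$phantom <- unclass(li$phantom)
  li$phantom <- li$phantom[setdiff(names(li$phantom), .phantom_derived)]
  txt <- jsonlite::toJSON(li, auto_unbox = TRUE, digits = I(17),
                          null = "null", matrix = "rowmajor")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname config_to_json
#' @param json JSON string (ignored when `path` is given).
#' @export
config_from_json <- function(json = NULL, path = NULL) {
  li <- if (!is.null(path)) jsonlite::read_json(path, simplifyVector = TRUE)
        else jsonlite::fromJSON(json)
  ph <- li$phantom
  ph$canthus_centers <- matrix(as.numeric(ph$canthus_centers), nrow = 2)
  li$phantom <- do.call(phantom_config, ph)
  li$render <- match.arg(li$render, c("series", "frames"))
  do.call(study_config, li)
}

# internal: process one trial through the post-simulation stages.
# Returns stats rows, runs-test rows and the usable/startle flags.
process_trial <- function(rec, config) {
  ph <- config$phantom
  usable <- TRUE; startle <- NA
  rows <- NULL; runs_rows <- NULL

  if (config$render == "frames") {
    stack <- rec$stack
    if (is.null(stack)) stack <- read_trial(rec$stack_ref)$stack
    mk_roi <- function(i) {
      ctr <- ph$canthus_centers[i, ]
      roi(round(ctr[1] - (config$roi_height - 1) / 2),
          round(ctr[2] - (config$roi_width - 1) / 2),
          config$roi_height, config$roi_width)
    }
    tl <- track_region(stack, mk_roi(1), side = "left",
                       max_step = config$max_step,
                       fail_mult = config$fail_mult,
                       fail_window = config$fail_window,
                       fail_k = config$fail_k)
    tr_ <- track_region(stack, mk_roi(2), side = "right",
                        max_step = config$max_step,
                        fail_mult = config$fail_mult,
                        fail_window = config$fail_window,
                        fail_k = config$fail_k)
    usable <- !flag_unusable(tl, tr_)
    if (!usable)
      return(list(usable = FALSE, startle = NA, rows = NULL,
                  runs = NULL))
    series <- list(left = series_from_track(stack, tl),
                   right = series_from_track(stack, tr_))
    startle <- if (rec$stimulus_flag)
      detect_formal_startle(stack, rec$t_stim,
                            z_threshold = config$z_threshold) else NA
  } else {
    series <- rec$series
    startle <- if (rec$stimulus_flag)
      rec$ground_truth$startle_occurred else NA
  }

  key <- data.frame(participant = rec$participant_id,
                    session = rec$session_index, trial = rec$trial_index,
                    stringsAsFactors = FALSE)
  for (side in c("left", "right")) {
    filt <- lowpass(series[[side]])
    rt <- runs_test(filt$values, alpha = config$alpha)
    runs_rows <- rbind(runs_rows, cbind(
      key, side = side, n_runs = rt$n_runs, p = rt$p,
      nonstationary = rt$nonstationary))
    if (rec$stimulus_flag) {
      wp <- extract_windows(filt, rec$t_stim, config$window_width)
      for (win in c("pre", "post")) {
        ws <- window_stats(wp[[win]], config$n_bins)
        rows <- rbind(rows, cbind(
          key, side = side, window = win,
          stimulus_flag = rec$stimulus_flag,
          formal_startle = isTRUE(startle), usable = TRUE, ws))
      }
    }
  }
  list(usable = usable, startle = startle, rows = rows, runs = runs_rows)
}

#' Run a full simulated study through the pipeline
#'
#' Simulates every trial, then runs each through tracking (frames mode),
#' series extraction, filtering, the full-trial runs test, startle
#' detection and window statistics; tallies the trial accounting; fits the
#' mixed ANOVA for all six measures on (a) all usable stimulus trials and
#' (b) the formal-startle subset; and builds the group-mean report. A
#' failing trial is quarantined — marked unusable and logged — never
#' aborting the study. Deterministic given `config$seed`.
#'
#' @param config a [study_config()].
#' @return object of class `study_result`: list with `config`, `trials`
#'   (per-trial flag table), `accounting` ([account_trials()] summary),
#'   `table` (long study table of window measures), `runs` (per-trial,
#'   per-side runs-test results), `anova` (per subset, per measure),
#'   `report` ([build_report()]), and `log` (quarantine messages).
#' @examples
#' \donttest{
#' cfg <- study_config(n_participants = 2, n_sessions = 1, n_trials = 4,
#'                     seed = 1)
#' res <- run_study(cfg)
#' res$accounting
#' }
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  trials <- simulate_study(config$phantom, config$n_participants,
                           config$n_sessions, config$n_trials,
                           seed = config$seed, render = config$render,
                           out_dir = if (config$render == "frames")
                             config$out_dir else NULL)
  flag_rows <- NULL; all_rows <- NULL; all_runs <- NULL
  log <- character(0)
  for (rec in trials) {
    out <- tryCatch(process_trial(rec, config), error = function(e) {
      list(usable = FALSE, startle = NA, rows = NULL, runs = NULL,
           err = conditionMessage(e))
    })
    if (!is.null(out$err))
      log <- c(log, sprintf("p%02d s%02d t%02d quarantined: %s",
                            rec$participant_id, rec$session_index,
                            rec$trial_index, out$err))
    flag_rows <- rbind(flag_rows, data.frame(
      participant = rec$participant_id, session = rec$session_index,
      trial = rec$trial_index, stimulus_flag = rec$stimulus_flag,
      usable_flag = out$usable,
      formal_startle_flag = if (rec$stimulus_flag && out$usable)
        isTRUE(out$startle) else NA,
      stringsAsFactors = FALSE))
    all_rows <- rbind(all_rows, out$rows)
    all_runs <- rbind(all_runs, out$runs)
  }
  accounting <- account_trials(flag_rows)
  report <- if (!is.null(all_rows)) build_report(all_rows, config$alpha)
            else NULL
  anovas <- if (!is.null(report))
    lapply(report$subsets, function(s) s$anova) else NULL
  res <- structure(list(config = config, trials = flag_rows,
                        accounting = accounting, table = all_rows,
                        runs = all_runs, anova = anovas, report = report,
                        log = log),
                   class = "study_result")
  if (!is.null(config$out_dir)) write_study_outputs(res, config$out_dir)
  res
}

#' @export
print.study_result <- function(x, ...) {
  print(x$accounting)
  if (length(x$log)) cat(length(x$log), "trial(s) quarantined\n")
  invisible(x)
}

#' Trial accounting
#'
#' Tallies a study's trials: totals, stimulus/non-stimulus counts,
#' unusable counts per arm, usable stimulus trials and the formal-startle
#' subset size. The additivity invariant `usable = total - unusable` holds
#' by construction and is asserted; a formal-startle flag on a
#' non-stimulus (or unusable) trial is an inconsistency and raises an
#' error.
#'
#' @param trials data.frame with logical columns `stimulus_flag`,
#'   `usable_flag` and `formal_startle_flag` (NA allowed for non-stimulus
#'   or unusable trials), one row per trial.
#' @return object of class `accounting_summary`.
#' @examples
#' fl <- data.frame(stimulus_flag = rep(c(TRUE, FALSE), c(550, 550)),
#'                  usable_flag = rep(c(FALSE, TRUE, FALSE, TRUE),
#'                                    c(16, 534, 15, 535)),
#'                  formal_startle_flag = NA)
#' account_trials(fl)$n_usable_stimulus  # 534
#' @export
account_trials <- function(trials) {
  st <- trials$stimulus_flag
  us <- trials$usable_flag
  fs <- trials$formal_startle_flag
  if (any(fs %in% TRUE & !st))
    pt_stop("inconsistent flags: formal startle on a non-stimulus trial")
  if (any(fs %in% TRUE & !us))
    pt_stop("inconsistent flags: formal startle on an unusable trial")
  out <- list(
    n_total = nrow(trials),
    n_stimulus = sum(st),
    n_nonstimulus = sum(!st),
    n_unusable_stimulus = sum(st & !us),
    n_unusable_nonstimulus = sum(!st & !us),
    n_unusable = sum(!us),
    n_usable_stimulus = sum(st & us),
    n_usable_nonstimulus = sum(!st & us),
    n_usable = sum(us),
    n_formal_startle = sum(fs %in% TRUE)
  )
  stopifnot(out$n_usable == out$n_total - out$n_unusable,
            out$n_usable_stimulus == out$n_stimulus -
              out$n_unusable_stimulus)
  structure(out, class = "accounting_summary")
}

#' @export
print.accounting_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "Of the %d trials (%d with stimulus), %d were unusable ",
    "(%d stimulus, %d non-stimulus).\n",
    "Of the %d usable stimulus trials, %d contained a visible formal ",
    "startle response.\n"),
    x$n_total, x$n_stimulus, x$n_unusable, x$n_unusable_stimulus,
    x$n_unusable_nonstimulus, x$n_usable_stimulus, x$n_formal_startle))
  invisible(x)
}

#' Write study outputs as CSV and Markdown
#'
#' Writes `trials.csv` (per-trial flags), `window_stats.csv` (the study
#' table), `runs.csv`, `anova.csv` (per subset, measure and effect) and
#' `report.md`. All writers are deterministic: the same study result
#' yields byte-identical files.
#'
#' @param result a [run_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  if (!is.null(result$table))
    utils::write.csv(result$table, file.path(dir, "window_stats.csv"),
                     row.names = FALSE)
  if (!is.null(result$runs))
    utils::write.csv(result$runs, file.path(dir, "runs.csv"),
                     row.names = FALSE)
  if (!is.null(result$anova)) {
    arows <- NULL
    for (ss in names(result$anova)) {
      for (m in names(result$anova[[ss]])) {
        a <- result$anova[[ss]][[m]]
        if (is.null(a)) next
        arows <- rbind(arows, cbind(subset = ss, measure = m,
                                    as.data.frame(a)))
      }
    }
    if (!is.null(arows))
      utils::write.csv(arows, file.path(dir, "anova.csv"),
                       row.names = FALSE)
  }
  if (!is.null(result$report))
    writeLines(format_report_md(result$report), file.path(dir, "report.md"))
  invisible(dir)
}
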