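# Shared fixtures, built in code.

# small, fast phantom for frames-mode tests (10 s, 60 x 80 px; canthus
# centres derive to (26, 34) and (26, 46))
tiny_phantom <- function(...) {
  phantom_config(frame_rows = 60L, frame_cols = 80L, trial_duration = 10, ...)
}

# ROI centred on a canthus of a config
centered_roi <- function(cfg, side = 1, height = 11, width = 15) {
  ctr <- cfg$canthus_centers[side, ]
  roi(round(ctr[1] - (height - 1) / 2), round(ctr[2] - (width - 1) / 2),
      height, width)
}

# reference block + translated frame pair from a noiseless phantom
translate_pair <- function(cfg, d, roi_obj) {
  frA <- make_frame(cfg, noise = FALSE)
  frB <- make_frame(cfg, offset = d, noise = FALSE)
  ref <- frA[roi_obj$top:(roi_obj$top + roi_obj$height - 1),
             roi_obj$left:(roi_obj$left + roi_obj$width - 1)]
  list(ref = ref, frame = frB, pos = c(roi_obj$top, roi_obj$left))
}

# long-format study table with one row per (participant, trial, side,
# window), for ANOVA tests; `shift` is added to post-window values
synth_table <- function(n_participants = 3, n_trials = 4, shift = 0,
                        participant_sd = 0.3, noise_sd = 0.02) {
  rows <- list()
  for (p in seq_len(n_participants)) {
    poff <- rnorm(1, 0, participant_sd)
    for (tr in seq_len(n_trials)) {
      for (side in c("left", "right")) {
        base <- 307.5 + poff + rnorm(1, 0, noise_sd)
        for (win in c("pre", "post")) {
          rows[[length(rows) + 1L]] <- data.frame(
            participant = p, session = 1L, trial = tr, side = side,
            window = win, stimulus_flag = TRUE, formal_startle = FALSE,
            usable = TRUE,
            range = 0.05, mean = base + rnorm(1, 0, noise_sd) +
              if (win == "post") shift else 0,
            variance = 3e-4, skewness = 0, kurtosis = 2.2,
            entropy = 4.92, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
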