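# Three-way repeated-measures mixed ANOVA and the study report.

MEASURES <- c("range", "mean", "variance", "skewness", "kurtosis", "entropy")

#' Three-way repeated-measures mixed ANOVA on a window measure
#'
#' Compares one per-window measure across the fixed factors window
#' (pre/post-stimulus) and side (left/right periorbital) with participant
#' as a random effect. Trials within a (participant, window, side) cell are
#' replicates; cell means are taken per participant first (the
#' unweighted-means solution, which keeps the expected-mean-squares
#' denominators valid under unequal post-exclusion trial counts), and the
#' classical repeated-measures decomposition is fitted on the cell means:
#' each fixed effect is tested against its interaction with participant.
#'
#' @param table a study table (see [run_study()]): long-format data.frame
#'   with columns `participant`, `side` (`"left"`/`"right"`), `window`
#'   (`"pre"`/`"post"`) and the measure columns.
#' @param measure one of `"range"`, `"mean"`, `"variance"`, `"skewness"`,
#'   `"kurtosis"`, `"entropy"`.
#' @return data.frame of class `anova_result` with one row per effect
#'   (`participant`, `window`, `side`, `window:side`): `df`, `sumsq`,
#'   `meansq`, `df_denom`, `denom_meansq`, `statistic` (F), `p.value`.
#'   Fixed effects whose denominator mean square is (numerically) zero are
#'   reported with `statistic = Inf`, `p.value = 0` and the attribute
#'   `zero_denominator` set.
#' @export
mixed_anova <- function(table, measure) {
  measure <- match.arg(measure, MEASURES)
  d <- table[!is.na(table[[measure]]), , drop = FALSE]
  if (nrow(d) == 0) pt_stop("mixed_anova: no data for measure ", measure)
  d$participant <- factor(d$participant)
  d$window <- factor(d$window, levels = c("pre", "post"))
  d$side <- factor(d$side, levels = c("left", "right"))
  if (nlevels(d$participant) < 2)
    pt_stop("mixed_anova: need at least 2 participants")
  # every participant must contribute all four window x side cells
  cells <- table(d$participant, d$window, d$side)
  if (any(cells == 0)) {
    idx <- which(cells == 0, arr.ind = TRUE)[1, ]
    pt_stop(sprintf(
      "mixed_anova: participant %s has no trials in cell (%s, %s)",
      dimnames(cells)[[1]][idx[1]], dimnames(cells)[[2]][idx[2]],
      dimnames(cells)[[3]][idx[3]]))
  }
  d$.y <- d[[measure]]
  cm <- aggregate(.y ~ participant + window + side, data = d, FUN = mean)
  fit <- aov(.y ~ window * side + Error(participant / (window * side)),
             data = cm)
  sm <- summary(fit)
  get_stratum <- function(nm) {
    tab <- sm[[paste0("Error: ", nm)]][[1]]
    rownames(tab) <- trimws(rownames(tab))
    tab
  }
  sp <- get_stratum("participant")
  sw <- get_stratum("participant:window")
  ss <- get_stratum("participant:side")
  sws <- get_stratum("participant:window:side")
  eff <- function(tab, row, label, denom_label) {
    num_df <- tab[row, "Df"]; num_ss <- tab[row, "Sum Sq"]
    den_df <- tab["Residuals", "Df"]; den_ss <- tab["Residuals", "Sum Sq"]
    num_ms <- num_ss / num_df; den_ms <- den_ss / den_df
    data.frame(effect = label, df = num_df, sumsq = num_ss, meansq = num_ms,
               df_denom = den_df, denom_meansq = den_ms,
               statistic = num_ms / den_ms,
               p.value = stats::pf(num_ms / den_ms, num_df, den_df,
                                   lower.tail = FALSE),
               denominator = denom_label, stringsAsFactors = FALSE)
  }
  out <- rbind(
    data.frame(effect = "participant", df = sp["Residuals", "Df"],
               sumsq = sp["Residuals", "Sum Sq"],
               meansq = sp["Residuals", "Sum Sq"] / sp["Residuals", "Df"],
               df_denom = NA_real_, denom_meansq = NA_real_,
               statistic = NA_real_, p.value = NA_real_,
               denominator = NA_character_, stringsAsFactors = FALSE),
    eff(sw, "window", "window", "participant:window"),
    eff(ss, "side", "side", "participant:side"),
    eff(sws, "window:side", "window:side", "participant:window:side")
  )
  # zero-denominator guard: an exactly reproduced effect has zero
  # interaction mean square; report F = Inf, p = 0 with a flag
  zd <- FALSE
  scale_ms <- max(out$meansq, na.rm = TRUE)
  for (i in which(!is.na(out$denom_meansq))) {
    if (out$denom_meansq[i] <= scale_ms * 1e-12) {
      if (out$meansq[i] > out$denom_meansq[i]) {
        out$statistic[i] <- Inf; out$p.value[i] <- 0; zd <- TRUE
      } else {
        out$statistic[i] <- NaN; out$p.value[i] <- NA_real_; zd <- TRUE
      }
    }
  }
  rownames(out) <- NULL
  structure(out, class = c("anova_result", "data.frame"),
            measure = measure, n_participants = nlevels(d$participant),
            zero_denominator = zd)
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Mixed repeated-measures ANOVA on '%s' (%d participants)\n",
              attr(x, "measure"), attr(x, "n_participants")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  if (isTRUE(attr(x, "zero_denominator")))
    cat("note: zero interaction mean square; F/p flagged\n")
  invisible(x)
}

#' Group-mean report of the window measures
#'
#' Produces the study's headline tables: group means and standard
#' deviations of all six window measures, organised by the levels of the
#' fixed ANOVA factors (pre/post-stimulus and left/right periorbital), for
#' (a) all usable stimulus trials and (b) the subset with a visible formal
#' startle response. Members of a factor pair whose mixed-ANOVA effect is
#' significant at `alpha` are both marked (`sig = TRUE` on both members of
#' the pair).
#'
#' @param table full study table (see [run_study()]) including the
#'   `usable`, `stimulus_flag` and `formal_startle` columns.
#' @param alpha significance level for marking pairs.
#' @return object of class `study_report`: per subset, the group-mean
#'   table (`measure`, `level`, `mean`, `sd`, `sig`), the per-measure
#'   ANOVA results, the number of trials, and an `empty` marker when the
#'   subset holds no trials.
#' @export
build_report <- function(table, alpha = 0.05) {
  base <- table[table$usable & table$stimulus_flag, , drop = FALSE]
  subsets <- list(
    all_stimulus = base,
    formal_startle = base[base$formal_startle %in% TRUE, , drop = FALSE]
  )
  out <- lapply(subsets, function(d) {
    n_tr <- if (nrow(d)) nrow(unique(d[c("participant", "session",
                                         "trial")])) else 0L
    if (nrow(d) == 0)
      return(list(empty = TRUE, n_trials = 0L, table = NULL, anova = NULL))
    anovas <- lapply(MEASURES, function(m)
      tryCatch(mixed_anova(d, m), error = function(e) NULL))
    names(anovas) <- MEASURES
    rows <- list()
    for (m in MEASURES) {
      a <- anovas[[m]]
      p_window <- if (!is.null(a)) a$p.value[a$effect == "window"] else NA
      p_side <- if (!is.null(a)) a$p.value[a$effect == "side"] else NA
      for (lv in c("pre", "post")) {
        v <- d[[m]][d$window == lv]
        rows[[length(rows) + 1L]] <- data.frame(
          measure = m, factor = "window", level = lv,
          mean = mean(v, na.rm = TRUE),
          sd = if (length(v) > 1) sd(v, na.rm = TRUE) else 0,
          sig = isTRUE(p_window < alpha), stringsAsFactors = FALSE)
      }
      for (lv in c("left", "right")) {
        v <- d[[m]][d$side == lv]
        rows[[length(rows) + 1L]] <- data.frame(
          measure = m, factor = "side", level = lv,
          mean = mean(v, na.rm = TRUE),
          sd = if (length(v) > 1) sd(v, na.rm = TRUE) else 0,
          sig = isTRUE(p_side < alpha), stringsAsFactors = FALSE)
      }
    }
    list(empty = FALSE, n_trials = n_tr, table = do.call(rbind, rows),
         anova = anovas)
  })
  structure(list(subsets = out, alpha = alpha), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  for (nm in names(x$subsets)) {
    s <- x$subsets[[nm]]
    cat(sprintf("== %s (n = %d trials) ==\n", nm, s$n_trials))
    if (isTRUE(s$empty)) {
      cat("   [empty subset]\n")
    } else {
      print.data.frame(s$table, digits = 4, row.names = FALSE)
    }
  }
  invisible(x)
}

#' Render a study report as Markdown lines
#'
#' @param report a [build_report()] result.
#' @return character vector of Markdown lines.
#' @export
format_report_md <- function(report) {
  lines <- c("# Periorbital window-measure report", "")
  for (nm in names(report$subsets)) {
    s <- report$subsets[[nm]]
    lines <- c(lines, sprintf("## %s (n = %d trials)", nm, s$n_trials), "")
    if (isTRUE(s$empty)) {
      lines <- c(lines, "_empty subset_", "")
      next
    }
    lines <- c(lines,
               "| measure | level | mean | sd | sig |",
               "|---|---|---|---|---|")
    tb <- s$table
    for (i in seq_len(nrow(tb))) {
      lines <- c(lines, sprintf("| %s | %s | %.5g | %.3g | %s |",
                                tb$measure[i], tb$level[i], tb$mean[i],
                                tb$sd[i], if (tb$sig[i]) "*" else ""))
    }
    lines <- c(lines, "",
               sprintf("Pairs marked `*` differ at p < %g ", report$alpha),
               "(both members of a significant pair are marked).", "")
  }
  lines
}
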