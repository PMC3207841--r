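# independent oracle: textbook EMS decomposition of a complete
# participant x window x side table of cell means
ems_oracle <- function(cm) {
  P <- length(unique(cm$participant))
  g <- mean(cm$value)
  yp <- tapply(cm$value, cm$participant, mean)
  yw <- tapply(cm$value, cm$window, mean)
  ys <- tapply(cm$value, cm$side, mean)
  ypw <- tapply(cm$value, list(cm$participant, cm$window), mean)
  yps <- tapply(cm$value, list(cm$participant, cm$side), mean)
  yws <- tapply(cm$value, list(cm$window, cm$side), mean)
  ss_p <- 4 * sum((yp - g)^2)
  ss_w <- 2 * P * sum((yw - g)^2)
  ss_s <- 2 * P * sum((ys - g)^2)
  ss_pw <- 0; ss_ps <- 0; ss_ws <- 0; ss_pws <- 0
  for (p in rownames(ypw)) for (w in colnames(ypw))
    ss_pw <- ss_pw + 2 * (ypw[p, w] - yp[p] - yw[w] + g)^2
  for (p in rownames(yps)) for (s in colnames(yps))
    ss_ps <- ss_ps + 2 * (yps[p, s] - yp[p] - ys[s] + g)^2
  for (w in rownames(yws)) for (s in colnames(yws))
    ss_ws <- ss_ws + P * (yws[w, s] - yw[w] - ys[s] + g)^2
  for (i in seq_len(nrow(cm))) {
    p <- as.character(cm$participant[i]); w <- cm$window[i]; s <- cm$side[i]
    ss_pws <- ss_pws + (cm$value[i] - ypw[p, w] - yps[p, s] - yws[w, s] +
                          yp[p] + yw[w] + ys[s] - g)^2
  }
  lapply(list(ss_p = ss_p, ss_w = ss_w, ss_s = ss_s, ss_ws = ss_ws,
              ss_pw = ss_pw, ss_ps = ss_ps, ss_pws = ss_pws,
              f_w = (ss_w / 1) / (ss_pw / (P - 1)),
              f_s = (ss_s / 1) / (ss_ps / (P - 1)),
              f_ws = (ss_ws / 1) / (ss_pws / (P - 1))),
         unname)
}

test_that("mixed ANOVA equals a hand-worked EMS decomposition", {
  set.seed(12)
  tab <- synth_table(n_participants = 3, n_trials = 4)
  a <- mixed_anova(tab, "mean")
  cm <- aggregate(mean ~ participant + window + side, tab, mean)
  names(cm)[names(cm) == "mean"] <- "value"
  or <- ems_oracle(cm)
  expect_equal(a$statistic[a$effect == "window"], or$f_w)
  expect_equal(a$statistic[a$effect == "side"], or$f_s)
  expect_equal(a$statistic[a$effect == "window:side"], or$f_ws)
  expect_equal(a$sumsq[a$effect == "participant"], or$ss_p)
  expect_equal(a$sumsq[a$effect == "window"], or$ss_w)
  # sums of squares are additive on the balanced cell-mean table
  total <- sum((cm$value - mean(cm$value))^2)
  parts <- or$ss_p + or$ss_w + or$ss_s + or$ss_ws + or$ss_pw + or$ss_ps +
    or$ss_pws
  expect_equal(parts, total)
  # p-values from the right reference distributions
  expect_equal(a$p.value[a$effect == "window"],
               stats::pf(or$f_w, 1, 2, lower.tail = FALSE))
})

test_that("an exactly reproduced window effect is flagged with p = 0", {
  set.seed(15)
  tab <- synth_table(n_participants = 3, n_trials = 2)
  tab$mean[tab$window == "post"] <-
    tab$mean[tab$window == "pre"] + 1  # same trial order: exact +1 K
  a <- mixed_anova(tab, "mean")
  i <- a$effect == "window"
  expect_true(is.infinite(a$statistic[i]))
  expect_identical(a$p.value[i], 0)
  expect_true(attr(a, "zero_denominator"))
})

test_that("incomplete designs are refused with a named cell", {
  set.seed(16)
  tab <- synth_table(n_participants = 3, n_trials = 2)
  drop <- tab$participant == 2 & tab$window == "post" & tab$side == "left"
  expect_error(mixed_anova(tab[!drop, ], "mean"), "participant 2")
  expect_error(mixed_anova(tab[tab$participant == 1, ], "mean"),
               "2 participants")
})

test_that("a large injected shift is detected, a null one is not biased", {
  set.seed(18)
  tab <- synth_table(n_participants = 4, n_trials = 10, shift = 0.3,
                     noise_sd = 0.02)
  a <- mixed_anova(tab, "mean")
  expect_lt(a$p.value[a$effect == "window"], 0.001)
  # unbalanced data: dropping trials changes nothing structurally
  tab2 <- tab[-(1:4), ]
  a2 <- mixed_anova(tab2, "mean")
  expect_lt(a2$p.value[a2$effect == "window"], 0.001)
})

test_that("the report tabulates group means and marks significant pairs", {
  set.seed(20)
  tab <- synth_table(n_participants = 4, n_trials = 6, shift = 0.5,
                     noise_sd = 0.01)
  rep_ <- build_report(tab)
  s <- rep_$subsets$all_stimulus
  expect_false(s$empty)
  expect_identical(s$n_trials, 24L)
  # group means recomputed independently
  m_pre <- mean(tab$mean[tab$window == "pre"])
  got <- s$table[s$table$measure == "mean" & s$table$level == "pre", ]
  expect_equal(got$mean, m_pre)
  # the forced window effect marks both pre and post
  win_rows <- s$table[s$table$measure == "mean" &
                        s$table$factor == "window", ]
  expect_true(all(win_rows$sig))
  # empty startle subset is marked, not an error
  expect_true(rep_$subsets$formal_startle$empty)
  md <- format_report_md(rep_)
  expect_true(any(grepl("empty subset", md)))
  # single-trial degenerate summary: mean equals the trial, sd 0
  one <- tab[tab$participant == 1 & tab$trial == 1, ]
  rep1 <- build_report(one)
  t1 <- rep1$subsets$all_stimulus$table
  expect_true(all(t1$sd[t1$measure == "entropy"] == 0))
})
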