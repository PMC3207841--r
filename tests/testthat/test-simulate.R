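test_that("trial structure respects the stimulus contract", {
  cfg <- tiny_phantom()
  tr <- simulate_trial(cfg, TRUE, seed = 2, render = "series")
  expect_true(tr$stimulus_flag)
  expect_gte(tr$t_stim, 2)
  expect_lte(tr$t_stim, cfg$trial_duration - 7)
  tr0 <- simulate_trial(cfg, FALSE, seed = 2, render = "series")
  expect_true(is.na(tr0$t_stim))
  expect_false(tr0$ground_truth$startle_occurred)
  # ambient stream: strictly increasing 1 Hz timestamps
  expect_equal(diff(tr$ambient$timestamp_s),
               rep(1, nrow(tr$ambient) - 1))
  expect_true(all(tr$ambient$airspeed_mps >= 0))
})

test_that("zero stochastic amplitudes give the exact analytic phantom", {
  cfg <- tiny_phantom(noise_sd = 0, jitter_sd = 0, drift_amplitude = 0)
  tr <- simulate_trial(cfg, FALSE, seed = 3, render = "frames")
  base <- make_frame(cfg, noise = FALSE)
  attributes(base) <- attributes(base)["dim"]
  for (f in c(1, 50, 150)) {
    expect_identical(tr$stack$data[, , f], base)
  }
  # and the series-level model is constant once its noise is off too
  cfg0 <- tiny_phantom(noise_sd = 0, jitter_sd = 0, drift_amplitude = 0,
                       series_noise_sd = 0)
  s <- simulate_trial(cfg0, FALSE, seed = 3, render = "series")
  expect_identical(diff(range(s$series$left$values)), 0)
})

test_that("identical seeds reproduce trials bit for bit", {
  cfg <- tiny_phantom()
  a <- simulate_trial(cfg, TRUE, seed = 9, render = "frames")
  b <- simulate_trial(cfg, TRUE, seed = 9, render = "frames")
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$t_stim, b$t_stim)
  expect_identical(a$ground_truth$offsets, b$ground_truth$offsets)
})

test_that("study composition is balanced, interleaved and reproducible", {
  cfg <- tiny_phantom()
  st <- simulate_study(cfg, n_participants = 2, n_sessions = 2,
                       n_trials = 4, seed = 5, render = "series")
  expect_length(st, 16)
  meta <- do.call(rbind, lapply(st, function(x)
    data.frame(p = x$participant_id, s = x$session_index,
               flag = x$stimulus_flag,
               poff = x$ground_truth$participant_offset)))
  # exactly half the trials of every session carry the stimulus
  tab <- aggregate(flag ~ p + s, meta, sum)
  expect_true(all(tab$flag == 2))
  # participant random effect drawn once per participant
  expect_length(unique(meta$poff[meta$p == 1]), 1)
  expect_length(unique(meta$poff), 2)
  # determinism of the whole schedule
  st2 <- simulate_study(cfg, 2, 2, 4, seed = 5, render = "series")
  expect_identical(lapply(st, function(x) x$t_stim),
                   lapply(st2, function(x) x$t_stim))
  expect_identical(st[[7]]$series$left$values, st2[[7]]$series$left$values)
  # minimal study: one stimulus, one non-stimulus trial
  st1 <- simulate_study(cfg, 1, 1, 2, seed = 1, render = "series")
  expect_equal(sum(vapply(st1, function(x) x$stimulus_flag, logical(1))), 1)
  expect_error(simulate_study(cfg, 1, 1, 3, seed = 1),
               class = "periotherm_config_error")
})

test_that("injected effect obeys the closed-form ramp average", {
  # same seed, configs differing only in effect_delta: the series
  # difference is exactly the injected effect time course
  cfg_on <- tiny_phantom(effect_delta = 0.3)
  cfg_off <- tiny_phantom(effect_delta = 0)
  on <- simulate_trial(cfg_on, TRUE, seed = 31, render = "series")
  off <- simulate_trial(cfg_off, TRUE, seed = 31, render = "series")
  expect_identical(on$t_stim, off$t_stim)
  dser <- on$series$left$values - off$series$left$values
  wp_idx <- extract_windows(temperature_series(dser, 15), on$t_stim)
  t_post <- (wp_idx$post_idx[1]:wp_idx$post_idx[2] - 1) / 15
  ramp_mean <- mean(effect_ramp(t_post, on$t_stim,
                                cfg_on$effect_latency,
                                cfg_on$effect_ramp_duration))
  expect_equal(mean(wp_idx$post), 0.3 * ramp_mean, tolerance = 1e-12)
  # pre window is untouched
  expect_identical(max(abs(wp_idx$pre)), 0)
})

test_that("startle ground truth appears only on stimulus trials", {
  cfg <- tiny_phantom(startle_prob = 1)
  tr <- simulate_trial(cfg, TRUE, seed = 4, render = "series")
  expect_true(tr$ground_truth$startle_occurred)
  gt <- tr$ground_truth
  tj <- (gt$jerk_frame - 1) / 15
  expect_gte(tj, tr$t_stim)
  expect_lte(tj, tr$t_stim + 3 + 1 / 15)
  expect_false(simulate_trial(cfg, FALSE, seed = 4,
                              render = "series")$ground_truth$startle_occurred)
})
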