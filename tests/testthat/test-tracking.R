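test_that("MSE matches a per-pixel loop oracle", {
  set.seed(8)
  a <- matrix(rnorm(64, 300, 0.5), 8)
  b <- matrix(rnorm(64, 300, 0.5), 8)
  acc <- 0
  for (i in 1:8) for (j in 1:8) acc <- acc + (a[i, j] - b[i, j])^2
  expect_equal(mse_score(a, b), acc / 64)
  expect_identical(mse_score(a, a), 0)
  expect_equal(mse_score(a, a + 0.1), 0.01, tolerance = 1e-9)
  expect_error(mse_score(a, matrix(0, 4, 4)))
})

test_that("cross-search equals the exhaustive oracle on translations", {
  cfg <- phantom_config(noise_sd = 0)
  r <- centered_roi(cfg)
  set.seed(13)
  ds <- cbind(sample(-8:8, 25, TRUE), sample(-8:8, 25, TRUE))
  ds <- rbind(c(0, 0), c(3, -2), ds)
  for (i in seq_len(nrow(ds))) {
    pr <- translate_pair(cfg, ds[i, ], r)
    cs <- cross_search(pr$ref, pr$frame, pr$pos, max_step = 8)
    fs_ <- full_search(pr$ref, pr$frame, pr$pos, radius = 8)
    expect_identical(cs$d, as.integer(ds[i, ]))
    expect_identical(fs_$d, as.integer(ds[i, ]))
    expect_identical(cs$mse, 0)
  }
})

test_that("beyond-range translations never beat the exhaustive oracle", {
  cfg <- phantom_config(noise_sd = 0)
  r <- centered_roi(cfg)
  pr <- translate_pair(cfg, c(9, 0), r)
  cs <- cross_search(pr$ref, pr$frame, pr$pos, max_step = 8)
  fs_ <- full_search(pr$ref, pr$frame, pr$pos, radius = 10)
  expect_gte(cs$mse, fs_$mse)
})

test_that("cross-search visits far fewer candidates than full search", {
  cfg <- phantom_config(noise_sd = 0)
  r <- centered_roi(cfg)
  set.seed(17)
  for (i in 1:10) {
    d <- sample(-8:8, 2, TRUE)
    pr <- translate_pair(cfg, d, r)
    cs <- cross_search(pr$ref, pr$frame, pr$pos, max_step = 8)
    expect_lt(cs$n_eval, 60)
    expect_lt(cs$n_eval, (2 * 8 + 1)^2)
  }
})

test_that("search preconditions and failure signals", {
  cfg <- tiny_phantom(noise_sd = 0)
  fr <- make_frame(cfg, noise = FALSE)
  expect_error(cross_search(matrix(0, 100, 100), fr, c(1, 1)),
               "larger than frame")
  expect_error(cross_search(fr[1:5, 1:5], fr, c(1, 1), max_step = 6),
               "power of two")
  # predicted position so far outside that every candidate is invalid
  res <- cross_search(fr[1:5, 1:5], fr, c(500, 500), max_step = 8)
  expect_true(res$lost)
})

test_that("tracking recovers a known random walk exactly", {
  # full-size phantom: the face ellipse leaves ~25 px of margin around
  # the canthus, so this seed's walk (max excursion 21 px) stays on-face
  cfg <- phantom_config(trial_duration = 10, jitter_sd = 1,
                        drift_amplitude = 0.02)
  tr <- simulate_trial(cfg, FALSE, seed = 14, render = "frames")
  expect_lte(max(abs(tr$ground_truth$offsets)), 24)
  r <- centered_roi(cfg)
  tk <- track_region(tr$stack, r)
  expect_false(tk$failed)
  rec <- sweep(tk$pos, 2, c(r$top, r$left), "-")
  expect_equal(unname(rec), unname(tr$ground_truth$offsets))
  # static noiseless stack: every ROI at the reference, all scores 0
  cfg0 <- tiny_phantom(noise_sd = 0, jitter_sd = 0, drift_amplitude = 0)
  tr0 <- simulate_trial(cfg0, FALSE, seed = 1, render = "frames")
  tk0 <- track_region(tr0$stack, r)
  expect_true(all(tk0$pos[, 1] == r$top & tk0$pos[, 2] == r$left))
  expect_true(all(tk0$scores == 0))
})

test_that("tracking is translation-equivariant", {
  cfg <- tiny_phantom(noise_sd = 0, jitter_sd = 1, drift_amplitude = 0)
  tr <- simulate_trial(cfg, FALSE, seed = 19, render = "frames")
  sub <- thermal_stack(tr$stack$data[, , 1:40], 15)
  d <- dim(sub$data)
  sh <- c(3, 4)
  shifted <- array(cfg$background_temp, d)
  shifted[(1 + sh[1]):d[1], (1 + sh[2]):d[2], ] <-
    sub$data[1:(d[1] - sh[1]), 1:(d[2] - sh[2]), ]
  r <- centered_roi(cfg, height = 9, width = 11)
  r_sh <- roi(r$top + sh[1], r$left + sh[2], r$height, r$width)
  tk <- track_region(sub, r)
  tk_sh <- track_region(thermal_stack(shifted, 15), r_sh)
  expect_false(tk$failed || tk_sh$failed)
  expect_equal(unname(sweep(tk_sh$pos, 2, sh, "-")), unname(tk$pos))
})

test_that("a region walking off the face fails the track near the edge", {
  cfg <- phantom_config()
  n <- 60
  offs <- cbind(-(seq_len(n) - 1), rep(0, n))  # walks up 1 px/frame
  set.seed(44)
  arr <- array(NA_real_, c(cfg$frame_rows, cfg$frame_cols, n))
  for (i in seq_len(n))
    arr[, , i] <- make_frame(cfg, offset = offs[i, ])
  stack <- thermal_stack(arr, 15)
  r <- centered_roi(cfg)  # 11 x 15 around (52, 68)
  tk <- track_region(stack, r)
  expect_true(tk$failed)
  # ground-truth edge crossing: the tracked block (5 rows above the spot)
  # first includes off-face background when the spot's row drops below
  # the face ellipse boundary at the block's columns (+5 rows)
  cols <- (r$left):(r$left + r$width - 1)
  face_top <- max(cfg$face_center[1] - cfg$face_semiaxes[1] *
                    sqrt(pmax(0, 1 - ((cols - cfg$face_center[2]) /
                                        cfg$face_semiaxes[2])^2)))
  spot_row <- cfg$canthus_centers[1, 1] + offs[, 1]
  i_edge <- which(spot_row - 5 < face_top)[1]
  expect_lte(abs(tk$failure_frame - i_edge), 5)
})

test_that("sustained score blow-up fails the track at the run start", {
  cfg <- tiny_phantom(noise_sd = 0, jitter_sd = 0, drift_amplitude = 0)
  tr <- simulate_trial(cfg, FALSE, seed = 1, render = "frames")
  arr <- tr$stack$data[, , 1:40]
  arr[, , 21:40] <- cfg$face_temp  # the scene vanishes at frame 21
  tk <- track_region(thermal_stack(arr, 15), centered_roi(cfg, height = 9,
                                                          width = 11))
  expect_true(tk$failed)
  expect_identical(tk$failure_frame, 21L)
})
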