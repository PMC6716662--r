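test_that("band-pass rejects DC and keeps the pass band", {
  fs <- 100
  t <- (0:1999) / fs
  # constant gravity: nothing left after the filter
  out <- bandpass_filter(rep(9.80665, 2000), fs)
  expect_lt(max(abs(out)), 1e-6)
  # 1.8 Hz tone passes nearly unattenuated
  y <- bandpass_filter(sin(2 * pi * 1.8 * t), fs)
  expect_gte(max(abs(y[500:1500])), 0.9)
  # 0.1 Hz tone is strongly attenuated; oracle = squared magnitude response
  # of the designed filter (forward-backward application)
  y_lo <- bandpass_filter(sin(2 * pi * 0.1 * t), fs)
  bf <- signal::butter(4, c(0.7, 3) / (fs / 2), type = "pass")
  w <- 2 * pi * 0.1 / fs
  resp <- function(cf) sum(cf * exp(-1i * w * (seq_along(cf) - 1)))
  H <- Mod(resp(bf$b) / resp(bf$a))^2
  meas <- max(abs(y_lo[500:1500]))
  expect_lte(meas, 0.1)
  expect_lt(abs(meas - H), 0.5 * H + 1e-4)
})

test_that("filter is linear and errors on too-short input", {
  set.seed(4)
  x <- rnorm(1000)
  # near-unit-circle poles amplify rounding, so exact scaling holds only to
  # about single precision
  expect_lt(max(abs(bandpass_filter(3.7 * x, 100) -
                      3.7 * bandpass_filter(x, 100))), 1e-5)
  expect_error(bandpass_filter(rnorm(50), 100), "too short")
})

test_that("window segmentation geometry matches the overlap contract", {
  mk <- function(dur) tone_recording(1.8, 1, duration = dur)
  expect_length(segment_windows(mk(10)), 7)     # floor((10-2.5)/1.25)+1
  expect_length(segment_windows(mk(2.5)), 1)
  expect_warning(w0 <- segment_windows(mk(2.4)), "shorter")
  expect_length(w0, 0)
  wins <- segment_windows(mk(10))
  expect_equal(wins[[2]]$t_start - wins[[1]]$t_start, 1.25)
  expect_equal(wins[[1]]$length, 2.5)
  # windows cover the recording to its end
  last <- wins[[length(wins)]]
  expect_gte(last$t_start + last$length, 10 - 1e-9)
})

test_that("dominant frequency recovers an in-band tone within 0.1 Hz", {
  rec <- tone_recording(2.0, 1.5, noise_sd = 0.05)
  feats <- window_features(rec)
  expect_true(all(abs(feats$f_dom_x - 2.0) <= 0.1))
  expect_true(all(feats$plausible))
})

test_that("white noise yields no dominant frequency", {
  set.seed(9)
  n <- 1000
  rec <- accel_recording(ax = 9.80665 + rnorm(n, sd = 0.01),
                         ay = rnorm(n, sd = 0.01),
                         az = rnorm(n, sd = 0.01), fs = 100)
  feats <- window_features(rec)
  expect_true(all(is.na(feats$f_dom_x)))
  expect_true(all(is.na(feats$f_dom_y)))
  expect_true(all(is.na(feats$f_dom_z)))
  expect_false(any(feats$plausible))
})

test_that("rest and posture gates fire with the documented reasons", {
  # device lying flat: gravity on z, not x
  n <- 1000
  set.seed(10)
  flat <- accel_recording(ax = rnorm(n, sd = 0.3),
                          ay = rnorm(n, sd = 0.3),
                          az = 9.80665 + sin(2 * pi * 1.8 * (1:n) / 100) +
                            rnorm(n, sd = 0.3), fs = 100)
  ff <- window_features(flat)
  expect_false(any(ff$plausible))
  expect_true(all(ff$reason == "gravity_angle"))
  expect_true(all(ff$gravity_angle >= 0 & ff$gravity_angle <= 180))
  # still upright device: zeros plus gravity
  still <- accel_recording(ax = rep(9.80665, n), ay = numeric(n),
                           az = numeric(n), fs = 100)
  fs_ <- window_features(still)
  expect_lt(max(fs_$activity), 1e-6)
  expect_lt(max(fs_$gravity_angle), 1e-6)
  expect_true(all(fs_$reason %in% c("low_activity", "no_dominant_freq")))
  expect_true(all(fs_$activity >= 0))
})

test_that("raising the activity floor never makes a window plausible", {
  sim <- walk_sim(0.6, duration = 20, seed = 11)
  feats <- window_features(sim$recording)
  for (min_act in c(0.2, 0.5, 1, 5)) {
    thr <- plausibility_thresholds(min_activity = min_act)
    gated <- check_plausibility(feats, thr)
    expect_true(all(which(gated$plausible) %in% which(feats$plausible)))
    feats <- gated
  }
})
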