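test_that("analytic features recover a pure tone's amplitude and frequency", {
  rec <- tone_recording(2.0, 1.5, duration = 10)
  wins <- segment_windows(rec)
  af <- narrowband_analytic(wins[[4]], 2.0)  # interior window
  core <- 50:200  # away from window edges
  expect_lt(max(abs(af$A[core, "x"] - 1.5) / 1.5), 0.02)
  expect_lt(max(abs(af$F[core, "x"] - 2.0) / 2.0), 0.02)
  # unwrapped vertical phase is non-decreasing and F = dP/dt / 2pi
  expect_true(all(diff(af$P[, "x"]) >= 0))
  expect_equal(af$F[2:250, "x"], diff(af$P[, "x"]) * 100 / (2 * pi))
})

test_that("envelope tracks an amplitude-modulated tone within 5%", {
  fs <- 100
  t <- (0:1999) / fs
  env_true <- 1 + 0.3 * sin(2 * pi * 0.2 * t)
  rec <- accel_recording(ax = 9.80665 + env_true * sin(2 * pi * 2 * t),
                         ay = numeric(2000), az = numeric(2000), fs = fs)
  wins <- segment_windows(rec)
  af <- narrowband_analytic(wins[[8]], 2.0)
  idx <- round(af$time * fs) + 1
  rel_err <- abs(af$A[, "x"] - env_true[idx]) / env_true[idx]
  expect_lt(max(rel_err), 0.05)
})

test_that("zero signal yields zero envelope and no steps", {
  n <- 250
  win <- structure(list(index = 1L, t_start = 0, length = 2.5, hop = 1.25,
                        fs = 100,
                        filtered = matrix(0, n, 3,
                                          dimnames = list(NULL, c("x", "y", "z"))),
                        raw = matrix(rep(c(9.80665, 0, 0), each = n), n, 3,
                                     dimnames = list(NULL, c("x", "y", "z")))),
                   class = "analysis_window")
  af <- narrowband_analytic(win, 1.8)
  expect_lt(max(af$A), 1e-8)
  expect_equal(nrow(extract_steps_wave(af)), 0)
})

test_that("step count on steady tones matches cycles within one step", {
  # 1.8 Hz vertical tone, 10 s: 18 cycles
  rec <- tone_recording(1.8, 1.5, duration = 10, noise_sd = 0.02)
  steps <- detect_steps_wave(rec)
  expect_lte(abs(nrow(steps) - 18), 1)
  # slow cadence 1.2 Hz (speed 0.25 under the default cadence law), 10 s
  sim <- walk_sim(0.25, duration = 10, seed = 5)
  st <- detect_steps_wave(sim$recording)
  expect_lte(abs(nrow(st) - 12), 1)
  expect_true(all(abs(st$F - 1.2) < 0.15))
  expect_true(all(st$duration >= 0.2 & st$duration <= 2.0))
  expect_true(all(st$t_end > st$t_start))
  expect_true(all(diff(st$t_start) > 0))
})

test_that("doubling the signal doubles amplitudes, not counts or cadence", {
  sim <- walk_sim(0.8, duration = 30, seed = 6)
  rec <- sim$recording
  rec2 <- accel_recording(ax = 2 * rec$ax, ay = 2 * rec$ay, az = 2 * rec$az,
                          fs = rec$fs)
  s1 <- detect_steps_wave(rec)
  s2 <- detect_steps_wave(rec2)
  expect_equal(nrow(s1), nrow(s2))
  expect_equal(s2$Ax, 2 * s1$Ax, tolerance = 1e-6)
  expect_equal(s2$Ay, 2 * s1$Ay, tolerance = 1e-6)
  expect_equal(s2$Az, 2 * s1$Az, tolerance = 1e-6)
  expect_equal(s2$F, s1$F, tolerance = 1e-6)
})

test_that("merging overlapping-window detections is exact and idempotent", {
  sim <- walk_sim(1.0, duration = 60, seed = 7)
  merged <- detect_steps_wave(sim$recording)
  expect_lte(abs(nrow(merged) - length(sim$truth$step_times)), 1)
  # identical duplicate lists collapse to one copy
  st <- random_steps(10)
  st$source_window <- 1L
  dup <- st
  dup$source_window <- 2L
  pooled <- rbind(st, dup)
  class(pooled) <- c("step_events", "data.frame")
  centers <- c(5, 5.1)
  out <- merge_window_steps(pooled, centers)
  expect_equal(nrow(out), nrow(st))
  expect_equal(out$t_start, st$t_start)
  # disjoint windows concatenate
  late <- random_steps(5)
  late$t_start <- late$t_start + 100
  late$source_window <- 2L
  pooled2 <- rbind(st, late)
  class(pooled2) <- c("step_events", "data.frame")
  expect_equal(nrow(merge_window_steps(pooled2, centers)), 15)
})

test_that("constant-phase input produces no steps", {
  af <- structure(list(
    time = (0:249) / 100,
    A = matrix(1, 250, 3, dimnames = list(NULL, c("x", "y", "z"))),
    P = matrix(2, 250, 3, dimnames = list(NULL, c("x", "y", "z"))),
    F = matrix(0, 250, 3, dimnames = list(NULL, c("x", "y", "z"))),
    f_dom = 1.8, window_index = 1L, t_center = 1.25),
    class = "analytic_features")
  expect_equal(nrow(extract_steps_wave(af)), 0)
})

test_that("steps survive a text round-trip", {
  st <- random_steps(8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_steps(st, path)
  back <- read_steps(path)
  expect_equal(back$t_start, st$t_start)
  expect_equal(back$Ax, st$Ax)
  expect_s3_class(back, "step_events")
})
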