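test_that("wheel phase advances by 2*pi per rotation", {
  tt <- seq(0, 10, by = 0.01)
  # constant 1 m/s push on a 1 m wheel: 1 Hz rotation, 10 s -> 20*pi
  rec <- simulate_wheel(tt, rep(1, length(tt)), noise_sd = 0.02, seed = 31)
  ph <- wheel_rotation_phase(rec)
  expect_false(ph$stationary)
  expect_lt(abs((max(ph$phase) - min(ph$phase)) - 20 * pi), 0.5)
})

test_that("a stationary wheel is flagged and yields no speed events", {
  tt <- seq(0, 10, by = 0.01)
  rec <- simulate_wheel(tt, rep(0, length(tt)), noise_sd = 0.02, seed = 32)
  ph <- wheel_rotation_phase(rec)
  expect_true(ph$stationary)
  ref <- wheel_speed_series(ph)
  expect_length(ref$event_times, 0)
  expect_equal(ref$total_distance, 0)
})

test_that("a speed ramp integrates to the closed-form phase", {
  tt <- seq(0, 10, by = 0.01)
  v <- seq(0.5, 1.5, length.out = length(tt))  # rotation 0.5 -> 1.5 Hz
  rec <- simulate_wheel(tt, v, noise_sd = 0.01, seed = 33)
  ph <- wheel_rotation_phase(rec)
  advance <- max(ph$phase) - min(ph$phase)
  expect_lt(abs(advance - 2 * pi * 10) / (2 * pi * 10), 0.01)
  # speeding up: phase increments grow
  d <- diff(ph$phase)
  mid <- length(d) %/% 2
  expect_gt(mean(d[(mid + 1):length(d)]), mean(d[1:mid]))
})

test_that("interval speeds equal rotation frequency times circumference", {
  tt <- seq(0, 20, by = 0.01)
  rec <- simulate_wheel(tt, rep(1, length(tt)), noise_sd = 0.02, seed = 34)
  ref <- wheel_speed_series(wheel_rotation_phase(rec))
  expect_true(all(abs(ref$speeds - 1.0) < 0.02))
  # quarter-rotation events: 25 cm spatial resolution on a 1 m wheel
  expect_equal(ref$total_distance / length(ref$event_times), 0.25)
  # homogeneity: half the rotation rate, half the speed
  rec2 <- simulate_wheel(tt, rep(0.5, length(tt)), noise_sd = 0.02, seed = 34)
  ref2 <- wheel_speed_series(wheel_rotation_phase(rec2))
  expect_lt(abs(mean(ref2$speeds) - 0.5 * mean(ref$speeds)), 0.02)
  # total distance matches circumference x rotations within a quarter turn
  expect_lt(abs(ref$total_distance - 20), 0.25 + 1e-9)
})

test_that("section means are distance-weighted", {
  # two 25 cm intervals at 0.5 and 1.5 m/s: 0.5 m over (0.5 + 1/6) s
  ref <- structure(list(event_times = c(0, 0.5, 0.5 + 1 / 6),
                        speeds = c(0.5, 1.5), total_distance = 0.5),
                   class = "reference_speed_series")
  sec <- section_definitions("all", 0, 1)
  out <- section_mean_speeds(ref, sec)
  expect_equal(out$speed, 0.75)
  # uniform speed gives the uniform mean in every section
  tt <- seq(0, 30, by = 0.01)
  rec <- simulate_wheel(tt, rep(1, length(tt)), noise_sd = 0.02, seed = 35)
  refu <- wheel_speed_series(wheel_rotation_phase(rec))
  secs <- section_definitions(c("a", "b", "stairs"), c(0, 10, 20),
                              c(10, 20, 30),
                              include_in_speed = c(TRUE, TRUE, FALSE))
  outu <- section_mean_speeds(refu, secs)
  expect_equal(nrow(outu), 2)  # stairs excluded
  expect_true(all(abs(outu$speed - 1.0) < 0.02))
})

test_that("estimate/reference pairing is an inner join on subject and section", {
  est <- expand.grid(subject = sprintf("S%d", 1:5),
                     section = sprintf("sec%d", 1:6),
                     stringsAsFactors = FALSE)
  est$speed <- runif(nrow(est), 0.5, 1.5)
  ref <- est
  ref$speed <- ref$speed + 0.01
  paired <- pair_estimates_with_reference(est, ref)
  expect_equal(nrow(paired), 30)
  expect_named(paired, c("subject", "section", "estimated", "reference"))
  # a missing row on one side drops exactly that pair
  expect_message(p2 <- pair_estimates_with_reference(est[-1, ], ref),
                 "unmatched")
  expect_equal(nrow(p2), 29)
  expect_warning(p0 <- pair_estimates_with_reference(
    est[0, ], ref), "no common")
  expect_equal(nrow(p0), 0)
})
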