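test_that("design rows are the amplitudes and pairwise products", {
  st <- random_steps(2)
  st$Ax <- c(0, 2); st$Ay <- c(0, 1); st$Az <- c(0, 3)
  X <- build_design_row(st)
  expect_equal(unname(X[1, ]), c(1, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(X[2, ]), c(1, 2, 1, 3, 2, 6, 3))
  # scaling amplitudes by c scales interactions by c^2
  st2 <- st
  st2$Ax <- 3 * st$Ax; st2$Ay <- 3 * st$Ay; st2$Az <- 3 * st$Az
  X2 <- build_design_row(st2)
  expect_equal(X2[, c("AxAy", "AxAz", "AyAz")],
               9 * X[, c("AxAy", "AxAz", "AyAz")])
  st$Ax[1] <- NA
  expect_error(build_design_row(st), "missing amplitudes")
})

test_that("ordinary least squares recovers a planted amplitude-speed law", {
  st <- random_steps(200, seed = 21)
  set.seed(22)
  v <- 0.1 + 0.4 * st$Ax + rnorm(200, sd = 0.02)
  m <- fit_speed_model(st, v)
  cf <- coef(m)
  expect_lt(abs(cf[["Ax"]] - 0.4) / 0.4, 0.10)
  expect_true(all(abs(cf[c("Ay", "Az", "AxAy", "AxAz", "AyAz")]) < 0.05))
  expect_lt(m$sigma, 0.04)
  # duplicating the training set leaves the fit unchanged
  m2 <- fit_speed_model(rbind(st, st), c(v, v))
  expect_equal(coef(m2), cf, tolerance = 1e-10)
})

test_that("fit preconditions are enforced", {
  st <- random_steps(3)
  expect_error(fit_speed_model(st, c(1, 1, 1)), "at least 20")
  st20 <- random_steps(25)
  expect_error(fit_speed_model(st20, rep(-1, 25)), "positive")
  collinear <- st20
  collinear$Ay <- collinear$Ax  # AxAy becomes Ax^2, AyAz == AxAz
  expect_error(fit_speed_model(collinear, rep(1, 25)), "collinear")
})

test_that("prediction applies the coefficients and clips to [0, 3] m/s", {
  m <- structure(list(coefficients = c(intercept = 1.1, Ax = 0, Ay = 0,
                                       Az = 0, AxAy = 0, AxAz = 0, AyAz = 0),
                      n_steps = 20L, sigma = 0, recipe = "amp_pairwise_v1"),
                 class = "speed_model")
  st <- random_steps(5)
  expect_equal(predict(m, st)$speed, rep(1.1, 5))
  m$coefficients["intercept"] <- -5
  expect_equal(predict(m, st)$speed, rep(0, 5))
  m$coefficients["intercept"] <- 99
  expect_equal(predict(m, st)$speed, rep(3, 5))
  # permutation invariance of the prediction set
  m$coefficients <- c(intercept = 0.2, Ax = 0.5, Ay = 0.1, Az = 0.1,
                      AxAy = 0, AxAz = 0, AyAz = 0)
  p1 <- predict(m, st)$speed
  p2 <- predict(m, st[5:1, ])$speed
  expect_equal(sort(p1), sort(p2))
})

test_that("held-out slow walks are recovered within 0.05 m/s", {
  speeds <- c(0.5, 0.7, 0.9, 1.2)
  detected <- lapply(seq_along(speeds), function(i)
    detect_steps_wave(walk_sim(speeds[i], 45, seed = 23 + i)$recording))
  st_all <- do.call(rbind, detected)
  v_all <- rep(speeds, vapply(detected, nrow, 0L))
  m <- fit_speed_model(st_all, v_all)
  held <- walk_sim(0.6, duration = 60, seed = 25)
  pred <- predict(m, detect_steps_wave(held$recording))
  expect_lt(abs(mean(pred$speed) - 0.6), 0.05)
})

test_that("section aggregation averages steps and excludes stairs", {
  est <- structure(data.frame(t_start = c(1, 2, 11, 12),
                              speed = c(1.0, 1.2, 0.5, 0.7)),
                   class = c("speed_estimates", "data.frame"))
  sec <- section_definitions(name = c("hall", "stairs", "empty"),
                             t_start = c(0, 10, 20), t_end = c(10, 20, 30),
                             include_in_speed = c(TRUE, FALSE, TRUE))
  expect_warning(agg <- aggregate_section_speed(est, sec), "empty")
  expect_equal(agg$speed[agg$section == "hall"], 1.1)
  expect_false("stairs" %in% agg$section)
  expect_true(is.na(agg$speed[agg$section == "empty"]))
})

test_that("a serialized model predicts identically after reload", {
  st <- random_steps(40, seed = 26)
  set.seed(27)
  m <- fit_speed_model(st, 0.2 + 0.3 * st$Ax + 0.1 * st$Az + rnorm(40, sd = 0.01))
  path <- withr::local_tempfile(fileext = ".model")
  write_speed_model(m, path)
  m2 <- read_speed_model(path)
  expect_identical(coef(m2), coef(m))
  expect_equal(predict(m2, st)$speed, predict(m, st)$speed)
})
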