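#' Synthetic gait scenario
#'
#' Parameterizes a synthetic waist-level walking recording as a sequence of
#' segments (walk / rest / stairs) with true speeds, plus the kinematic
#' coupling laws that make speed recoverable from the signal:
#' cadence law `f_step = cadence[1] + cadence[2] * v` (Hz) and per-axis
#' amplitude laws `A = alpha + beta * v` (m/s^2). Defaults place cadence in
#' the 0.7-3 Hz walking band over speeds 0.4-1.5 m/s and give the vertical
#' axis the strongest, monotone speed-amplitude coupling (which is what
#' makes an amplitude-only linear speed model identifiable).
#'
#' @param segments `data.frame` with columns `duration` (s), `speed` (m/s)
#'   and `activity` (`"walk"`, `"rest"` or `"stairs"`).
#' @param cadence `c(a, b)` of the cadence law, default `c(1.0, 0.8)`.
#' @param amp_x,amp_y,amp_z `c(alpha, beta)` of the per-axis amplitude laws;
#'   defaults `c(0.5, 1.5)`, `c(0.2, 0.5)`, `c(0.3, 1.0)` m/s^2.
#' @param noise_sd White sensor-noise SD, m/s^2 (default 0.15).
#' @param tilt Device tilt from vertical, degrees (default 5).
#' @param harmonic2 Relative amplitude of the second vertical harmonic
#'   (default 0.3); makes spectra realistic and exercises dominant-peak
#'   selection.
#' @param fs Sampling rate, Hz (default 100).
#' @param seed Integer seed; a fixed seed makes the simulation reproducible
#'   bit for bit.
#' @return A list of class `gait_scenario`.
#' @export
gait_scenario <- function(segments, cadence = c(1.0, 0.8),
                          amp_x = c(0.5, 1.5), amp_y = c(0.2, 0.5),
                          amp_z = c(0.3, 1.0), noise_sd = 0.15, tilt = 5,
                          harmonic2 = 0.3, fs = 100, seed = 1L) {
  stopifnot(is.data.frame(segments),
            all(c("duration", "speed", "activity") %in% names(segments)),
            all(segments$duration > 0), all(segments$speed >= 0),
            all(segments$activity %in% c("walk", "rest", "stairs")))
  moving <- segments$activity != "rest"
  f_step <- cadence[1] + cadence[2] * segments$speed[moving]
  if (any(f_step < 0.7 | f_step > 3))
    stop("cadence outside 0.7-3 Hz for a walk segment")
  structure(list(segments = segments, cadence = cadence, amp_x = amp_x,
                 amp_y = amp_y, amp_z = amp_z, noise_sd = noise_sd,
                 tilt = tilt, harmonic2 = harmonic2, fs = fs,
                 seed = as.integer(seed)),
            class = "gait_scenario")
}

#' Simulate a waist-level walking recording with ground truth
#'
#' Per walking (or stairs) segment the vertical axis carries a
#' step-frequency sinusoid plus a second harmonic, the longitudinal axis a
#' step-frequency sinusoid, and the lateral axis a stride-frequency (half
#' step rate) sinusoid; gravity projects on the vertical axis through the
#' tilt angle, and white noise is added everywhere. Rest segments are
#' gravity plus noise. The oscillation phase is continuous within a
#' contiguous moving bout and resets to zero at each bout start (a walker
#' begins a fresh step after standing still); every full 2*pi cycle of the
#' step phase is recorded as one ground-truth step.
#'
#' @param scenario A [gait_scenario()].
#' @return List with `recording` (an [accel_recording()]) and `truth`
#'   (list: `step_times` (s), `steps_per_segment`, `speed` — instantaneous
#'   true speed per sample — and `sections`, a [section_definitions()]
#'   table, one section per segment).
#' @export
simulate_walk <- function(scenario) {
  stopifnot(inherits(scenario, "gait_scenario"))
  set.seed(scenario$seed)
  fs <- scenario$fs
  seg <- scenario$segments
  nseg <- vapply(seg$duration, function(d) round(d * fs), 0)
  n <- sum(nseg)
  speed <- rep(ifelse(seg$activity == "rest", 0, seg$speed), nseg)
  moving <- rep(seg$activity != "rest", nseg)
  f_inst <- ifelse(moving, scenario$cadence[1] + scenario$cadence[2] * speed, 0)
  # step phase: continuous within a contiguous moving bout, reset to zero at
  # each bout start (a walker starts a fresh step after standing still)
  phase <- numeric(n)
  bout_id <- cumsum(moving & !c(FALSE, moving[-n])) * moving
  step_times <- numeric(0)
  tt <- (seq_len(n) - 1) / fs
  for (b in setdiff(unique(bout_id), 0)) {
    idx <- which(bout_id == b)
    ph <- 2 * pi * cumsum(f_inst[idx]) / fs
    phase[idx] <- ph
    k <- seq_len(floor(max(ph) / (2 * pi)))
    if (length(k)) {
      st <- stats::approx(ph, tt[idx], xout = k * 2 * pi, ties = "ordered")$y
      step_times <- c(step_times, st[is.finite(st)])
    }
  }
  amp <- function(law) ifelse(moving, law[1] + law[2] * speed, 0)
  Ax <- amp(scenario$amp_x); Ay <- amp(scenario$amp_y); Az <- amp(scenario$amp_z)
  g_x <- GRAVITY * cos(scenario$tilt * pi / 180)
  ax <- g_x + Ax * sin(phase) + scenario$harmonic2 * Ax * sin(2 * phase) +
    stats::rnorm(n, sd = scenario$noise_sd)
  az <- Az * sin(phase + pi / 4) + stats::rnorm(n, sd = scenario$noise_sd)
  ay <- Ay * sin(phase / 2) + stats::rnorm(n, sd = scenario$noise_sd)
  rec <- accel_recording(ax = ax, ay = ay, az = az, fs = fs,
                         meta = list(source = "simulate_walk"))
  step_times <- sort(step_times)
  bounds <- cumsum(c(0, nseg)) / fs
  steps_per_segment <- vapply(seq_len(nrow(seg)), function(i) {
    sum(step_times >= bounds[i] & step_times < bounds[i + 1])
  }, 0L)
  sections <- section_definitions(
    name = sprintf("%s_%02d", seg$activity, seq_len(nrow(seg))),
    t_start = bounds[-length(bounds)], t_end = bounds[-1],
    include_in_speed = seg$activity == "walk",
    is_walking = seg$activity != "rest")
  list(recording = rec,
       truth = list(step_times = step_times,
                    steps_per_segment = steps_per_segment,
                    speed = speed, time = tt, sections = sections))
}

#' Simulate a measuring-wheel (perambulator) recording
#'
#' The accelerometer sits near the rotational axis of a calibrated wheel;
#' as the wheel rolls, the gravity vector rotates in the sensor frame, so
#' the two in-plane axes (x and z) record quadrature sinusoids of the
#' accumulated rotation phase. Rotation frequency follows the pushed speed:
#' `f(t) = v(t) / circumference`.
#'
#' @param time Time base of the speed profile, seconds.
#' @param speed True speed profile, m/s (same length as `time`).
#' @param wheel A [wheel_spec()].
#' @param fs Sampling rate, Hz (default 100).
#' @param noise_sd Sensor noise SD, m/s^2 (default 0.05).
#' @param seed Integer seed.
#' @return An [accel_recording()]; in-plane axes x and z, axle axis y.
#' @export
simulate_wheel <- function(time, speed, wheel = wheel_spec(), fs = 100,
                           noise_sd = 0.05, seed = 1L) {
  stopifnot(length(time) == length(speed), all(speed >= 0))
  set.seed(seed)
  tt <- seq(min(time), max(time), by = 1 / fs)
  v <- stats::approx(time, speed, xout = tt, rule = 2)$y
  f_rot <- v / wheel$circumference
  phase <- 2 * pi * cumsum(f_rot) / fs
  n <- length(tt)
  accel_recording(ax = GRAVITY * cos(phase) + stats::rnorm(n, sd = noise_sd),
                  ay = stats::rnorm(n, sd = noise_sd),
                  az = GRAVITY * sin(phase) + stats::rnorm(n, sd = noise_sd),
                  fs = fs, start_time = min(time),
                  meta = list(source = "simulate_wheel",
                              circumference = wheel$circumference))
}

#' Simulate a walking-course cohort with wheel reference
#'
#' Generates, per subject, a multi-section course — hallway, stairs, lobby,
#' outdoor walkway and return, walked continuously — with a
#' subject-level base speed and about +/-10\% section-to-section variation,
#' plus a paired measuring-wheel recording driven by the same true speed
#' profile. Subject base speeds are spread evenly across `speed_range`
#' (with a small seeded jitter), so a cohort of 20 spanning 0.5-1.4 m/s
#' deterministically includes slow walkers (< 0.8 m/s).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param speed_range `c(lo, hi)` of subject base speeds, m/s
#'   (default `c(0.5, 1.4)`).
#' @param seed Integer seed for the whole cohort.
#' @param ... Passed to [gait_scenario()] (noise level, coupling laws, ...).
#' @return List of length `n_subjects`; each element has `subject` (id),
#'   `base_speed`, `recording`, `wheel` (wheel [accel_recording()]) and
#'   `truth` (as in [simulate_walk()]).
#' @export
simulate_parcours <- function(n_subjects, speed_range = c(0.5, 1.4),
                              seed = 1L, ...) {
  stopifnot(n_subjects >= 1, speed_range[1] > 0,
            speed_range[1] <= speed_range[2])
  set.seed(seed)
  base <- if (n_subjects == 1) mean(speed_range) else
    seq(speed_range[1], speed_range[2], length.out = n_subjects)
  base <- base + stats::rnorm(n_subjects, sd = 0.02)
  base <- pmin(pmax(base, speed_range[1]), speed_range[2])
  # the course is walked continuously: hallway, stairs, lobby, outdoor
  # walkway, return; sections are course regions, not separate bouts
  section_plan <- data.frame(
    activity = c("walk", "stairs", "walk", "walk", "walk"),
    duration = c(30, 10, 20, 40, 30))
  subject_seeds <- sample.int(.Machine$integer.max, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    set.seed(subject_seeds[i])
    sf <- 1 + stats::runif(nrow(section_plan), -0.1, 0.1)
    segments <- data.frame(
      duration = section_plan$duration,
      speed = ifelse(section_plan$activity == "rest", 0, base[i] * sf),
      activity = section_plan$activity)
    sc <- gait_scenario(segments = segments, seed = subject_seeds[i], ...)
    sim <- simulate_walk(sc)
    wheel_rec <- simulate_wheel(sim$truth$time, sim$truth$speed,
                                seed = subject_seeds[i] %% 1000000L + 1L)
    list(subject = sprintf("S%02d", i), base_speed = base[i],
         recording = sim$recording, wheel = wheel_rec, truth = sim$truth)
  })
}
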