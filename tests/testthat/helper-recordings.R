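# shared fixtures, built in code

# recording with a vertical tone riding on gravity; quiet y/z noise
tone_recording <- function(freq, amp, duration = 10, fs = 100,
                           noise_sd = 0, seed = 1) {
  set.seed(seed)
  t <- (seq_len(round(duration * fs)) - 1) / fs
  n <- length(t)
  accel_recording(
    ax = 9.80665 + amp * sin(2 * pi * freq * t) + rnorm(n, sd = noise_sd),
    ay = rnorm(n, sd = noise_sd),
    az = rnorm(n, sd = noise_sd), fs = fs)
}

# single-segment walking simulation at one speed
walk_sim <- function(speed, duration = 60, seed = 1, ...) {
  sc <- gait_scenario(segments = data.frame(duration = duration,
                                            speed = speed,
                                            activity = "walk"),
                      seed = seed, ...)
  simulate_walk(sc)
}

# synthetic step table with independent amplitudes
random_steps <- function(n, seed = 1) {
  set.seed(seed)
  structure(data.frame(t_start = seq_len(n), t_end = seq_len(n) + 0.5,
                       duration = 0.5,
                       Ax = runif(n, 0.5, 2.5), Ay = runif(n, 0.2, 1),
                       Az = runif(n, 0.3, 1.5), F = runif(n, 1.2, 2.2),
                       source_window = NA_integer_, detector = "stepwave",
                       stringsAsFactors = FALSE),
            class = c("step_events", "data.frame"))
}
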