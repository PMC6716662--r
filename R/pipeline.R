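#' Run configuration
#'
#' Collects every tunable parameter of the pipeline with its default. A
#' config round-trips through the key-value text serialization used by
#' [write_run_config()] / [read_run_config()].
#'
#' @param detector `"stepwave"` or `"stepslc"`.
#' @param thresholds A [plausibility_thresholds()].
#' @param slc An [slc_params()].
#' @param wheel A [wheel_spec()].
#' @param halfwidth Narrowband half-width, Hz.
#' @param min_amplitude Minimum per-step vertical envelope, m/s^2.
#' @param window_length,overlap Analysis-window geometry.
#' @param seed Integer seed driving every stochastic stage.
#' @param verbose Print progress messages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(detector = c("stepwave", "stepslc"),
                       thresholds = plausibility_thresholds(),
                       slc = slc_params(), wheel = wheel_spec(),
                       halfwidth = 0.5, min_amplitude = 0.15,
                       window_length = 2.5, overlap = 0.5,
                       seed = 1L, verbose = FALSE) {
  structure(list(detector = match.arg(detector), thresholds = thresholds,
                 slc = slc, wheel = wheel, halfwidth = halfwidth,
                 min_amplitude = min_amplitude,
                 window_length = window_length, overlap = overlap,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Serialize / restore a run configuration
#' @param config A [run_config()].
#' @param path File path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  thr <- config$thresholds; slc <- config$slc
  writeLines(c(
    sprintf("detector=%s", config$detector),
    sprintf("max_gravity_angle=%.10g", thr$max_gravity_angle),
    sprintf("min_activity=%.10g", thr$min_activity),
    sprintf("band_low=%.10g", thr$band[1]),
    sprintf("band_high=%.10g", thr$band[2]),
    sprintf("min_prominence=%.10g", thr$min_prominence),
    sprintf("slc_window_length=%.10g", slc$window_length),
    sprintf("slc_k_mag=%.10g", slc$k_mag),
    sprintf("slc_min_interval=%.10g", slc$min_interval),
    sprintf("slc_max_interval=%.10g", slc$max_interval),
    sprintf("wheel_circumference=%.10g", config$wheel$circumference),
    sprintf("halfwidth=%.10g", config$halfwidth),
    sprintf("min_amplitude=%.10g", config$min_amplitude),
    sprintf("window_length=%.10g", config$window_length),
    sprintf("overlap=%.10g", config$overlap),
    sprintf("seed=%d", config$seed)), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  v <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  num <- function(k) as.numeric(v[[k]])
  run_config(
    detector = v[["detector"]],
    thresholds = plausibility_thresholds(num("max_gravity_angle"),
                                         num("min_activity"),
                                         c(num("band_low"), num("band_high")),
                                         num("min_prominence")),
    slc = slc_params(num("slc_window_length"), num("slc_k_mag"),
                     num("slc_min_interval"), num("slc_max_interval")),
    wheel = wheel_spec(num("wheel_circumference")),
    halfwidth = num("halfwidth"), min_amplitude = num("min_amplitude"),
    window_length = num("window_length"), overlap = num("overlap"),
    seed = as.integer(num("seed")))
}

detect_steps <- function(rec, config) {
  if (config$detector == "stepwave") {
    detect_steps_wave(rec, thr = config$thresholds,
                      halfwidth = config$halfwidth,
                      min_amplitude = config$min_amplitude,
                      window_length = config$window_length,
                      overlap = config$overlap)
  } else {
    detect_steps_slc(rec, params = config$slc, band = config$thresholds$band)
  }
}

#' Run the detection and speed pipeline on recording files
#'
#' For each input recording: detect steps with the configured detector,
#' predict per-step speeds with the supplied model, aggregate per-section
#' means if a matching section file (`<input>.sections`) exists, and write
#' the results (`*_steps.csv`, `*_speeds.csv`, `*_sections.csv`) to
#' `out_dir`.
#'
#' @param inputs Character vector of recording file paths.
#' @param out_dir Output directory (created if needed).
#' @param model A fitted [fit_speed_model()] (or path to a serialized one);
#'   `NULL` skips speed prediction.
#' @param config A [run_config()].
#' @return Invisibly, `out_dir`.
#' @export
run_pipeline <- function(inputs, out_dir, model = NULL,
                         config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(model)) model <- read_speed_model(model)
  for (path in inputs) {
    rec <- read_recording(path)
    steps <- detect_steps(rec, config)
    stem <- file.path(out_dir, sub("\\.[^.]*$", "", basename(path)))
    write_steps(steps, paste0(stem, "_steps.csv"))
    if (config$verbose)
      message(basename(path), ": ", nrow(steps), " steps")
    if (!is.null(model)) {
      est <- predict(model, steps)
      utils::write.csv(est, paste0(stem, "_speeds.csv"), row.names = FALSE)
      secfile <- paste0(sub("\\.[^.]*$", "", path), ".sections")
      if (file.exists(secfile)) {
        sec <- aggregate_section_speed(est, read_sections(secfile))
        utils::write.csv(sec, paste0(stem, "_sections.csv"),
                         row.names = FALSE)
      }
    }
  }
  invisible(out_dir)
}

# true per-step speed: instantaneous ground-truth speed at each step start
truth_speed_at <- function(truth, t) {
  stats::approx(truth$time, truth$speed, xout = t, rule = 2)$y
}

# detect + label steps for a simulated cohort; returns list of per-subject
# results (steps, truth, section tables)
cohort_detect <- function(cohort, config) {
  lapply(cohort, function(subj) {
    steps <- detect_steps(subj$recording, config)
    list(subject = subj$subject, steps = steps, truth = subj$truth,
         wheel = subj$wheel)
  })
}

#' End-to-end evaluation on simulated cohorts
#'
#' The full validation experiment: simulate disjoint training and
#' evaluation cohorts, detect steps on both, fit the per-step speed model
#' on the training steps (labelled with true instantaneous speeds), predict
#' on the held-out cohort, derive wheel reference speeds per section, and
#' compute the agreement statistics.
#'
#' @param n_train,n_eval Cohort sizes (default 20 each).
#' @param speed_range Subject base-speed range, m/s (default
#'   `c(0.5, 1.4)`).
#' @param seed Integer master seed; training and evaluation cohorts derive
#'   disjoint seeds from it.
#' @param config A [run_config()].
#' @return List of class `agreement_report`:
#'   `step_deviation` (per-subject %, stepwave),
#'   `speed_error` (per-subject: true vs estimated mean walking speed),
#'   `paired_sections` (subject x section estimated and wheel reference),
#'   `bland_altman`, `regression`, `rmse`, `binned` (grouped mean
#'   differences), `model` (the fitted `speed_model`).
#' @export
run_end_to_end_eval <- function(n_train = 20, n_eval = 20,
                                speed_range = c(0.5, 1.4), seed = 1L,
                                config = run_config(seed = seed)) {
  seed <- as.integer(seed)
  train <- simulate_parcours(n_train, speed_range, seed = seed)
  eval_ <- simulate_parcours(n_eval, speed_range, seed = seed + 104729L)
  train_det <- cohort_detect(train, config)
  eval_det <- cohort_detect(eval_, config)

  # fit the speed model on training steps labelled with true speed
  train_steps <- do.call(rbind, lapply(train_det, `[[`, "steps"))
  train_speeds <- unlist(lapply(train_det, function(d)
    truth_speed_at(d$truth, d$steps$t_start)))
  walk <- train_speeds > 0.05
  model <- fit_speed_model(train_steps[walk, , drop = FALSE],
                           train_speeds[walk])

  # per-subject step-count deviation on the evaluation cohort
  step_dev <- data.frame(
    subject = vapply(eval_det, `[[`, "", "subject"),
    estimated = vapply(eval_det, function(d) nrow(d$steps), 0L),
    truth = vapply(eval_det, function(d) length(d$truth$step_times), 0L))
  step_dev$deviation_pct <- step_count_deviation(step_dev$estimated,
                                                 step_dev$truth)

  # per-subject mean walking speed, estimated vs true
  speed_err <- do.call(rbind, lapply(eval_det, function(d) {
    est <- predict(model, d$steps)
    tv <- truth_speed_at(d$truth, d$steps$t_start)
    in_walk <- tv > 0.05
    data.frame(subject = d$subject,
               true_speed = mean(tv[in_walk]),
               estimated_speed = mean(est$speed[in_walk]),
               stringsAsFactors = FALSE)
  }))
  speed_err$abs_error <- abs(speed_err$estimated_speed - speed_err$true_speed)

  # per-section estimated vs wheel reference speeds
  est_sec <- do.call(rbind, lapply(eval_det, function(d) {
    est <- predict(model, d$steps)
    agg <- aggregate_section_speed(est, d$truth$sections)
    agg <- agg[agg$n_steps > 0, , drop = FALSE]
    data.frame(subject = d$subject, section = agg$section,
               speed = agg$speed, stringsAsFactors = FALSE)
  }))
  ref_sec <- do.call(rbind, lapply(eval_det, function(d) {
    ph <- wheel_rotation_phase(d$wheel, config$wheel)
    ref <- wheel_speed_series(ph, config$wheel)
    sec <- section_mean_speeds(ref, d$truth$sections)
    data.frame(subject = d$subject, section = sec$section,
               speed = sec$speed, stringsAsFactors = FALSE)
  }))
  paired <- pair_estimates_with_reference(est_sec, ref_sec)

  report <- list(step_deviation = step_dev, speed_error = speed_err,
                 paired_sections = paired,
                 bland_altman = bland_altman(paired$estimated,
                                             paired$reference),
                 regression = regression_agreement(paired$estimated,
                                                   paired$reference),
                 rmse = rmse(paired$estimated, paired$reference),
                 binned = grouped_mean_difference(paired),
                 model = model)
  class(report) <- "agreement_report"
  report
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  cat(sprintf("  step-count deviation: max |%%| = %.3f (n = %d subjects)\n",
              max(abs(x$step_deviation$deviation_pct)),
              nrow(x$step_deviation)))
  cat(sprintf("  per-subject mean speed error: max = %.4f m/s\n",
              max(x$speed_error$abs_error)))
  cat(sprintf("  section RMSE vs wheel reference: %.4f m/s (n = %d)\n",
              x$rmse, nrow(x$paired_sections)))
  cat(sprintf("  Bland-Altman: mean %.4f, LoA [%.4f, %.4f] m/s\n",
              x$bland_altman$mean_difference, x$bland_altman$lower_limit,
              x$bland_altman$upper_limit))
  cat(sprintf("  regression agreement: intercept %.4f, slope %.4f\n",
              x$regression$intercept, x$regression$slope))
  invisible(x)
}

#' Write an agreement report as delimited text files
#' @param report An `agreement_report`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_agreement_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$step_deviation,
                   file.path(out_dir, "step_deviation.csv"), row.names = FALSE)
  utils::write.csv(report$speed_error,
                   file.path(out_dir, "speed_error.csv"), row.names = FALSE)
  utils::write.csv(report$paired_sections,
                   file.path(out_dir, "paired_sections.csv"), row.names = FALSE)
  utils::write.csv(report$binned,
                   file.path(out_dir, "binned_differences.csv"),
                   row.names = FALSE)
  summary_df <- data.frame(
    metric = c("rmse", "ba_mean", "ba_lower", "ba_upper",
               "reg_intercept", "reg_slope", "max_abs_step_dev_pct",
               "max_abs_speed_err"),
    value = c(report$rmse, report$bland_altman$mean_difference,
              report$bland_altman$lower_limit, report$bland_altman$upper_limit,
              report$regression$intercept, report$regression$slope,
              max(abs(report$step_deviation$deviation_pct)),
              max(report$speed_error$abs_error)))
  utils::write.csv(summary_df, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
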