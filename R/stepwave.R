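#' Narrowband analytic-signal features of a window
#'
#' For a window that passed the plausibility gate, each axis is band-pass
#' filtered (zero-phase Butterworth, order 2) to a narrow band around its
#' gait frequency — the dominant step frequency for the vertical and
#' longitudinal axes, half of it (the stride frequency) for the lateral
#' axis — and the analytic signal is computed. This yields per axis the
#' amplitude envelope A (modulus, m/s^2), unwrapped instantaneous phase P
#' (radians) and instantaneous frequency F (phase derivative / 2*pi, Hz).
#'
#' @param win An `analysis_window` from [segment_windows()].
#' @param f_dom Dominant step frequency of the window, Hz (vertical axis).
#' @param halfwidth Half-width of the narrow band, Hz (default 0.5). Band
#'   lower edges that would fall at or below 0 are clipped to 0.1 Hz with a
#'   warning.
#' @return An object of class `analytic_features`: list with `time`
#'   (seconds, recording clock), per-axis `A`, `P`, `F` (n x 3 matrices),
#'   `f_dom`, `window_index`, `t_center`.
#' @export
narrowband_analytic <- function(win, f_dom, halfwidth = 0.5) {
  stopifnot(inherits(win, "analysis_window"), is.finite(f_dom), f_dom > 0)
  fs <- win$fs
  centers <- c(x = f_dom, y = f_dom / 2, z = f_dom)
  # filter and compute the analytic signal on the window plus its real
  # signal context, then keep only the window core: slow (stride-rate)
  # components have too few cycles inside 2.5 s for an accurate envelope
  raw <- if (is.null(win$raw_context)) win$raw else win$raw_context
  pad <- if (is.null(win$pad_left)) 0L else win$pad_left
  core <- pad + seq_len(nrow(win$raw))
  A <- P <- Fm <- matrix(NA_real_, nrow(win$raw), 3,
                         dimnames = list(NULL, c("x", "y", "z")))
  for (axis in c("x", "y", "z")) {
    lo <- centers[[axis]] - halfwidth
    hi <- centers[[axis]] + halfwidth
    if (lo <= 0) {
      warning("narrow band lower edge clipped to 0.1 Hz on axis ", axis)
      lo <- 0.1
    }
    bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
    nb <- zerophase_filter(bf, raw[, axis] - mean(raw[, axis]))
    z <- analytic_signal(nb)[core]
    A[, axis] <- Mod(z)
    P[, axis] <- unwrap_phase(Arg(z))
    Fm[, axis] <- c(NA, diff(P[, axis])) * fs / (2 * pi)
  }
  # broad-band vertical envelope: a genuine step is supported by energy in
  # the full walking band, while narrowband ringing past a gait bout is not
  fx <- if (is.null(win$filtered_context)) win$filtered[, "x"]
        else win$filtered_context[, "x"]
  A_broad <- Mod(analytic_signal(fx))[core]
  structure(list(time = win$t_start + (seq_len(nrow(A)) - 1) / fs,
                 A = A, P = P, F = Fm, f_dom = f_dom, A_broad = A_broad,
                 window_index = win$index,
                 t_center = win$t_start + win$length / 2),
            class = "analytic_features")
}

# empty step table with the canonical columns
empty_steps <- function() {
  structure(data.frame(t_start = numeric(0), t_end = numeric(0),
                       duration = numeric(0), Ax = numeric(0),
                       Ay = numeric(0), Az = numeric(0), F = numeric(0),
                       source_window = integer(0),
                       detector = character(0), stringsAsFactors = FALSE),
            class = c("step_events", "data.frame"))
}

#' Extract steps from analytic features by phase cycles
#'
#' One step corresponds to one full 2*pi cycle of the vertical instantaneous
#' phase: at the waist the vertical acceleration oscillates once per step
#' (twice per stride), and the phase gives the relative position within the
#' step. Step boundaries are placed at the times where the unwrapped
#' vertical phase crosses multiples of 2*pi (linearly interpolated between
#' samples); per step, Ax, Ay, Az are the mean amplitude envelopes over the
#' step interval and F the mean vertical instantaneous frequency. Steps
#' shorter than 0.2 s or longer than 2.0 s are discarded, as is any step
#' whose mean vertical envelope falls below `min_amplitude` (narrowband
#' noise during non-walking passages produces phase cycles with a near-zero
#' envelope) or whose broad-band vertical envelope falls below half its
#' narrowband envelope (narrowband filter ringing past the end of a gait
#' bout carries no broad-band support).
#'
#' @param features An `analytic_features` object from
#'   [narrowband_analytic()].
#' @param min_amplitude Minimum mean vertical envelope for an accepted step,
#'   m/s^2 (default 0.15).
#' @param duration_bounds Accepted step duration range in seconds
#'   (default `c(0.2, 2)`).
#' @return A `step_events` data frame (possibly empty) with columns
#'   `t_start`, `t_end`, `duration`, `Ax`, `Ay`, `Az`, `F`,
#'   `source_window`, `detector`. Returns the empty table when the
#'   unwrapped phase is non-monotone over more than 10\% of the window
#'   (unstable narrowband fit).
#' @export
extract_steps_wave <- function(features, min_amplitude = 0.15,
                               duration_bounds = c(0.2, 2)) {
  stopifnot(inherits(features, "analytic_features"))
  P <- features$P[, "x"]
  tt <- features$time
  if (mean(diff(P) < 0) > 0.10) return(empty_steps())
  # crossing times of multiples of 2*pi, interpolated within samples
  k <- seq(ceiling(min(P) / (2 * pi)), floor(max(P) / (2 * pi)))
  if (length(k) < 2) return(empty_steps())
  cross <- vapply(k * 2 * pi, function(lev) {
    i <- which(P[-length(P)] <= lev & P[-1] > lev)[1]
    if (is.na(i)) return(NA_real_)
    tt[i] + (lev - P[i]) / (P[i + 1] - P[i]) * (tt[i + 1] - tt[i])
  }, 0)
  cross <- cross[is.finite(cross)]
  if (length(cross) < 2) return(empty_steps())
  out <- lapply(seq_len(length(cross) - 1), function(j) {
    t0 <- cross[j]; t1 <- cross[j + 1]
    sel <- tt >= t0 & tt < t1
    if (!any(sel)) return(NULL)
    data.frame(t_start = t0, t_end = t1, duration = t1 - t0,
               A_broad = if (is.null(features$A_broad)) Inf
                         else mean(features$A_broad[sel]),
               Ax = mean(features$A[sel, "x"]),
               Ay = mean(features$A[sel, "y"]),
               Az = mean(features$A[sel, "z"]),
               F = mean(features$F[sel, "x"], na.rm = TRUE),
               source_window = features$window_index,
               detector = "stepwave", stringsAsFactors = FALSE)
  })
  steps <- do.call(rbind, out)
  if (is.null(steps)) return(empty_steps())
  keep <- steps$duration >= duration_bounds[1] &
    steps$duration <= duration_bounds[2] & steps$Ax >= min_amplitude &
    steps$A_broad >= 0.5 * steps$Ax
  steps <- steps[keep, , drop = FALSE]
  steps$A_broad <- NULL
  rownames(steps) <- NULL
  class(steps) <- c("step_events", "data.frame")
  steps
}

#' Merge step events from overlapping windows
#'
#' Overlapping analysis windows detect the same step more than once. Two
#' events whose start times differ by less than half a step period
#' (`0.5 / F`) are taken to be the same step; the copy from the window whose
#' center lies nearer the event is kept (it is least affected by filter edge
#' effects). Output is sorted with strictly increasing `t_start`.
#'
#' @param steps A `step_events` table pooled over windows, carrying
#'   `source_window`.
#' @param window_centers Numeric vector of window center times indexed by
#'   `source_window` (seconds).
#' @return Deduplicated `step_events` table.
#' @export
merge_window_steps <- function(steps, window_centers) {
  if (!nrow(steps)) return(steps)
  steps <- steps[order(steps$t_start), , drop = FALSE]
  dist_to_center <- abs(steps$t_start -
                          window_centers[steps$source_window])
  keep <- logical(nrow(steps))
  i <- 1
  while (i <= nrow(steps)) {
    # group of duplicates: events within half a period of the group leader
    tol <- 0.5 / max(steps$F[i], 0.5)
    grp <- i
    while (max(grp) < nrow(steps) &&
           steps$t_start[max(grp) + 1] - steps$t_start[i] < tol)
      grp <- c(grp, max(grp) + 1)
    keep[grp[which.min(dist_to_center[grp])]] <- TRUE
    i <- max(grp) + 1
  }
  out <- steps[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect steps with the stepwave algorithm
#'
#' Full stepwave chain: broad-band pre-filter and windowing
#' ([segment_windows()]), spectral features and plausibility gating
#' ([spectral_features()], [check_plausibility()]), narrowband
#' analytic-signal features per plausible window ([narrowband_analytic()]),
#' phase-cycle step extraction ([extract_steps_wave()]) and cross-window
#' merging ([merge_window_steps()]).
#'
#' @param rec An [accel_recording()].
#' @param thr A [plausibility_thresholds()] object.
#' @param halfwidth Narrowband half-width, Hz.
#' @param min_amplitude Minimum per-step vertical envelope, m/s^2.
#' @param window_length,overlap Window geometry in seconds / fraction.
#' @return A `step_events` data frame, one row per detected step.
#' @examples
#' sc <- gait_scenario(segments = data.frame(duration = 20, speed = 1,
#'                                           activity = "walk"), seed = 1)
#' sim <- simulate_walk(sc)
#' steps <- detect_steps_wave(sim$recording)
#' nrow(steps)  # close to length(sim$truth$step_times)
#' @export
detect_steps_wave <- function(rec, thr = plausibility_thresholds(),
                              halfwidth = 0.5, min_amplitude = 0.15,
                              window_length = 2.5, overlap = 0.5) {
  feats <- window_features(rec, thr, length = window_length, overlap = overlap)
  wins <- attr(feats, "windows")
  if (!length(wins) || !any(feats$plausible)) return(empty_steps())
  centers <- vapply(wins, function(w) w$t_start + w$length / 2, 0)
  per_win <- lapply(which(feats$plausible), function(i) {
    af <- narrowband_analytic(wins[[i]], feats$f_dom_x[i],
                              halfwidth = halfwidth)
    extract_steps_wave(af, min_amplitude = min_amplitude)
  })
  pooled <- do.call(rbind, c(list(empty_steps()), per_win))
  merge_window_steps(pooled, centers)
}

#' @export
print.step_events <- function(x, ...) {
  cat(sprintf("<step_events> %d steps", nrow(x)))
  if (nrow(x)) {
    cat(sprintf(" | span %.1f-%.1f s | median cadence %.2f Hz | mean Ax %.2f m/s^2",
                min(x$t_start), max(x$t_end),
                stats::median(x$F), mean(x$Ax)))
  }
  cat("\n")
  invisible(x)
}

#' Write / read detected steps as delimited text
#'
#' Columns: `t_start`, `t_end`, `duration`, `Ax`, `Ay`, `Az`, `F`,
#' `detector`.
#'
#' @param steps A `step_events` table.
#' @param path File path.
#' @return `path` (write) or a `step_events` table (read).
#' @export
write_steps <- function(steps, path) {
  utils::write.csv(steps[c("t_start", "t_end", "duration", "Ax", "Ay", "Az",
                           "F", "detector")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_steps
#' @export
read_steps <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$source_window <- NA_integer_
  class(df) <- c("step_events", "data.frame")
  df
}
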