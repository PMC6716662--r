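#' Measuring-wheel specification
#'
#' @param circumference Wheel circumference in meters (default 1.0, so a
#'   quarter rotation corresponds to 25 cm of travel).
#' @return A list of class `wheel_spec`.
#' @export
wheel_spec <- function(circumference = 1.0) {
  stopifnot(circumference > 0)
  structure(list(circumference = circumference), class = "wheel_spec")
}

#' Wheel rotation phase from in-plane gravity sinusoids
#'
#' An accelerometer near the rotational axis of a rolling wheel sees the
#' gravity vector rotate in the sensor frame: the two in-plane axes (x, z)
#' record quadrature sinusoids whose angle is the rotation phase. Both axes
#' are low-pass filtered at 5 Hz (walking-range rotation rates are well
#' below that) and the phase is the unwrapped arctangent of the pair.
#'
#' @param rec Wheel [accel_recording()] (in-plane axes x and z).
#' @param wheel A [wheel_spec()].
#' @return List of class `wheel_phase`: `time` (s), `phase` (radians,
#'   unwrapped, zero-based), `stationary` flag (in-plane variance near 0).
#' @export
wheel_rotation_phase <- function(rec, wheel = wheel_spec()) {
  validate_recording(rec)
  lp <- signal::butter(4, 5 / (rec$fs / 2), type = "low")
  x <- zerophase_filter(lp, rec$ax)
  z <- zerophase_filter(lp, rec$az)
  stationary <- stats::var(x - mean(x)) + stats::var(z - mean(z)) <
    (0.05 * GRAVITY)^2
  phase <- unwrap_phase(atan2(z, x))
  phase <- phase - phase[1]
  structure(list(time = recording_times(rec), phase = phase,
                 stationary = stationary), class = "wheel_phase")
}

#' Reference speed series from wheel rotation phase
#'
#' Emits one event per quarter rotation (phase multiples of pi/2), i.e.
#' every `circumference / 4` meters of travel — 25 cm for the default
#' 1 m wheel. Interval speed is distance over inter-event time. A
#' non-monotone phase (sensor jitter while nearly stopped) is made
#' non-decreasing by a running-maximum smoothing, with a warning.
#'
#' @param phase A `wheel_phase` from [wheel_rotation_phase()].
#' @param wheel A [wheel_spec()].
#' @return List of class `reference_speed_series`: `event_times` (s),
#'   `speeds` (m/s per interval, one fewer than events), `total_distance`
#'   (m).
#' @export
wheel_speed_series <- function(phase, wheel = wheel_spec()) {
  stopifnot(inherits(phase, "wheel_phase"))
  p <- phase$phase
  if (phase$stationary || max(p) < pi / 2) {
    return(structure(list(event_times = numeric(0), speeds = numeric(0),
                          total_distance = 0),
                     class = "reference_speed_series"))
  }
  if (any(diff(p) < 0)) {
    warning("non-monotone wheel phase smoothed (running maximum)")
    p <- cummax(p)
  }
  levels <- seq(pi / 2, max(p), by = pi / 2)
  ev <- stats::approx(p, phase$time, xout = levels, ties = "ordered")$y
  ev <- ev[is.finite(ev)]
  d <- wheel$circumference / 4
  structure(list(event_times = ev, speeds = d / diff(ev),
                 total_distance = d * length(ev)),
            class = "reference_speed_series")
}

#' @export
print.reference_speed_series <- function(x, ...) {
  cat(sprintf("<reference_speed_series> %d quarter-rotation events, %.2f m total",
              length(x$event_times), x$total_distance))
  if (length(x$speeds))
    cat(sprintf(", mean speed %.3f m/s", mean(x$speeds)))
  cat("\n")
  invisible(x)
}

#' Distance-weighted mean reference speed per section
#'
#' Each quarter-rotation interval covers the same distance, so the
#' distance-weighted mean speed over a section is total distance divided by
#' total time of the intervals whose midpoint falls inside the section.
#' Sections with `include_in_speed = FALSE` (stairs) are excluded.
#'
#' @param ref A `reference_speed_series`.
#' @param sections A [section_definitions()] table.
#' @return Data frame `section`, `speed` (m/s), `n_intervals`.
#' @export
section_mean_speeds <- function(ref, sections) {
  keep <- sections[sections$include_in_speed, , drop = FALSE]
  ev <- ref$event_times
  mid <- (ev[-1] + ev[-length(ev)]) / 2
  dt <- diff(ev)
  d <- if (length(ref$speeds)) ref$speeds[1] * dt[1] else NA_real_  # interval distance
  out <- lapply(seq_len(nrow(keep)), function(i) {
    sel <- mid >= keep$t_start[i] & mid < keep$t_end[i]
    if (!any(sel)) {
      return(data.frame(section = keep$name[i], speed = NA_real_,
                        n_intervals = 0L, stringsAsFactors = FALSE))
    }
    # equal distance per interval: distance-weighted mean = total d / total t
    data.frame(section = keep$name[i],
               speed = sum(sel) * d / sum(dt[sel]),
               n_intervals = sum(sel), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pair estimated and reference section speeds
#'
#' Inner join on subject and section name; rows missing on either side are
#' dropped (a message reports how many).
#'
#' @param est Data frame `subject`, `section`, `speed` (estimated m/s).
#' @param ref Data frame `subject`, `section`, `speed` (reference m/s).
#' @return Data frame `subject`, `section`, `estimated`, `reference`.
#' @export
pair_estimates_with_reference <- function(est, ref) {
  m <- merge(est[c("subject", "section", "speed")],
             ref[c("subject", "section", "speed")],
             by = c("subject", "section"), suffixes = c("_est", "_ref"))
  names(m)[names(m) == "speed_est"] <- "estimated"
  names(m)[names(m) == "speed_ref"] <- "reference"
  m <- m[stats::complete.cases(m), , drop = FALSE]
  dropped <- max(nrow(est), nrow(ref)) - nrow(m)
  if (nrow(m) == 0) warning("no common (subject, section) pairs")
  else if (dropped > 0) message(dropped, " unmatched rows dropped")
  m[order(m$subject, m$section), , drop = FALSE]
}
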