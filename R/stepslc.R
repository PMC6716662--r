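#' Parameters of the legacy stepslc detector
#'
#' @param window_length Sliding-window length, seconds (default 5).
#' @param k_mag Adaptive magnitude-threshold multiplier: minima below
#'   `mean - k_mag * sd` of the window qualify (default 0.7).
#' @param min_interval,max_interval Accepted spacing between consecutive
#'   heel strikes, seconds (defaults 0.33 and 1.43 s, i.e. the 0.7-3 Hz
#'   walking band).
#' @param min_depth Absolute floor for a heel-strike minimum, m/s^2
#'   (default 0.3): the adaptive threshold alone fires on sensor noise at
#'   rest, where mean - k*sd still tracks the noise amplitude.
#' @return A list of class `slc_params`.
#' @export
slc_params <- function(window_length = 5, k_mag = 0.7,
                       min_interval = 1 / 3, max_interval = 1 / 0.7,
                       min_depth = 0.3) {
  stopifnot(min_interval < max_interval, window_length >= max_interval,
            k_mag >= 0, min_depth >= 0)
  structure(list(window_length = window_length, k_mag = k_mag,
                 min_interval = min_interval, max_interval = max_interval,
                 min_depth = min_depth),
            class = "slc_params")
}

#' Detect steps with the legacy stepslc algorithm
#'
#' Sliding-window heel-strike detector: within each window the band-passed
#' vertical acceleration is scanned for local minima below an adaptive
#' threshold (`mean - k_mag * sd` of the window); candidate minima closer
#' together than `min_interval` keep only the deeper one, and an accepted
#' pair of consecutive heel strikes spaced within
#' `[min_interval, max_interval]` delimits one step. Step amplitude
#' parameters are filled from broad-band analytic envelopes so stepslc
#' steps are directly comparable with stepwave steps.
#'
#' @param rec An [accel_recording()].
#' @param params An [slc_params()] object.
#' @param band Band-pass edges for the vertical pre-filter, Hz.
#' @return A `step_events` data frame with `detector = "stepslc"`.
#' @export
detect_steps_slc <- function(rec, params = slc_params(), band = c(0.7, 3)) {
  validate_recording(rec)
  fs <- rec$fs
  x <- bandpass_filter(rec$ax, fs, band[1], band[2])
  tt <- recording_times(rec)
  if (stats::sd(x) == 0) return(empty_steps())
  nwin <- round(params$window_length * fs)
  starts <- seq(1, max(1, rec$n - nwin + 1), by = nwin)
  cand <- integer(0)
  for (s in starts) {
    idx <- s:min(s + nwin - 1, rec$n)
    w <- x[idx]
    thr <- min(mean(w) - params$k_mag * stats::sd(w), -params$min_depth)
    # local minima below the adaptive threshold
    iw <- which(diff(sign(diff(w))) > 0) + 1
    cand <- c(cand, idx[iw[w[iw] < thr]])
  }
  cand <- sort(unique(cand))
  if (length(cand) < 2) return(empty_steps())
  # enforce minimum spacing: of any too-close pair keep the deeper minimum
  accepted <- cand[1]
  for (i in cand[-1]) {
    last <- accepted[length(accepted)]
    if ((i - last) / fs >= params$min_interval) {
      accepted <- c(accepted, i)
    } else if (x[i] < x[last]) {
      accepted[length(accepted)] <- i
    }
  }
  if (length(accepted) < 2) return(empty_steps())
  hs <- tt[accepted]
  gap <- diff(hs)
  ok <- gap >= params$min_interval & gap <= params$max_interval
  if (!any(ok)) return(empty_steps())
  # per-step amplitudes from broad-band analytic envelopes
  env <- cbind(x = Mod(analytic_signal(x)),
               y = Mod(analytic_signal(bandpass_filter(rec$ay, fs, band[1], band[2]))),
               z = Mod(analytic_signal(bandpass_filter(rec$az, fs, band[1], band[2]))))
  out <- data.frame(t_start = hs[-length(hs)][ok], t_end = hs[-1][ok])
  out$duration <- out$t_end - out$t_start
  feat <- t(vapply(seq_len(nrow(out)), function(j) {
    sel <- tt >= out$t_start[j] & tt < out$t_end[j]
    c(colMeans(env[sel, , drop = FALSE]), 1 / out$duration[j])
  }, numeric(4)))
  out$Ax <- feat[, 1]; out$Ay <- feat[, 2]; out$Az <- feat[, 3]
  out$F <- feat[, 4]
  out$source_window <- NA_integer_
  out$detector <- "stepslc"
  class(out) <- c("step_events", "data.frame")
  out
}
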