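#' Plausibility thresholds for walking windows
#'
#' Gates applied per analysis window before step extraction: the mean raw
#' acceleration must point close enough to the vertical device axis
#' (upright posture), overall activity must exceed a floor, and the vertical
#' axis must carry a sufficiently prominent spectral peak in the walking
#' band. The band itself and the gate values are configuration, not
#' measurements; defaults are tuned on the bundled simulator.
#'
#' @param max_gravity_angle Maximum angle (degrees) between the mean raw
#'   acceleration vector and the +x (vertical) axis. Default 30.
#' @param min_activity Minimum standard deviation of the band-passed
#'   acceleration magnitude, m/s^2. Default 0.1.
#' @param band Walking frequency band `c(low, high)` in Hz. Default
#'   `c(0.7, 3)`.
#' @param min_prominence Minimum ratio of the in-band spectral peak to the
#'   above-band spectral noise floor for a dominant frequency to count.
#'   Default 6.
#' @return A list of class `plausibility_thresholds`.
#' @export
plausibility_thresholds <- function(max_gravity_angle = 30, min_activity = 0.1,
                                    band = c(0.7, 3), min_prominence = 6) {
  stopifnot(band[1] > 0, band[1] < band[2], max_gravity_angle > 0,
            min_activity > 0, min_prominence > 0)
  structure(list(max_gravity_angle = max_gravity_angle,
                 min_activity = min_activity, band = band,
                 min_prominence = min_prominence),
            class = "plausibility_thresholds")
}

#' Cut a recording into overlapping analysis windows
#'
#' The recording is band-pass filtered as a whole (walking band), then cut
#' into overlapping windows of about 2.5 s; each window keeps both the
#' filtered samples (for spectral and analytic features) and the raw samples
#' (for the gravity-direction gate). The last partial window is dropped.
#'
#' @param rec An [accel_recording()].
#' @param length Window length in seconds (default 2.5).
#' @param overlap Overlap fraction between consecutive windows (default 0.5,
#'   i.e. hop = 1.25 s).
#' @param band Band-pass edges in Hz for the pre-filter.
#' @return List of `analysis_window` objects, each with `index`, `t_start`,
#'   `length`, `hop`, `fs`, `filtered` and `raw` (n x 3 matrices, columns
#'   x,y,z). Empty list (with a warning) if the recording is shorter than one
#'   window.
#' @export
segment_windows <- function(rec, length = 2.5, overlap = 0.5,
                            band = c(0.7, 3)) {
  validate_recording(rec)
  stopifnot(length > 0, overlap >= 0, overlap < 1)
  nwin <- round(length * rec$fs)
  if (rec$n < nwin) {
    warning("recording shorter than one window; no windows produced")
    return(list())
  }
  hop <- length * (1 - overlap)
  nhop <- round(hop * rec$fs)
  filt <- cbind(x = bandpass_filter(rec$ax, rec$fs, band[1], band[2]),
                y = bandpass_filter(rec$ay, rec$fs, band[1], band[2]),
                z = bandpass_filter(rec$az, rec$fs, band[1], band[2]))
  raw <- cbind(x = rec$ax, y = rec$ay, z = rec$az)
  starts <- seq(1, rec$n - nwin + 1, by = nhop)
  # keep the tail covered: align a final window to the recording end when
  # the hop grid stops short of it
  if (max(starts) < rec$n - nwin + 1) starts <- c(starts, rec$n - nwin + 1)
  # context: real neighboring samples kept around each window so the
  # narrowband stage can filter with support longer than the window itself
  # (a stride-frequency component has < 2 cycles in 2.5 s) and keep only
  # the center
  npad <- nwin
  lapply(seq_along(starts), function(i) {
    idx <- starts[i]:(starts[i] + nwin - 1)
    lo <- max(1, starts[i] - npad)
    hi <- min(rec$n, starts[i] + nwin - 1 + npad)
    structure(list(index = i,
                   t_start = rec$start_time + (starts[i] - 1) / rec$fs,
                   length = nwin / rec$fs, hop = nhop / rec$fs, fs = rec$fs,
                   filtered = filt[idx, , drop = FALSE],
                   raw = raw[idx, , drop = FALSE],
                   raw_context = raw[lo:hi, , drop = FALSE],
                   filtered_context = filt[lo:hi, , drop = FALSE],
                   pad_left = starts[i] - lo),
              class = "analysis_window")
  })
}

# Dominant frequency of one axis within a band, from a zero-padded magnitude
# spectrum of the demeaned raw window. Returns c(freq, prominence); freq is
# NA when the peak is not prominent. Prominence is SNR-style: the in-band
# peak over the median spectral magnitude just above the walking band, where
# broadband sensor noise is flat but gait energy is absent — a 2.5 s window
# has too few independent in-band bins for an in-band median to give a
# stable noise floor.
dominant_frequency <- function(x, fs, band, min_prominence, nfft = 8192) {
  n <- length(x)
  x <- x - mean(x)
  nfft <- max(nfft, 2^ceiling(log2(n)))
  X <- Mod(stats::fft(c(x * signal::hanning(n), numeric(nfft - n))))
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  inband <- which(freqs >= band[1] & freqs <= band[2])
  refband <- which(freqs >= band[2] + 0.5 &
                     freqs <= min(2 * band[2] + 4, fs / 2 - 1))
  mag <- X[inband]
  ipk <- which.max(mag)
  floor_mag <- max(stats::median(X[refband]), .Machine$double.eps)
  prom <- mag[ipk] / floor_mag
  f <- if (prom >= min_prominence) freqs[inband[ipk]] else NA_real_
  c(freq = f, prominence = prom)
}

#' Spectral and posture features of an analysis window
#'
#' Computes, per axis, the dominant frequency within the walking band from a
#' zero-padded FFT magnitude spectrum of the demeaned raw window (padded to
#' >= 8192 points, about 0.012 Hz bins at 100 Hz), with a peak-prominence
#' criterion (in-band peak over the above-band spectral noise floor); the
#' gravity angle between the mean raw
#' acceleration vector and the +x axis; and the activity level (standard
#' deviation of the band-passed acceleration magnitude).
#'
#' @param win An `analysis_window` from [segment_windows()].
#' @param thr A [plausibility_thresholds()] object.
#' @return A one-row `data.frame` (class `window_features`) with columns
#'   `index`, `t_start`, `f_dom_x/y/z`, `prom_x/y/z`, `gravity_angle`,
#'   `activity`, `plausible` (NA until gated), `reason`.
#' @export
spectral_features <- function(win, thr = plausibility_thresholds()) {
  stopifnot(inherits(win, "analysis_window"))
  dx <- dominant_frequency(win$raw[, "x"], win$fs, thr$band, thr$min_prominence)
  dy <- dominant_frequency(win$raw[, "y"], win$fs, thr$band, thr$min_prominence)
  dz <- dominant_frequency(win$raw[, "z"], win$fs, thr$band, thr$min_prominence)
  g <- colMeans(win$raw)
  gnorm <- sqrt(sum(g^2))
  angle <- if (gnorm < .Machine$double.eps) 180
           else acos(pmin(1, pmax(-1, g[["x"]] / gnorm))) * 180 / pi
  mag <- sqrt(rowSums(win$filtered^2))
  feat <- data.frame(index = win$index, t_start = win$t_start,
                     f_dom_x = dx[["freq"]], f_dom_y = dy[["freq"]],
                     f_dom_z = dz[["freq"]],
                     prom_x = dx[["prominence"]], prom_y = dy[["prominence"]],
                     prom_z = dz[["prominence"]],
                     gravity_angle = angle, activity = stats::sd(mag),
                     plausible = NA, reason = NA_character_,
                     stringsAsFactors = FALSE)
  class(feat) <- c("window_features", "data.frame")
  feat
}

#' Gate a window on plausibility for upright walking
#'
#' A window is plausible when the gravity angle is within the upright limit,
#' the activity exceeds the floor, and the vertical axis has a dominant
#' frequency in the walking band. The first failing condition (in that
#' order: gravity, activity, dominant frequency) is recorded as the reason.
#' The vertical axis is authoritative for step frequency; lateral and
#' longitudinal dominant frequencies are kept as diagnostics (at the waist
#' the lateral axis oscillates at the stride rate, half the step rate).
#'
#' @param feat A `window_features` row from [spectral_features()].
#' @param thr A [plausibility_thresholds()] object.
#' @return `feat` with `plausible` and `reason` filled
#'   (`ok`, `gravity_angle`, `low_activity`, or `no_dominant_freq`).
#' @export
check_plausibility <- function(feat, thr = plausibility_thresholds()) {
  reason <- rep("ok", nrow(feat))
  reason[is.na(feat$f_dom_x)] <- "no_dominant_freq"
  reason[feat$activity < thr$min_activity] <- "low_activity"
  reason[feat$gravity_angle > thr$max_gravity_angle] <- "gravity_angle"
  feat$plausible <- reason == "ok"
  feat$reason <- reason
  feat
}

#' Windowed features for a whole recording
#'
#' Convenience wrapper: segments, featurizes and gates every window.
#'
#' @param rec An [accel_recording()].
#' @param thr A [plausibility_thresholds()] object.
#' @param length,overlap Window geometry, see [segment_windows()].
#' @return A `data.frame` with one gated [spectral_features()] row per
#'   window; the windows themselves are attached as attribute `"windows"`.
#' @export
window_features <- function(rec, thr = plausibility_thresholds(),
                            length = 2.5, overlap = 0.5) {
  wins <- segment_windows(rec, length = length, overlap = overlap,
                          band = thr$band)
  if (!base::length(wins)) {
    return(structure(data.frame(), windows = list()))
  }
  feats <- do.call(rbind, lapply(wins, spectral_features, thr = thr))
  feats <- check_plausibility(feats, thr)
  attr(feats, "windows") <- wins
  feats
}
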