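#' Tri-axial acceleration recording
#'
#' Container for a uniformly sampled tri-axial waist-worn accelerometer
#' recording. Axis convention: x vertical, y lateral, z longitudinal
#' (anterior-posterior). All series are stored in m/s^2; the canonical
#' sampling rate is 100 Hz but any rate is accepted (see
#' [resample_uniform()]).
#'
#' @param ax,ay,az Numeric acceleration series in m/s^2 (x vertical, y
#'   lateral, z longitudinal), equal length.
#' @param fs Sampling rate in Hz (> 0).
#' @param start_time Recording start in seconds (zero-based clock; section
#'   definitions reference this clock).
#' @param meta Named list of free-form metadata.
#' @return An object of class `accel_recording` with fields `ax`, `ay`, `az`,
#'   `fs`, `start_time`, `n`, `meta`.
#' @examples
#' rec <- accel_recording(ax = rep(9.81, 100), ay = numeric(100),
#'                        az = numeric(100), fs = 100)
#' @export
accel_recording <- function(ax, ay, az, fs, start_time = 0, meta = list()) {
  rec <- structure(
    list(ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az),
         fs = as.numeric(fs), start_time = as.numeric(start_time),
         n = length(ax), meta = meta),
    class = "accel_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  stopifnot(inherits(rec, "accel_recording"))
  if (!(is.numeric(rec$fs) && length(rec$fs) == 1 && rec$fs > 0))
    stop("fs must be a single positive number")
  n <- length(rec$ax)
  if (n < 1 || length(rec$ay) != n || length(rec$az) != n)
    stop("ax, ay, az must have identical length >= 1")
  if (!all(is.finite(rec$ax)) || !all(is.finite(rec$ay)) ||
      !all(is.finite(rec$az)))
    stop("acceleration series must be finite")
  invisible(rec)
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> %d samples @ %g Hz (%.2f s), start %.2f s\n",
              x$n, x$fs, x$n / x$fs, x$start_time))
  cat(sprintf("  mean |a| = %.3f m/s^2\n",
              mean(sqrt(x$ax^2 + x$ay^2 + x$az^2))))
  invisible(x)
}

#' Sample time base of a recording
#' @param rec An `accel_recording`.
#' @return Numeric vector of sample times in seconds (recording clock).
#' @export
recording_times <- function(rec) {
  rec$start_time + (seq_len(rec$n) - 1) / rec$fs
}

# gravitational constant used for unit conversion (standard gravity)
GRAVITY <- 9.80665

#' Read a tri-axial recording from delimited text
#'
#' The file format is delimited text with `#`-prefixed header lines declaring
#' `fs=<Hz>`, `unit=<m/s2|g>` and `axes=xyz`, followed by a column header
#' `t,x,y,z` (or `x,y,z` when only `fs` defines the time base) and one row per
#' sample. Values recorded in units of g are converted to m/s^2 (multiplied
#' by 9.80665). Timestamps, when present, must be uniform within 1% of
#' `1/fs`.
#'
#' @param path Path to the recording file.
#' @param unit Unit override: `"m/s2"` or `"g"`. Defaults to the header's
#'   `unit=` entry, else `"m/s2"`.
#' @return An [accel_recording()].
#' @export
read_recording <- function(path, unit = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  header <- list()
  for (h in lines[hdr_idx]) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) header[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 1) stop("format error: no data rows in ", path)
  dat <- utils::read.csv(text = paste(body, collapse = "\n"),
                         header = TRUE, strip.white = TRUE)
  names(dat) <- tolower(names(dat))
  if (!all(c("x", "y", "z") %in% names(dat)))
    stop("format error: columns x,y,z required, found: ",
         paste(names(dat), collapse = ","))
  bad <- which(!stats::complete.cases(dat[c("x", "y", "z")]))
  if (length(bad))
    stop("NaN/missing values in rows: ", paste(utils::head(bad, 5), collapse = ","))
  fs <- if (!is.null(header$fs)) as.numeric(header$fs) else NA_real_
  start_time <- 0
  if ("t" %in% names(dat)) {
    tt <- dat$t
    if (length(tt) > 1) {
      dt <- diff(tt)
      if (is.na(fs)) fs <- 1 / stats::median(dt)
      if (any(abs(dt - 1 / fs) > 0.01 / fs))
        stop("sampling error: timestamps not uniform within 1% of 1/fs")
    }
    start_time <- tt[1]
  }
  if (is.na(fs)) stop("format error: no fs header and no timestamps")
  if (is.null(unit)) unit <- if (!is.null(header$unit)) header$unit else "m/s2"
  unit <- match.arg(unit, c("m/s2", "g"))
  scale <- if (unit == "g") GRAVITY else 1
  accel_recording(ax = dat$x * scale, ay = dat$y * scale, az = dat$z * scale,
                  fs = fs, start_time = start_time,
                  meta = header[setdiff(names(header), c("fs", "unit", "axes"))])
}

#' Write a recording to delimited text
#'
#' Writes the format read by [read_recording()]: header lines `# fs=`,
#' `# unit=m/s2`, `# axes=xyz`, then `t,x,y,z` rows. Round-trips with
#' [read_recording()] to the printed precision (15 significant digits).
#'
#' @param rec An [accel_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%.10g", rec$fs), "# unit=m/s2", "# axes=xyz"), con)
  tt <- recording_times(rec)
  writeLines("t,x,y,z", con)
  writeLines(sprintf("%.10g,%.15g,%.15g,%.15g", tt, rec$ax, rec$ay, rec$az), con)
  invisible(path)
}

#' Resample a recording to a uniform target rate
#'
#' Linear interpolation onto a uniform grid at `target_fs`. Used to bring
#' recordings from other devices onto the canonical 100 Hz time base so a
#' single set of filter constants applies.
#'
#' @param rec An [accel_recording()].
#' @param target_fs Target sampling rate in Hz, within \[20, 500\].
#' @return A new [accel_recording()] at `target_fs`; duration preserved
#'   within one sample period.
#' @export
resample_uniform <- function(rec, target_fs) {
  validate_recording(rec)
  if (target_fs < 20 || target_fs > 500)
    stop("target_fs out of range [20, 500]")
  if (target_fs == rec$fs) return(rec)
  t_old <- recording_times(rec)
  duration <- (rec$n - 1) / rec$fs
  t_new <- rec$start_time + seq(0, duration, by = 1 / target_fs)
  interp <- function(y) stats::approx(t_old, y, xout = t_new, rule = 2)$y
  accel_recording(ax = interp(rec$ax), ay = interp(rec$ay), az = interp(rec$az),
                  fs = target_fs, start_time = rec$start_time, meta = rec$meta)
}
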