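#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass filter forward and backward (zero phase
#' distortion), after removing the series mean and padding both ends with an
#' odd reflection of the signal so that filter start-up transients decay
#' outside the region of interest. The broad walking band of 0.7-3 Hz removes
#' gravity and most non-gait noise while keeping step-frequency content.
#'
#' @param x Numeric series (one acceleration axis), m/s^2.
#' @param fs Sampling rate, Hz.
#' @param low,high Band edges, Hz; `0 < low < high < fs/2`.
#' @param order Butterworth design order (default 4).
#' @return Filtered series, same length as `x`, zero mean.
#' @examples
#' fs <- 100; t <- seq(0, 10, by = 1 / fs)
#' y <- bandpass_filter(sin(2 * pi * 1.8 * t) + 9.81, fs, 0.7, 3)
#' @export
bandpass_filter <- function(x, fs, low = 0.7, high = 3, order = 4) {
  stopifnot(is.numeric(x), fs > 0)
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2")
  # need at least one period of the low cutoff for the zero-phase
  # application to settle
  if (length(x) < max(3 * (2 * order + 1), fs / low))
    stop("window too short for filter warm-up (", length(x), " samples)")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  zerophase_filter(bf, x - mean(x))
}

# Forward-backward application of an ARMA filter with odd-reflection padding.
# Padding length is capped at n - 1 so short windows remain filterable.
zerophase_filter <- function(bf, x) {
  n <- length(x)
  np <- min(n - 1, max(50, 3 * length(bf$a) * 20))
  head_pad <- 2 * x[1] - x[(np + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - np)]
  xp <- c(head_pad, x, tail_pad)
  y <- signal::filter(bf, xp)
  y <- rev(signal::filter(bf, rev(y)))
  as.numeric(y[(np + 1):(np + n)])
}

#' Analytic signal via the Hilbert transform
#'
#' Computes the complex analytic extension of a real series using the
#' one-sided-spectrum construction: the FFT is taken, negative frequencies are
#' zeroed and positive frequencies doubled, and the inverse FFT returns
#' `x + i * H(x)` where `H` is the Hilbert transform. The modulus of the
#' result is the amplitude envelope, its argument the instantaneous phase.
#'
#' @param x Real numeric series.
#' @return Complex series of the same length.
#' @export
analytic_signal <- function(x) {
  stopifnot(is.numeric(x))
  n <- length(x)
  if (n < 2) return(complex(real = x, imaginary = 0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Unwrap a phase series (radians) by removing 2*pi jumps.
unwrap_phase <- function(p) {
  dp <- diff(p)
  jumps <- round(dp / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi
}
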