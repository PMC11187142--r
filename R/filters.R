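#' Zero-phase Butterworth band-pass filter
#'
#' Two-pass (forward-backward) Butterworth band-pass, order `order` per pass,
#' so the effective magnitude response is the squared single-pass response and
#' the phase delay is zero. This is the one filter used everywhere a band is
#' isolated (ripple 80-120 Hz, spindle 12-15 Hz, comodulogram bands).
#'
#' @param x numeric vector (one channel's samples).
#' @param band length-2 numeric, band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param order Butterworth order per pass (default 3).
#' @return filtered vector, same length as `x`.
#' @export
bandpass <- function(x, band, fs, order = 3) {
  ny <- fs / 2
  if (length(band) != 2L || band[1L] <= 0 || band[2L] <= band[1L])
    stop("`band` must be increasing positive Hz edges", call. = FALSE)
  if (band[2L] >= ny)
    stop(sprintf("band edge %.1f Hz at/above Nyquist (%.1f Hz)", band[2L], ny),
         call. = FALSE)
  bf <- signal::butter(order, band / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal whose real part is `x` and whose
#' imaginary part is the Hilbert transform of `x`, built by zeroing negative
#' frequencies of the DFT.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) return(complex(real = x, imaginary = rep(0, n)))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Centered moving average with shrinking edge windows
#'
#' @param x numeric vector.
#' @param n odd window length in samples.
#' @return smoothed vector, same length; edges average over the part of the
#'   window that lies inside the signal.
#' @keywords internal
moving_average <- function(x, n) {
  len <- length(x)
  half <- (n - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(len) - half, 1L)
  hi <- pmin(seq_len(len) + half, len)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Root-mean-square signal in a centered sliding window
#'
#' @param x numeric vector.
#' @param n window length in samples (forced odd by rounding up).
#' @return RMS series, same length as `x` (shrinking windows at the edges).
#' @keywords internal
moving_rms <- function(x, n) {
  if (n %% 2L == 0L) n <- n + 1L
  sqrt(moving_average(x^2, n))
}

# window length in samples for a duration in seconds, forced odd so the
# window can be centered on a sample
odd_window <- function(width_s, fs) {
  n <- max(1L, round(width_s * fs))
  if (n %% 2L == 0L) n <- n + 1L
  as.integer(n)
}
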