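# Deterministic conditioning of continuous and epoched data: resampling,
# epoching, referencing, normalization, smoothing, baselining. All operations
# preserve trial order and labels (documented drops excepted).

#' Downsample a recording
#'
#' Fourier-domain resampling: the spectrum is truncated at the new Nyquist
#' frequency (an ideal anti-alias low-pass) and inverted on the coarser grid,
#' so any ratio works (1000 -> 200 Hz included) and pass-band amplitudes are
#' preserved exactly for band-limited content. `target_fs == fs` is a
#' bit-exact pass-through.
#'
#' @param rec a [recording()].
#' @param target_fs new sampling rate (Hz), `0 < target_fs <= fs`.
#' @return the resampled [recording()]; duration preserved within one sample.
#' @export
downsample <- function(rec, target_fs) {
  stopifnot(inherits(rec, "recording"))
  if (target_fs <= 0 || target_fs > rec$fs)
    stop("`target_fs` must be in (0, fs]", call. = FALSE)
  if (target_fs == rec$fs) return(rec)
  n <- ncol(rec$data)
  n_out <- round(n * target_fs / rec$fs)
  dat <- t(apply(rec$data, 1L, .fft_resample, n_out = n_out))
  if (nrow(rec$data) == 1L) dat <- matrix(dat, nrow = 1L)
  recording(dat, target_fs, rec$labels, rec$roles)
}

# ideal-filter resampling of one channel to n_out samples
.fft_resample <- function(x, n_out) {
  n <- length(x)
  X <- stats::fft(x)
  Y <- complex(n_out)
  k <- ceiling(n_out / 2) - 1L            # positive bins below new Nyquist
  Y[1L] <- X[1L]
  if (k >= 1L) {
    Y[1L + seq_len(k)] <- X[1L + seq_len(k)]
    Y[n_out + 1L - seq_len(k)] <- X[n + 1L - seq_len(k)]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Cut a continuous recording into event-locked epochs
#'
#' The sample at t = 0 of each epoch is the recording sample nearest the
#' onset. Onsets whose window falls outside the recording are skipped with a
#' warning and their label rows dropped; the number of drops is reported in
#' the warning and in `attr(, "n_dropped")`.
#'
#' @param rec a [recording()].
#' @param onsets event onsets (s, on the recording clock).
#' @param window length-2 numeric, epoch window (s) relative to each onset,
#'   e.g. `c(-1, 3)`.
#' @param labels optional data.frame with one row per onset.
#' @return an [epochs()] object.
#' @export
epoch_recording <- function(rec, onsets, window = c(-1, 3), labels = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (window[1L] > 0 || window[2L] < 0)
    stop("epoch window must contain the lock time 0", call. = FALSE)
  fs <- rec$fs
  n_smp <- round((window[2L] - window[1L]) * fs) + 1L
  rel <- round(window[1L] * fs) + seq_len(n_smp) - 1L   # sample offsets
  lock_idx <- round(onsets * fs) + 1L                   # nearest sample
  lo <- lock_idx + rel[1L]
  hi <- lock_idx + rel[n_smp]
  keep <- lo >= 1L & hi <= ncol(rec$data)
  if (any(!keep))
    warning(sum(!keep), " onset(s) out of range; dropped", call. = FALSE)
  lock_idx <- lock_idx[keep]
  if (!is.null(labels)) labels <- labels[keep, , drop = FALSE]
  dat <- array(0, c(length(lock_idx), nrow(rec$data), n_smp))
  for (i in seq_along(lock_idx))
    dat[i, , ] <- rec$data[, lock_idx[i] + rel, drop = FALSE]
  ep <- epochs(dat, rel / fs, fs, labels, rec$labels, rec$roles)
  attr(ep, "n_dropped") <- sum(!keep)
  ep
}

#' Common average reference
#'
#' Subtracts, at every trial and time point, the instantaneous mean across
#' channels. Idempotent; the post-hoc channel mean is zero to float tolerance.
#'
#' @param ep an [epochs()] object with >= 2 channels.
#' @return the re-referenced `epochs` object.
#' @export
common_average_reference <- function(ep) {
  stopifnot(inherits(ep, "epochs"))
  if (dim(ep$data)[2L] < 2L)
    stop("CAR undefined for a single channel", call. = FALSE)
  m <- apply(ep$data, c(1L, 3L), mean)          # trials x time
  ep$data <- ep$data - aperm(
    array(m, c(dim(m), dim(ep$data)[2L])), c(1L, 3L, 2L))
  ep
}

#' Z-score across trials, per channel and time point
#'
#' For each (channel, time) cell the mean over trials becomes 0 and the
#' sample standard deviation (n - 1 denominator) becomes 1. Zero-variance
#' cells are set to 0 with a warning.
#'
#' @param ep an [epochs()] object with >= 2 trials.
#' @return the normalized `epochs` object.
#' @export
zscore_across_trials <- function(ep) {
  stopifnot(inherits(ep, "epochs"))
  n <- n_trials(ep)
  if (n < 2L) stop("need >= 2 trials to z-score across trials", call. = FALSE)
  mu <- apply(ep$data, c(2L, 3L), mean)
  sdv <- apply(ep$data, c(2L, 3L), stats::sd)
  zero <- sdv < 1e-15
  if (any(zero)) {
    warning(sum(zero), " zero-variance (channel, time) cell(s) set to 0",
            call. = FALSE)
    sdv[zero] <- Inf
  }
  for (tr in seq_len(n))
    ep$data[tr, , ] <- (ep$data[tr, , ] - mu) / sdv
  ep
}

#' Running-average smoothing
#'
#' Centered moving average with an odd window of `round(width * fs)` samples
#' (rounded up to odd); edges use shrinking windows so the output length
#' equals the input length and constant input is unchanged.
#'
#' @param ep an [epochs()] object.
#' @param width window width in seconds (default 0.150 s).
#' @return the smoothed `epochs` object.
#' @export
smooth_running_average <- function(ep, width = 0.150) {
  stopifnot(inherits(ep, "epochs"))
  n_win <- odd_window(width, ep$fs)
  if (n_win < 2L + 1L && round(width * ep$fs) < 2L)
    stop("smoothing window must span at least 2 samples", call. = FALSE)
  if (n_win > dim(ep$data)[3L])
    stop("smoothing window longer than the epoch", call. = FALSE)
  d <- dim(ep$data)
  for (tr in seq_len(d[1L]))
    for (ch in seq_len(d[2L]))
      ep$data[tr, ch, ] <- moving_average(ep$data[tr, ch, ], n_win)
  ep
}

#' Whole-trial baseline correction
#'
#' Subtracts, per trial and channel, the mean over the full epoch window.
#' Idempotent.
#'
#' @param ep an [epochs()] object.
#' @return the baselined `epochs` object.
#' @export
baseline_whole_trial <- function(ep) {
  stopifnot(inherits(ep, "epochs"))
  m <- apply(ep$data, c(1L, 2L), mean)          # trials x channels
  ep$data <- ep$data - array(m, dim(ep$data))
  ep
}
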