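# Time-frequency decomposition and power-based trial scoring.

#' Hanning-taper sliding-window time-frequency decomposition
#'
#' Fourier power on sliding windows moving in `step` increments. The window
#' length at frequency `f` is five cycles (`5 / f` s); each windowed segment
#' is multiplied with a Hanning taper before evaluating the Fourier
#' coefficient at `f`. Output times where the window would exceed the epoch
#' are set to `NA` (excluded, not zero-filled, from any later averaging); a
#' frequency whose window is longer than the whole epoch yields an all-`NA`
#' row.
#'
#' @param ep an [epochs()] object.
#' @param freqs frequencies of interest (Hz), default 1-25 Hz in 1 Hz steps.
#' @param step time step (s) of the sliding window (default 0.050 s).
#' @param n_cycles window length in cycles of each frequency (default 5).
#' @return object of class `"tfr"`: list with `power` (trials x channels x
#'   freqs x times), `freqs`, `times`, `fs`, `labels`, `zscored = FALSE`.
#' @export
tfr_hanning <- function(ep, freqs = 1:25, step = 0.050, n_cycles = 5) {
  stopifnot(inherits(ep, "epochs"))
  if (max(freqs) >= ep$fs / 2) stop("frequency above Nyquist", call. = FALSE)
  d <- dim(ep$data)
  out_t <- seq(min(ep$times), max(ep$times), by = step)
  pow <- array(NA_real_, c(d[1L], d[2L], length(freqs), length(out_t)))
  # flatten trials x channels into rows for fast matrix products
  flat <- matrix(aperm(ep$data, c(3L, 1L, 2L)), nrow = d[3L])  # time x (tr*ch)
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    n_win <- odd_window(n_cycles / f, ep$fs)
    half <- (n_win - 1L) %/% 2L
    tw <- (seq_len(n_win) - (n_win + 1) / 2) / ep$fs
    taper <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = n_win)))
    kern <- taper * exp(-2i * pi * f * tw)
    norm <- 2 / sum(taper)                       # single-sided amplitude
    for (ti in seq_along(out_t)) {
      c_idx <- which.min(abs(ep$times - out_t[ti]))
      lo <- c_idx - half; hi <- c_idx + half
      if (lo < 1L || hi > d[3L]) next
      coefs <- crossprod(flat[lo:hi, , drop = FALSE], kern)  # (tr*ch) x 1
      pow[, , fi, ti] <- matrix(Mod(coefs * norm)^2, d[1L], d[2L])
    }
  }
  structure(list(power = pow, freqs = freqs, times = out_t, fs = ep$fs,
                 labels = ep$labels, ch_labels = ep$ch_labels,
                 zscored = FALSE),
            class = "tfr")
}

#' @export
print.tfr <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<tfr> %d trial(s) x %d channel(s) x %d freq(s) x %d time(s)%s\n",
              d[1L], d[2L], d[3L], d[4L], if (x$zscored) " (z-scored)" else ""))
  invisible(x)
}

#' Z-score a TFR across time
#'
#' Per trial, channel and frequency, power is z-scored using the mean and
#' sample SD over the time points inside `window` (`NA` edge values are
#' ignored). Zero-SD cells are set to 0 with a warning.
#'
#' @param tfr a [tfr_hanning()] result.
#' @param window time window (s) supplying the normalization statistics
#'   (default: the full time axis).
#' @return the z-scored `"tfr"`.
#' @export
zscore_tfr <- function(tfr, window = NULL) {
  stopifnot(inherits(tfr, "tfr"))
  if (is.null(window)) window <- range(tfr$times)
  sel <- tfr$times >= window[1L] & tfr$times <= window[2L]
  if (!any(sel)) stop("window outside the TFR time axis", call. = FALSE)
  d <- dim(tfr$power)
  n_zero <- 0L
  for (tr in seq_len(d[1L])) for (ch in seq_len(d[2L])) {
    p <- tfr$power[tr, ch, , , drop = TRUE]
    if (is.null(dim(p))) p <- matrix(p, nrow = d[3L])
    mu <- rowMeans(p[, sel, drop = FALSE], na.rm = TRUE)
    sdv <- apply(p[, sel, drop = FALSE], 1L, stats::sd, na.rm = TRUE)
    zero <- !is.na(sdv) & sdv < 1e-15
    n_zero <- n_zero + sum(zero)
    sdv[zero] <- Inf
    tfr$power[tr, ch, , ] <- (p - mu) / sdv
  }
  if (n_zero) warning(n_zero, " zero-variance TFR row(s) set to 0", call. = FALSE)
  tfr$zscored <- TRUE
  tfr
}

#' Per-trial power score over a cluster mask
#'
#' Mean (z-scored) power over the masked cells of each trial. The mask is a
#' logical array over `freqs x times` (applied to every channel and averaged
#' over channels) or `channels x freqs x times`. `NA` power cells under the
#' mask are excluded.
#'
#' @param tfr a `"tfr"` object.
#' @param mask logical mask as described above; must select >= 1 cell.
#' @return numeric vector, one score per trial.
#' @export
trial_power_score <- function(tfr, mask) {
  stopifnot(inherits(tfr, "tfr"))
  d <- dim(tfr$power)
  mask <- array(as.logical(mask), dim(mask))   # 0/1 masks become logical
  if (length(dim(mask)) == 2L) {
    if (!all(dim(mask) == d[3:4]))
      stop("mask must be freqs x times", call. = FALSE)
    mask <- aperm(array(mask, c(d[3L], d[4L], d[2L])), c(3L, 1L, 2L))
  }
  if (!all(dim(mask) == d[2:4]))
    stop("mask must be (channels x) freqs x times", call. = FALSE)
  if (!any(mask)) stop("empty cluster mask", call. = FALSE)
  vapply(seq_len(d[1L]), function(tr) {
    v <- tfr$power[tr, , , , drop = FALSE]
    dim(v) <- d[2:4]
    mean(v[mask], na.rm = TRUE)
  }, numeric(1L))
}

#' Median split of trial scores
#'
#' `high` contains the indices of scores strictly greater than the median;
#' ties at the median and everything below go to `low`. The two index sets
#' are disjoint and exhaustive; permuting the scores permutes the sets
#' accordingly.
#'
#' @param scores numeric vector, length >= 2.
#' @return list with integer vectors `high` and `low`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2L) stop("need >= 2 scores", call. = FALSE)
  if (max(scores) - min(scores) < .Machine$double.eps)
    stop("median split undefined: all scores equal", call. = FALSE)
  med <- stats::median(scores)
  list(high = which(scores > med), low = which(scores <= med))
}

#' Event-locked power spectral density
#'
#' Averages Hanning-tapered periodograms of raw (unfiltered) segments of
#' `2 * half_window` s centered on each event's peak. Events whose segment
#' would leave the recording are skipped.
#'
#' @param rec a [recording()].
#' @param events event table with `channel` and `peak_s` columns.
#' @param half_window half segment length (s), default 0.300 s.
#' @return data.frame with `freq` (Hz) and `power` columns.
#' @export
psd_around_events <- function(rec, events, half_window = 0.300) {
  stopifnot(inherits(rec, "recording"))
  if (!nrow(events)) stop("no events", call. = FALSE)
  half <- round(half_window * rec$fs)
  n_seg <- 2L * half + 1L
  taper <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = n_seg)))
  acc <- NULL; n_used <- 0L
  for (i in seq_len(nrow(events))) {
    ch <- match(events$channel[i], rec$labels)
    if (is.na(ch)) next
    c_idx <- round(events$peak_s[i] * rec$fs) + 1L
    lo <- c_idx - half; hi <- c_idx + half
    if (lo < 1L || hi > ncol(rec$data)) next
    seg <- rec$data[ch, lo:hi] * taper
    pgram <- Mod(stats::fft(seg))^2 / (sum(taper^2) * rec$fs)
    if (is.null(acc)) acc <- pgram else acc <- acc + pgram
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no event segment lies fully inside the recording",
                         call. = FALSE)
  pgram <- acc / n_used
  n_keep <- (n_seg + 1L) %/% 2L
  data.frame(freq = (seq_len(n_keep) - 1L) * rec$fs / n_seg,
             power = pgram[seq_len(n_keep)])
}
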