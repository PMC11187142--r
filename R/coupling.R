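# Cross-frequency coupling: instantaneous phase, the Kullback-Leibler
# Modulation Index, comodulograms with trial-shuffle surrogates, event-locked
# phase statistics and peri-event rate histograms.
#
# Phase convention throughout: Hilbert phase of the band-filtered signal with
# 0 at the oscillation peak and +/- pi at the trough, so "ripples nested
# towards the spindle trough" maps to angles near +/- pi.

#' Instantaneous phase of a band-limited oscillation
#'
#' Band-pass filters (two-pass Butterworth) and applies the analytic-signal
#' construction. Phase is 0 at filtered-signal peaks and +/- pi at troughs.
#'
#' @param x numeric vector of samples.
#' @param band band edges (Hz), default the 12-15 Hz spindle band.
#' @param fs sampling rate (Hz); must exceed twice the upper band edge.
#' @return phase series in (-pi, pi], same length as `x`.
#' @export
instantaneous_phase <- function(x, band = c(12, 15), fs) {
  if (fs <= 2 * band[2L]) stop("band outside Nyquist range", call. = FALSE)
  wrap_angle(Arg(analytic_signal(bandpass(x, band, fs))))
}

#' Band-limited amplitude envelope
#'
#' Modulus of the analytic signal of the band-filtered input.
#'
#' @inheritParams instantaneous_phase
#' @return non-negative envelope, same length as `x`.
#' @export
instantaneous_amplitude <- function(x, band, fs) {
  if (fs <= 2 * band[2L]) stop("band outside Nyquist range", call. = FALSE)
  Mod(analytic_signal(bandpass(x, band, fs)))
}

#' Kullback-Leibler Modulation Index
#'
#' Phases are sorted into `n_bins` equal bins over (-pi, pi] and the mean
#' amplitude per bin forms a distribution P after normalization to unit sum
#' (empty bins contribute zero mass). MI = KL(P || uniform) / log(n_bins),
#' which is 0 for phase-independent amplitude and 1 when all mass falls in a
#' single bin.
#'
#' @param phase phase series (rad).
#' @param amp amplitude series (>= 0), same length.
#' @param n_bins number of phase bins (default 18, i.e. 20 degrees each).
#' @return MI in `[0, 1]`.
#' @export
modulation_index <- function(phase, amp, n_bins = 18) {
  if (length(phase) != length(amp))
    stop("phase and amplitude series must have equal length", call. = FALSE)
  if (any(amp < 0)) stop("amplitude must be non-negative", call. = FALSE)
  if (all(amp == 0)) {
    warning("all-zero amplitude; MI = 0 by convention", call. = FALSE)
    return(0)
  }
  m <- .binned_mean_amp(.phase_bins(phase, n_bins), amp, n_bins)
  .mi_from_binned(m)
}

# bin index in 1..n_bins for phases in (-pi, pi]
.phase_bins <- function(phase, n_bins) {
  b <- ceiling((wrap_angle(phase) + pi) / (2 * pi) * n_bins)
  pmin(pmax(b, 1L), n_bins)
}

.binned_mean_amp <- function(bins, amp, n_bins) {
  s <- rowsum(amp, bins)                       # grouped sums, sorted bins
  n <- tabulate(bins, n_bins)
  m <- numeric(n_bins)
  idx <- as.integer(rownames(s))
  m[idx] <- s[, 1L] / n[idx]
  m
}

.mi_from_binned <- function(m) {
  tot <- sum(m)
  if (tot <= 0) return(0)
  p <- m / tot
  nb <- length(p)
  kl <- sum(p[p > 0] * log(p[p > 0] * nb))
  min(kl / log(nb), 1)
}

#' Phase-amplitude comodulogram with trial-shuffle surrogates
#'
#' For every (low, high) frequency pair: phase is extracted from `phase_src`
#' in a band of full width `bw_low * f_low` centered on `f_low`, amplitude
#' from `amp_src` in a band of full width `bw_high * f_high` centered on
#' `f_high` (band widths narrower than `min_bw` Hz are clamped with a
#' warning). Filtering and the analytic signal run per segment (row) to avoid
#' cross-segment edge artifacts; the MI is computed on the concatenated
#' series. Surrogates shuffle the segment order of the amplitude relative to
#' the phase (`n_surrogates` independent shuffles, shared across cells within
#' a repetition), exactly the trial-shuffle null used for observed-vs-null MI
#' comparisons.
#'
#' @param phase_src,amp_src numeric matrices, segments x time (a vector is
#'   treated as one segment). Typically event-locked segments of the cortical
#'   (phase) and MTL (amplitude) contact.
#' @param fs sampling rate (Hz).
#' @param low_freqs,high_freqs phase / amplitude frequency grids (Hz).
#' @param bw_low,bw_high full bandwidths as multiples of the center frequency.
#' @param n_bins phase bins for the MI.
#' @param n_surrogates number of trial shuffles (0 = none; >= 1 requires >= 3
#'   segments).
#' @param seed integer seed for the shuffles.
#' @param min_bw minimum full bandwidth (Hz).
#' @return object of class `"mi_matrix"`: list with `mi` (low x high),
#'   `low_freqs`, `high_freqs`, `surrogate_mi` (n_surrogates x low x high or
#'   `NULL`).
#' @export
comodulogram <- function(phase_src, amp_src, fs,
                         low_freqs = seq(4, 20, by = 2),
                         high_freqs = seq(30, 130, by = 10),
                         bw_low = 0.3, bw_high = 0.7, n_bins = 18,
                         n_surrogates = 0, seed = NULL, min_bw = 1) {
  if (is.vector(phase_src)) phase_src <- matrix(phase_src, nrow = 1L)
  if (is.vector(amp_src)) amp_src <- matrix(amp_src, nrow = 1L)
  stopifnot(nrow(phase_src) == nrow(amp_src),
            ncol(phase_src) == ncol(amp_src))
  n_seg <- nrow(phase_src)
  if (n_surrogates > 0 && n_seg < 3L)
    stop("surrogates require >= 3 segments", call. = FALSE)
  if (fs <= 2 * max(high_freqs) * (1 + bw_high / 2))
    stop("fs does not support the highest amplitude band", call. = FALSE)

  band_of <- function(f, bw) {
    w <- f * bw
    if (w < min_bw) {
      warning("bandwidth clamped to ", min_bw, " Hz at ", f, " Hz",
              call. = FALSE)
      w <- min_bw
    }
    c(f - w / 2, f + w / 2)
  }
  # per-segment phase series for each low frequency
  ph <- lapply(low_freqs, function(f) {
    b <- band_of(f, bw_low)
    t(apply(phase_src, 1L, instantaneous_phase, band = b, fs = fs))
  })
  am <- lapply(high_freqs, function(f) {
    b <- band_of(f, bw_high)
    t(apply(amp_src, 1L, instantaneous_amplitude, band = b, fs = fs))
  })

  nl <- length(low_freqs); nh <- length(high_freqs)
  mi <- matrix(0, nl, nh, dimnames = list(low_freqs, high_freqs))
  bins <- lapply(ph, function(p) .phase_bins(as.vector(t(p)), n_bins))
  for (i in seq_len(nl)) for (j in seq_len(nh)) {
    a <- as.vector(t(am[[j]]))
    mi[i, j] <- .mi_from_binned(.binned_mean_amp(bins[[i]], a, n_bins))
  }

  surrogate_mi <- NULL
  if (n_surrogates > 0) {
    if (!is.null(seed)) set.seed(seed)
    perms <- replicate(n_surrogates, sample.int(n_seg), simplify = FALSE)
    surrogate_mi <- array(0, c(n_surrogates, nl, nh))
    for (r in seq_len(n_surrogates)) {
      for (j in seq_len(nh)) {
        a_sh <- as.vector(t(am[[j]][perms[[r]], , drop = FALSE]))
        for (i in seq_len(nl))
          surrogate_mi[r, i, j] <-
            .mi_from_binned(.binned_mean_amp(bins[[i]], a_sh, n_bins))
      }
    }
  }
  structure(list(mi = mi, low_freqs = low_freqs, high_freqs = high_freqs,
                 surrogate_mi = surrogate_mi, n_bins = n_bins),
            class = "mi_matrix")
}

#' @export
print.mi_matrix <- function(x, ...) {
  pk <- arrayInd(which.max(x$mi), dim(x$mi))
  cat(sprintf(
    "<mi_matrix> %d x %d cells; peak MI = %.4g at (%g Hz phase, %g Hz amp)%s\n",
    nrow(x$mi), ncol(x$mi), max(x$mi),
    x$low_freqs[pk[1L]], x$high_freqs[pk[2L]],
    if (!is.null(x$surrogate_mi))
      sprintf("; %d surrogates", dim(x$surrogate_mi)[1L]) else ""))
  invisible(x)
}

#' Trial-shuffle surrogate distribution of the Modulation Index
#'
#' Shuffles the segment (trial) assignment of the amplitude series relative
#' to the phase series and recomputes the MI on the concatenation, `n` times.
#' Identical segments therefore reproduce the observed MI exactly.
#'
#' @param phase_segs,amp_segs numeric matrices, segments x time, of
#'   instantaneous phase and amplitude (already extracted for one frequency
#'   pair).
#' @param n number of shuffles (>= 1).
#' @param seed integer seed.
#' @param n_bins phase bins.
#' @return numeric vector of `n` surrogate MI values.
#' @export
mi_surrogates <- function(phase_segs, amp_segs, n = 100, seed = NULL,
                          n_bins = 18) {
  if (n < 1) stop("need n >= 1 surrogates", call. = FALSE)
  stopifnot(is.matrix(phase_segs), is.matrix(amp_segs),
            all(dim(phase_segs) == dim(amp_segs)))
  n_seg <- nrow(phase_segs)
  if (n_seg < 3L) stop("surrogates require >= 3 segments", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  bins <- .phase_bins(as.vector(t(phase_segs)), n_bins)
  vapply(seq_len(n), function(r) {
    a <- as.vector(t(amp_segs[sample.int(n_seg), , drop = FALSE]))
    .mi_from_binned(.binned_mean_amp(bins, a, n_bins))
  }, numeric(1L))
}

#' Phase at event times
#'
#' Nearest-sample phase of a phase series at each event peak, restricted to
#' events inside `window` (e.g. the 0.7-1.4 s post-cue window of preferred
#' spindle-ripple interactions).
#'
#' @param phase phase series (rad).
#' @param event_peaks event times (s) on the same clock as the series.
#' @param fs sampling rate (Hz).
#' @param t0 time (s) of the first sample of `phase`.
#' @param window optional length-2 window (s); events outside are dropped.
#' @return angles (rad) in (-pi, pi]; empty when no event qualifies.
#' @export
phase_at_events <- function(phase, event_peaks, fs, t0 = 0, window = NULL) {
  if (!is.null(window))
    event_peaks <- event_peaks[event_peaks >= window[1L] &
                                 event_peaks <= window[2L]]
  if (!length(event_peaks)) return(numeric(0))
  idx <- round((event_peaks - t0) * fs) + 1L
  if (any(idx < 1L | idx > length(phase)))
    stop("event peak outside the phase series", call. = FALSE)
  phase[idx]
}

#' Peri-event histogram of event rates
#'
#' Rate per bin = count / (n_trials * bin width), so the conservation
#' identity `sum(rate) * bin * n_trials = total in-window events` holds
#' exactly.
#'
#' @param event_times_per_trial list with one numeric vector of event times
#'   (s, trial clock) per trial; trials without events contribute empty
#'   vectors.
#' @param window length-2 histogram window (s).
#' @param bin bin width (s), default 0.050 s; must not exceed the window span.
#' @return list with `t_mid` (bin centers), `rate` (events/s),
#'   `trial_counts` (trials x bins matrix) and `bin`.
#' @export
peri_event_histogram <- function(event_times_per_trial, window, bin = 0.050) {
  if (!length(event_times_per_trial)) stop("need >= 1 trial", call. = FALSE)
  span <- window[2L] - window[1L]
  if (bin > span) stop("bin wider than the window", call. = FALSE)
  breaks <- seq(window[1L], window[2L], by = bin)
  if (abs(breaks[length(breaks)] - window[2L]) > 1e-12)
    breaks <- c(breaks, window[2L])
  n_bins <- length(breaks) - 1L
  n_tr <- length(event_times_per_trial)
  counts <- matrix(0L, n_tr, n_bins)
  for (tr in seq_len(n_tr)) {
    t <- event_times_per_trial[[tr]]
    t <- t[t >= window[1L] & t < breaks[length(breaks)]]
    if (length(t))
      counts[tr, ] <- as.integer(
        table(cut(t, breaks, right = FALSE, include.lowest = TRUE)))
  }
  list(t_mid = (breaks[-1L] + breaks[-length(breaks)]) / 2,
       rate = colSums(counts) / (n_tr * bin),
       trial_counts = counts, bin = bin)
}

#' Cross-histogram of ripple onsets around spindle onsets
#'
#' For each ripple onset, the lag to the nearest spindle onset; lags are
#' binned over `+/- half_window` s and expressed as a percentage of all
#' ripples, so the histogram sums to 100 when every ripple falls within the
#' window.
#'
#' @param ripple_onsets,spindle_onsets event onset times (s), non-empty.
#' @param half_window half width (s) of the lag window (default 1 s).
#' @param bin bin width (s).
#' @return data.frame with `lag_mid` (s) and `pct` columns.
#' @export
event_onset_cross_histogram <- function(ripple_onsets, spindle_onsets,
                                        half_window = 1, bin = 0.050) {
  if (!length(ripple_onsets) || !length(spindle_onsets))
    stop("both event tables must be non-empty", call. = FALSE)
  lags <- vapply(ripple_onsets, function(r)
    r - spindle_onsets[which.min(abs(r - spindle_onsets))], numeric(1L))
  breaks <- seq(-half_window, half_window, by = bin)
  if (abs(breaks[length(breaks)] - half_window) > 1e-12)
    breaks <- c(breaks, half_window)
  cnt <- as.integer(table(cut(lags, breaks, right = FALSE,
                              include.lowest = TRUE)))
  data.frame(lag_mid = (breaks[-1L] + breaks[-length(breaks)]) / 2,
             pct = 100 * cnt / length(ripple_onsets))
}
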