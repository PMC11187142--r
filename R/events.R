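# Ripple and spindle detection on continuous or epoched data.
#
# Both detectors share one mechanism: band-pass filter (two-pass Butterworth,
# order 3 per pass), centered RMS in a short window, an additional smoothing
# pass with the same window, and a threshold of mean + k * SD of the smoothed
# RMS computed over a user-supplied scope mask. Contiguous supra-threshold
# runs (merged across < 20 ms gaps) form candidate events, which are then
# filtered by duration and, for ripples, by a minimum cycle count in the
# band-filtered signal.

#' Ripple detection parameters
#'
#' Defaults implement the standard MTL ripple detector: 80-120 Hz band, 20 ms
#' RMS window plus one smoothing pass of the same length, threshold mean +
#' 2 SD, duration 25-300 ms, at least 3 cycles.
#'
#' @param band band edges (Hz).
#' @param rms_window,smooth_window RMS and smoothing window lengths (s).
#' @param threshold_sd threshold in SDs above the scope mean.
#' @param min_dur,max_dur event duration bounds (s).
#' @param min_cycles minimum cycles in the band-filtered signal.
#' @param merge_gap supra-threshold runs closer than this (s) are merged.
#' @param peak_sign `"negative"` locks `peak_s` to the band-filtered minimum
#'   (maximal negative amplitude); `"absolute"` to the largest absolute value.
#' @return list of class `"detect_params"`.
#' @export
ripple_params <- function(band = c(80, 120), rms_window = 0.020,
                          smooth_window = 0.020, threshold_sd = 2,
                          min_dur = 0.025, max_dur = 0.300, min_cycles = 3,
                          merge_gap = 0.020, peak_sign = "negative") {
  stopifnot(min_dur < max_dur, threshold_sd > 0)
  structure(list(band = band, rms_window = rms_window,
                 smooth_window = smooth_window, threshold_sd = threshold_sd,
                 min_dur = min_dur, max_dur = max_dur,
                 min_cycles = min_cycles, merge_gap = merge_gap,
                 peak_sign = match.arg(peak_sign, c("negative", "absolute")),
                 type = "ripple"),
            class = "detect_params")
}

#' Spindle detection parameters
#'
#' A documented stand-in detector with the same RMS-threshold mechanism as the
#' ripple detector: 12-15 Hz, 200 ms RMS window, mean + 1.5 SD, duration
#' 0.5-3 s, no cycle criterion.
#'
#' @inheritParams ripple_params
#' @return list of class `"detect_params"`.
#' @export
spindle_params <- function(band = c(12, 15), rms_window = 0.200,
                           smooth_window = 0.200, threshold_sd = 1.5,
                           min_dur = 0.5, max_dur = 3, min_cycles = 0,
                           merge_gap = 0.050, peak_sign = "negative") {
  p <- ripple_params(band, rms_window, smooth_window, threshold_sd,
                     min_dur, max_dur, min_cycles, merge_gap, peak_sign)
  p$type <- "spindle"
  p
}

# band-filtered signal and its smoothed RMS for one channel
.filter_rms <- function(x, fs, params) {
  filt <- bandpass(x, params$band, fs)
  n_rms <- odd_window(params$rms_window, fs)
  n_sm <- odd_window(params$smooth_window, fs)
  list(filt = filt, rms = moving_average(moving_rms(filt, n_rms), n_sm))
}

# supra-threshold run detection given a precomputed threshold; `x` is the
# raw signal, used for the cycle criterion ("cycles in the raw signal")
.detect_runs <- function(x, filt, rms, thr, fs, params, t0 = 0) {
  above <- rms > thr                               # strict exceedance
  if (!any(above)) return(NULL)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # merge runs separated by short sub-threshold gaps
  gap_max <- round(params$merge_gap * fs)
  if (nrow(runs) > 1L) {
    keep <- list(runs[1L, ])
    for (i in 2L:nrow(runs)) {
      last <- keep[[length(keep)]]
      if (runs[i, 1L] - last[2L] - 1L < gap_max)
        keep[[length(keep)]] <- c(last[1L], runs[i, 2L])
      else keep[[length(keep) + 1L]] <- runs[i, ]
    }
    runs <- do.call(rbind, keep)
  }
  out <- NULL
  for (i in seq_len(nrow(runs))) {
    a <- runs[i, 1L]; b <- runs[i, 2L]
    dur <- (b - a) / fs
    if (dur < params$min_dur || dur > params$max_dur) next
    seg <- filt[a:b]
    raw_seg <- x[a:b]
    n_cyc <- .cycles_from_filtered(raw_seg - mean(raw_seg))
    if (params$min_cycles > 0 && n_cyc < params$min_cycles) next
    pk <- if (params$peak_sign == "negative") a - 1L + which.min(seg)
          else a - 1L + which.max(abs(seg))
    out <- rbind(out, data.frame(
      onset_s = t0 + (a - 1L) / fs, offset_s = t0 + (b - 1L) / fs,
      peak_s = t0 + (pk - 1L) / fs, duration_s = dur,
      peak_amp = if (params$peak_sign == "negative") filt[pk] else abs(filt[pk]),
      n_cycles = n_cyc))
  }
  out
}

# cycle count = floor(sign changes / 2) of a (demeaned or band-filtered)
# segment; samples below 10% of the segment's peak amplitude are ignored, a
# hysteresis that keeps numerical ripple and demeaning artifacts from
# counting as oscillation
.cycles_from_filtered <- function(seg) {
  if (length(seg) < 2L) return(0L)
  m <- max(abs(seg))
  if (m < 1e-9) return(0L)
  s <- sign(seg)
  s[abs(seg) < 0.10 * m] <- 0
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  as.integer(sum(diff(s) != 0) %/% 2L)
}

#' Count oscillation cycles in a raw segment
#'
#' Returns `floor(sign changes / 2)` of the demeaned segment, ignoring
#' samples below 10% of the peak amplitude. Demeaning stands in for the
#' DC-removing band-pass here because event extents are far too short for a
#' two-pass filter (its edge transients would dominate the crossing count);
#' `band` and `fs` delimit the oscillation the caller is counting and are kept
#' for interface stability.
#'
#' @param raw_segment numeric vector (one event's raw samples).
#' @param band band edges (Hz) of the oscillation of interest.
#' @param fs sampling rate (Hz).
#' @return integer cycle count (0 for segments shorter than 2 samples).
#' @export
count_cycles <- function(raw_segment, band, fs) {
  n <- length(raw_segment)
  if (n < 2L) return(0L)
  if (stats::sd(raw_segment) == 0) return(0L)      # constant segment
  .cycles_from_filtered(raw_segment - mean(raw_segment))
}

# shared driver over channels of a recording or trials x channels of epochs.
# For epochs, the threshold statistics are pooled over the scope samples of
# ALL trials of a channel ("across all data points"), then runs are extracted
# per trial against that common threshold.
.detect_events <- function(obj, channels, params, scope_mask) {
  if (inherits(obj, "recording")) {
    sel <- if (is.null(channels)) seq_along(obj$labels)
           else match(channels, obj$labels)
    if (anyNA(sel)) stop("unknown channel label", call. = FALSE)
    if (is.null(scope_mask)) scope_mask <- rep(TRUE, ncol(obj$data))
    if (!any(scope_mask)) stop("empty scope mask", call. = FALSE)
    out <- NULL
    for (ch in sel) {
      fr <- .filter_rms(obj$data[ch, ], obj$fs, params)
      scope <- fr$rms[scope_mask]
      thr <- mean(scope) + params$threshold_sd * stats::sd(scope)
      ev <- .detect_runs(obj$data[ch, ], fr$filt, fr$rms, thr, obj$fs, params)
      if (!is.null(ev)) {
        ev$channel <- obj$labels[ch]; ev$trial <- NA_integer_
        out <- rbind(out, ev)
      }
    }
  } else if (inherits(obj, "epochs")) {
    sel <- if (is.null(channels)) seq_along(obj$ch_labels)
           else match(channels, obj$ch_labels)
    if (anyNA(sel)) stop("unknown channel label", call. = FALSE)
    n_t <- dim(obj$data)[3L]
    if (is.null(scope_mask)) scope_mask <- rep(TRUE, n_t)
    if (!any(scope_mask)) stop("empty scope mask", call. = FALSE)
    out <- NULL
    for (ch in sel) {
      frs <- lapply(seq_len(n_trials(obj)), function(tr)
        .filter_rms(obj$data[tr, ch, ], obj$fs, params))
      scope <- unlist(lapply(frs, function(fr) fr$rms[scope_mask]))
      thr <- mean(scope) + params$threshold_sd * stats::sd(scope)
      for (tr in seq_len(n_trials(obj))) {
        ev <- .detect_runs(obj$data[tr, ch, ], frs[[tr]]$filt, frs[[tr]]$rms,
                           thr, obj$fs, params, t0 = obj$times[1L])
        if (!is.null(ev)) {
          ev$channel <- obj$ch_labels[ch]; ev$trial <- tr
          out <- rbind(out, ev)
        }
      }
    }
  } else stop("expected a recording or epochs object", call. = FALSE)
  if (is.null(out)) {
    out <- empty_event_table()
  } else {
    out$type <- params$type
    out <- out[, c("channel", "type", "onset_s", "offset_s", "peak_s",
                   "duration_s", "peak_amp", "n_cycles", "trial")]
    out <- out[order(out$channel, out$trial, out$onset_s), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Detect MTL ripples
#'
#' RMS-threshold detector in the ripple band. The threshold is
#' `mean + threshold_sd * SD` of the smoothed RMS over `scope_mask` (the
#' artifact-free samples; defaults to all samples; for epoched input the
#' statistics pool over all trials of a channel). `peak_s` is the time of the
#' maximal negative band-filtered amplitude within the supra-threshold run;
#' the cycle criterion counts sign changes of the raw (demeaned) signal over
#' the event extent.
#'
#' Detection is invariant to DC offsets (the filter removes them) and to
#' rescaling the signal (the threshold scales with it).
#'
#' @param obj a [recording()] or [epochs()] object. For epochs, detection runs
#'   per trial and the returned table carries a `trial` column with times on
#'   the epoch axis.
#' @param channels channel labels to scan (default: all).
#' @param params a [ripple_params()] object.
#' @param scope_mask logical vector over samples (recording) or epoch time
#'   points (epochs) marking where threshold statistics are computed.
#' @return event table (see [empty_event_table()] for columns).
#' @export
detect_ripples <- function(obj, channels = NULL, params = ripple_params(),
                           scope_mask = NULL) {
  fs <- if (inherits(obj, "recording")) obj$fs else obj$fs
  if (fs < 250) stop("ripple band unresolvable below fs = 250 Hz", call. = FALSE)
  .detect_events(obj, channels, params, scope_mask)
}

#' Detect sleep spindles
#'
#' Same mechanism as [detect_ripples()] with spindle-band defaults
#' (see [spindle_params()]). The algorithm is a documented stand-in: duration
#' statistics from it are not comparable to published values obtained with
#' other detectors.
#'
#' @inheritParams detect_ripples
#' @param params a [spindle_params()] object.
#' @return event table.
#' @export
detect_spindles <- function(obj, channels = NULL, params = spindle_params(),
                            scope_mask = NULL) {
  fs <- if (inherits(obj, "recording")) obj$fs else obj$fs
  if (fs < 50) stop("spindle band unresolvable below fs = 50 Hz", call. = FALSE)
  .detect_events(obj, channels, params, scope_mask)
}

#' Select the spindle-reference cortical contact
#'
#' Returns the cortical channel with the strongest mean band power (squared
#' band-filtered amplitude averaged over the window and all trials). Ties
#' break deterministically toward the earlier channel index; the choice is
#' invariant to trial order.
#'
#' @param ep an [epochs()] object.
#' @param band spindle band (Hz).
#' @param window scoring window (s) on the epoch axis (default `[0, 1.5]` s
#'   after cue onset).
#' @return the selected channel label.
#' @export
select_spindle_contact <- function(ep, band = c(12, 15), window = c(0, 1.5)) {
  stopifnot(inherits(ep, "epochs"))
  cort <- which(ep$roles %in% c("cortical", "scalp"))
  if (!length(cort)) stop("no cortical channels", call. = FALSE)
  idx <- which(ep$times >= window[1L] & ep$times <= window[2L])
  pow <- vapply(cort, function(ch) {
    p <- 0
    for (tr in seq_len(n_trials(ep)))
      p <- p + mean(bandpass(ep$data[tr, ch, ], band, ep$fs)[idx]^2)
    p / n_trials(ep)
  }, numeric(1L))
  ep$ch_labels[cort[which.max(pow)]]
}
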