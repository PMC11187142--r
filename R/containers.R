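#' Continuous multichannel recording
#'
#' Lightweight container for a continuous electrophysiological recording:
#' a channels x samples matrix in microvolts, a sampling rate, unique channel
#' labels and a per-channel role tag. Roles distinguish scalp electrodes,
#' cortical depth contacts and medial-temporal-lobe (MTL) contacts; ripple
#' analyses run on `mtl` channels and spindle analyses on `cortical`/`scalp`
#' channels.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param labels character vector of unique channel labels.
#' @param roles character vector, one of `"scalp"`, `"cortical"`, `"mtl"` per
#'   channel.
#' @return An object of class `"recording"`.
#' @export
recording <- function(data, fs, labels = NULL, roles = NULL) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1L)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  if (!all(is.finite(data))) stop("recording data must be finite", call. = FALSE)
  nch <- nrow(data)
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(nch))
  if (anyDuplicated(labels)) stop("channel labels must be unique", call. = FALSE)
  if (length(labels) != nch) stop("one label per channel required", call. = FALSE)
  if (is.null(roles)) roles <- rep("cortical", nch)
  roles <- match.arg(roles, c("scalp", "cortical", "mtl"), several.ok = TRUE)
  if (length(roles) == 1L) roles <- rep(roles, nch)
  if (length(roles) != nch) stop("one role per channel required", call. = FALSE)
  structure(
    list(data = data, fs = fs, labels = labels, roles = roles),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs
  ))
  cat("  roles:", paste(sprintf("%s=%s", x$labels, x$roles), collapse = ", "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a `recording`.
#' @return length in seconds.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$fs

#' Set of event-locked epochs
#'
#' Trials x channels x time array with a time axis in seconds relative to the
#' lock event (t = 0 is the locked sample) and a per-trial label table. The
#' label table carries whatever per-trial metadata the analysis needs; the
#' columns used by the pipeline are `class` ("left"/"right"/"control"),
#' `condition` ("retrieval"/"tmr"), `remembered` (logical) and `session`
#' ("pre"/"post").
#'
#' @param data numeric array, trials x channels x time.
#' @param times numeric vector of epoch times (s), strictly increasing,
#'   uniformly spaced, containing 0.
#' @param fs sampling rate in Hz.
#' @param labels data.frame with one row per trial (may have zero columns).
#' @param ch_labels,roles channel labels and roles as in [recording()].
#' @return An object of class `"epochs"`.
#' @export
epochs <- function(data, times, fs, labels = NULL, ch_labels = NULL, roles = NULL) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a trials x channels x time array", call. = FALSE)
  if (length(times) != dim(data)[3L])
    stop("`times` length must match the time dimension", call. = FALSE)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing", call. = FALSE)
  if (min(times) > 0 || max(times) < 0)
    stop("the lock time 0 must be inside the epoch window", call. = FALSE)
  n_tr <- dim(data)[1L]
  if (is.null(labels)) labels <- data.frame(row.names = seq_len(max(n_tr, 1L)))[seq_len(n_tr), , drop = FALSE]
  if (nrow(labels) != n_tr) stop("label rows must equal trial count", call. = FALSE)
  nch <- dim(data)[2L]
  if (is.null(ch_labels)) ch_labels <- sprintf("ch%02d", seq_len(nch))
  if (is.null(roles)) roles <- rep("cortical", nch)
  structure(
    list(data = data, times = as.numeric(times), fs = fs, labels = labels,
         ch_labels = ch_labels, roles = roles),
    class = "epochs"
  )
}

#' @export
print.epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epochs> %d trial(s) x %d channel(s) x %d samples @ %g Hz, t in [%g, %g] s\n",
    d[1L], d[2L], d[3L], x$fs, min(x$times), max(x$times)
  ))
  if (ncol(x$labels)) {
    cat("  labels:", paste(names(x$labels), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of trials in an epoch set
#' @param ep an `epochs` object.
#' @return integer trial count.
#' @export
n_trials <- function(ep) dim(ep$data)[1L]

#' Subset trials of an epoch set
#'
#' Keeps labels aligned with the data; never reorders channels or time.
#'
#' @param ep an `epochs` object.
#' @param idx integer or logical trial index.
#' @return the subsetted `epochs` object.
#' @export
subset_trials <- function(ep, idx) {
  ep$data <- ep$data[idx, , , drop = FALSE]
  ep$labels <- ep$labels[idx, , drop = FALSE]
  rownames(ep$labels) <- NULL
  ep
}

#' Read / write event tables
#'
#' Event tables are plain tab-separated files with one detected or injected
#' event per row. Detection output uses the columns `channel`, `type`,
#' `onset_s`, `offset_s`, `peak_s`, `duration_s`, `peak_amp`, `n_cycles`
#' (and `trial` when detection ran on epoched data).
#'
#' @param events data.frame of events.
#' @param path file path.
#' @return `read_event_table` returns a data.frame; `write_event_table`
#'   returns `path` invisibly.
#' @export
write_event_table <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Empty event table with the canonical columns
#' @return zero-row data.frame with the event-table columns.
#' @export
empty_event_table <- function() {
  data.frame(
    channel = character(), type = character(), onset_s = numeric(),
    offset_s = numeric(), peak_s = numeric(), duration_s = numeric(),
    peak_amp = numeric(), n_cycles = integer(), trial = integer(),
    stringsAsFactors = FALSE
  )
}
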