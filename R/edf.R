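# Minimal EDF (European Data Format) reader/writer for continuous
# recordings: fixed 256-byte header + 256 bytes per signal, then 16-bit
# little-endian samples in 1-second data records. Channel roles are stored
# in (and recovered from) the transducer field. Signals are quantized to the
# 16-bit digital range on write (amplitude error bounded by one digital step
# per write).

.pad <- function(x, n) {
  x <- substr(as.character(x), 1L, n)
  sprintf(sprintf("%%-%ds", n), x)
}

#' Write a recording to an EDF file
#'
#' Uses 1-second data records, so the recording length must be a whole number
#' of seconds and `fs` an integer. Physical scaling is per channel
#' (symmetric around 0, spanning the observed amplitude range).
#'
#' @param rec a [recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer needs integer fs", call. = FALSE)
  fs <- as.integer(round(fs))
  n_smp <- ncol(rec$data)
  if (n_smp %% fs != 0L)
    stop("EDF writer needs a whole number of seconds", call. = FALSE)
  n_rec <- n_smp %/% fs
  ns <- nrow(rec$data)
  phys_max <- apply(abs(rec$data), 1L, max)
  phys_max[phys_max == 0] <- 1
  phys_max <- phys_max * 1.0001
  dig_max <- 32767; dig_min <- -32768

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .pad("0", 8), .pad("synthetic", 80), .pad("ripplecue", 80),
    .pad("01.01.26", 8), .pad("00.00.00", 8),
    .pad(256L * (1L + ns), 8), .pad("", 44),
    .pad(n_rec, 8), .pad(1, 8), .pad(ns, 4),
    paste(vapply(rec$labels, .pad, "", n = 16), collapse = ""),
    paste(vapply(paste0("role:", rec$roles), .pad, "", n = 80), collapse = ""),
    paste(rep(.pad("uV", 8), ns), collapse = ""),
    paste(vapply(sprintf("%.6g", -phys_max), .pad, "", n = 8), collapse = ""),
    paste(vapply(sprintf("%.6g", phys_max), .pad, "", n = 8), collapse = ""),
    paste(rep(.pad(dig_min, 8), ns), collapse = ""),
    paste(rep(.pad(dig_max, 8), ns), collapse = ""),
    paste(rep(.pad("", 80), ns), collapse = ""),
    paste(rep(.pad(fs, 8), ns), collapse = ""),
    paste(rep(.pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  scale <- (dig_max - dig_min) / (2 * phys_max)
  dig <- round((rec$data + phys_max) * scale) + dig_min
  dig <- pmin(pmax(dig, dig_min), dig_max)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Supports continuous EDF with equal per-signal sampling rates (the format
#' written by [write_edf()] and by standard EEG exporters). Channel roles are
#' recovered from `role:` prefixes in the transducer field, defaulting to
#' `"cortical"`.
#'
#' @param path EDF file path.
#' @return a [recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16)
  transducer <- fld(80)
  fld(8)                                   # physical dimension
  phys_min <- as.numeric(fld(8))
  phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8))
  dig_max <- as.numeric(fld(8))
  fld(80)                                  # prefilter
  spr <- as.integer(fld(8))                # samples per record
  fld(32)
  if (length(unique(spr)) != 1L)
    stop("mixed sampling rates not supported", call. = FALSE)
  fs <- spr[1L] / rec_dur
  dat <- matrix(0, ns, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns * spr[1L], size = 2L,
                     signed = TRUE, endian = "little")
    idx <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    dat[, idx] <- matrix(block, spr[1L], ns)[, seq_len(ns)] |> t()
  }
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  dat <- dat * scale + (phys_min - dig_min * scale)
  roles <- ifelse(startsWith(transducer, "role:"),
                  sub("^role:", "", transducer), "cortical")
  recording(dat, fs, labels, roles)
}
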