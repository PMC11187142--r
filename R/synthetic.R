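#' Simulation parameters for NREM-like synthetic recordings
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe the
#' intracranial arm of a TMR experiment: 1000 Hz sampling, a mix of cortical
#' and MTL depth contacts, sleep spindles of ~0.75 s at 13.5 Hz riding on slow
#' oscillations, and 80-120 Hz ripple bursts on MTL contacts whose timing on
#' the spindle phase is von Mises distributed around the spindle trough.
#'
#' @param fs sampling rate (Hz). Must exceed twice the upper ripple band edge
#'   when MTL channels are present.
#' @param n_channels number of channels.
#' @param channel_roles per-channel role, `"cortical"` or `"mtl"`.
#' @param duration_s recording length in seconds (continuous generation).
#' @param n_trials number of trials for task datasets (per condition set; see
#'   [make_task_dataset()]).
#' @param iti,iti_jitter TMR inter-trial interval mean and uniform jitter (s);
#'   cues are spaced 5.5 +/- 0.2 s apart.
#' @param background_slope exponent of the 1/f^slope background power
#'   spectrum.
#' @param background_sd per-channel background standard deviation (microvolts).
#' @param spindle_rate spindle complexes per second of continuous recording.
#' @param ripple_rate ripples per spindle; the injected count is
#'   `round(ripple_rate * n_spindles)`, a deterministic function of rate and
#'   opportunity windows.
#' @param so_freq slow-oscillation frequency (Hz, < 1).
#' @param spindle_freq,spindle_band,spindle_dur spindle center frequency (Hz),
#'   detection band (Hz) and burst duration (s).
#' @param ripple_freq,ripple_band,ripple_dur ripple center frequency (Hz),
#'   band (Hz) and burst duration (s); duration must lie in [0.025, 0.150] s.
#' @param so_amp,spindle_amp,ripple_amp burst amplitudes as multiples of
#'   `background_sd`.
#' @param coupling_mu preferred ripple phase on the spindle (rad; 0 = spindle
#'   peak, +/- pi = trough; default `pi`, the trough).
#' @param coupling_kappa von Mises concentration of the ripple phase
#'   (>= 0; 0 = uniform).
#' @param pattern_snr amplitude of the class-specific multichannel template as
#'   a multiple of `background_sd`.
#' @param pattern_window time window (s, relative to the epoch lock) carrying
#'   the class pattern in retrieval trials.
#' @param pattern_dur duration (s) of the ripple-locked pattern in TMR trials.
#' @param remembered_frac fraction of retrieval trials flagged as remembered;
#'   not-remembered trials carry no class pattern.
#' @param tmr_event_frac fraction of learning-cue TMR trials that carry the
#'   SO-spindle-ripple complex and the reactivated class pattern.
#' @param seed integer seed; fixed seed implies bit-identical output.
#' @return a list of class `"sim_params"`.
#' @export
sim_params <- function(fs = 1000,
                       n_channels = 8,
                       channel_roles = c(rep("cortical", 6), rep("mtl", 2)),
                       duration_s = 60,
                       n_trials = 40,
                       iti = 5.5, iti_jitter = 0.2,
                       background_slope = 1,
                       background_sd = 10,
                       spindle_rate = 0.1,
                       ripple_rate = 1,
                       so_freq = 0.75,
                       spindle_freq = 13.5, spindle_band = c(12, 15),
                       spindle_dur = 1.0,
                       ripple_freq = 90, ripple_band = c(80, 120),
                       ripple_dur = 0.1,
                       so_amp = 3, spindle_amp = 3, ripple_amp = 4,
                       coupling_mu = pi, coupling_kappa = 2,
                       pattern_snr = 1,
                       pattern_window = c(0.1, 0.6),
                       pattern_dur = 0.3,
                       remembered_frac = 0.8,
                       tmr_event_frac = 0.5,
                       seed = 1L) {
  p <- as.list(environment())
  if (p$fs <= 0 || p$duration_s <= 0)
    stop("fs and duration_s must be positive", call. = FALSE)
  if (length(p$channel_roles) != p$n_channels)
    stop("channel_roles must have one entry per channel", call. = FALSE)
  if (any(p$channel_roles == "mtl") && p$fs <= 2 * p$ripple_band[2L])
    stop("fs must exceed twice the upper ripple band edge for MTL channels",
         call. = FALSE)
  if (p$coupling_kappa < 0) stop("coupling_kappa must be >= 0", call. = FALSE)
  if (p$spindle_rate < 0 || p$ripple_rate < 0)
    stop("event rates must be >= 0", call. = FALSE)
  if (p$ripple_dur < 0.025 || p$ripple_dur > 0.150)
    stop("ripple_dur must lie in [0.025, 0.150] s", call. = FALSE)
  class(p) <- "sim_params"
  p
}

#' 1/f^slope Gaussian background recording
#'
#' Shapes white Gaussian noise in the frequency domain so the power spectrum
#' falls off as `1/f^background_slope`, then rescales each channel to zero
#' mean and `background_sd` standard deviation. Deterministic under
#' `params$seed` (one `rnorm` call per channel, channels in order).
#'
#' @param params a [sim_params()] object.
#' @return a [recording()].
#' @export
make_background <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- round(params$duration_s * params$fs)
  if (n < 2L) stop("duration too short", call. = FALSE)
  set.seed(params$seed)
  dat <- matrix(0, params$n_channels, n)
  freq <- seq(0, params$fs * (n - 1) / n, length.out = n)
  fold <- pmin(freq, params$fs - freq)           # two-sided spectrum
  amp_scale <- c(0, fold[-1L]^(-params$background_slope / 2))
  for (ch in seq_len(params$n_channels)) {
    w <- stats::rnorm(n)
    x <- Re(stats::fft(stats::fft(w) * amp_scale, inverse = TRUE)) / n
    x <- x - mean(x)
    dat[ch, ] <- x / stats::sd(x) * params$background_sd
  }
  recording(dat, params$fs,
            labels = sprintf("%s%02d", ifelse(params$channel_roles == "mtl", "M", "C"),
                             seq_len(params$n_channels)),
            roles = params$channel_roles)
}

# --- burst waveforms ------------------------------------------------------

# Gaussian-windowed sinusoid; phase 0 (cosine peak) at the center sample when
# polarity = +1, trough at center when polarity = -1. Used for ripples.
burst_wave <- function(freq, dur, fs, amp, polarity = 1) {
  n <- odd_window(dur, fs)
  t <- (seq_len(n) - (n + 1) / 2) / fs
  win <- exp(-0.5 * (t / (dur / 6))^2)           # ~3 sd inside the burst
  polarity * amp * win * cos(2 * pi * freq * t)
}

# Tukey(0.5)-windowed sinusoid (flat central half, cosine tapers), phase 0 at
# the center. Used for spindles: the flat plateau keeps the burst above an
# RMS threshold for most of its nominal duration, which a Gaussian envelope
# does not.
# Tukey(0.5) amplitude envelope over n samples: flat central half, cosine
# tapers over the outer quarters
tukey_env <- function(n) {
  a <- abs(seq(-1, 1, length.out = n))
  ifelse(a <= 0.5, 1, 0.5 * (1 + cos(pi * (a - 0.5) / 0.5)))
}

spindle_burst_wave <- function(freq, dur, fs, amp) {
  n <- odd_window(dur, fs)
  t <- (seq_len(n) - (n + 1) / 2) / fs
  a <- abs(t) / (dur / 2)                         # 0 at center, 1 at edges
  win <- ifelse(a <= 0.5, 1, 0.5 * (1 + cos(pi * (a - 0.5) / 0.5)))
  amp * win * cos(2 * pi * freq * t)
}

# Hann-windowed slow wave, one period of so_freq, positive peak at center
so_wave <- function(so_freq, fs, amp) {
  n <- odd_window(1 / so_freq, fs)
  t <- (seq_len(n) - (n + 1) / 2) / fs
  win <- 0.5 * (1 + cos(2 * pi * t * so_freq))
  amp * win * cos(2 * pi * so_freq * t)
}

# add `wave` to channel `ch` of matrix `dat`, centered at `center_s`;
# returns modified matrix or NULL when the wave does not fit
add_burst <- function(dat, ch, center_s, wave, fs) {
  n <- length(wave)
  c_idx <- round(center_s * fs) + 1L
  lo <- c_idx - (n - 1L) %/% 2L
  hi <- lo + n - 1L
  if (lo < 1L || hi > ncol(dat)) return(NULL)
  dat[ch, lo:hi] <- dat[ch, lo:hi] + wave
  dat
}

#' Inject coupled SO-spindle-ripple complexes into a recording
#'
#' Places `round(spindle_rate * duration)` spindle complexes on the cortical
#' channels: a slow-oscillation wave whose upstate carries a 12-15 Hz
#' Gaussian-windowed spindle burst (per-channel amplitude scaling makes one
#' cortical contact the strongest, as in real recordings). For each complex,
#' ripples are injected on every MTL channel as Gaussian-windowed bursts whose
#' center time is placed where the spindle's instantaneous phase equals an
#' angle drawn from von Mises(`coupling_mu`, `coupling_kappa`) (0 = spindle
#' peak, +/- pi = trough). Ripple bursts are polarity-negative so the
#' band-filtered minimum marks the ground-truth peak time.
#'
#' Draw order under `params$seed + 1`: (1) spindle center jitter, one draw per
#' spindle; (2) per ripple, its von Mises angle then its cycle offset.
#'
#' @param rec a [recording()] (typically from [make_background()]).
#' @param params a [sim_params()] object.
#' @return list with elements `recording` (events added) and `ground_truth`
#'   (see [ground_truth()]).
#' @export
inject_coupled_events <- function(rec, params) {
  stopifnot(inherits(rec, "recording"), inherits(params, "sim_params"))
  cort <- which(rec$roles %in% c("cortical", "scalp"))
  mtl <- which(rec$roles == "mtl")
  if (!length(cort) || !length(mtl))
    stop("need at least one cortical and one MTL channel", call. = FALSE)
  dur <- rec_duration(rec)
  n_sp <- round(params$spindle_rate * dur)
  if (n_sp == 0 && params$ripple_rate > 0 && params$coupling_kappa > 0)
    stop("coupled ripples requested but no spindles will be injected ",
         "(spindle_rate too low)", call. = FALSE)
  set.seed(params$seed + 1L)
  fs <- rec$fs
  dat <- rec$data
  bg <- params$background_sd

  # spindle centers: regular grid with jitter, complexes never overlapping
  margin <- 1 / params$so_freq / 2 + 0.1
  centers <- if (n_sp > 0) {
    grid <- (seq_len(n_sp) - 0.5) * dur / n_sp
    jit <- stats::runif(n_sp, -0.2, 0.2)
    pmin(pmax(grid + jit, margin), dur - margin)
  } else numeric(0)

  # per-cortical-channel spindle amplitude scaling (fixed, makes the first
  # cortical contact the strongest spindle site)
  sp_scale <- seq(1.4, 0.6, length.out = length(cort))

  ev <- list()
  sp_wave_unit <- spindle_burst_wave(params$spindle_freq, params$spindle_dur, fs, 1)
  so_unit <- so_wave(params$so_freq, fs, params$so_amp * bg)
  for (j in seq_along(centers)) {
    tc <- centers[j]
    for (k in seq_along(cort)) {
      w <- sp_wave_unit * params$spindle_amp * bg * sp_scale[k]
      upd <- add_burst(dat, cort[k], tc, w, fs)
      if (!is.null(upd)) dat <- upd
      upd <- add_burst(dat, cort[k], tc, so_unit, fs)
      if (!is.null(upd)) dat <- upd
    }
    ev[[length(ev) + 1L]] <- data.frame(
      channel = rec$labels[cort], type = "spindle",
      onset_s = tc - params$spindle_dur / 2, peak_s = tc,
      duration_s = params$spindle_dur, angle = NA_real_, trial = NA_integer_
    )
  }

  # ripples: count is a deterministic function of rate x opportunity windows
  n_rip <- round(params$ripple_rate * n_sp)
  rip_wave <- burst_wave(params$ripple_freq, params$ripple_dur, fs,
                         params$ripple_amp * bg, polarity = -1)
  if (n_rip > 0) {
    sp_assign <- rep(seq_len(n_sp), length.out = n_rip)
    half_cycles <- floor((params$spindle_dur / 2 - params$ripple_dur / 2) *
                           params$spindle_freq)
    for (i in seq_len(n_rip)) {
      theta <- rvonmises(1L, params$coupling_mu, params$coupling_kappa)
      k_off <- sample(seq(-half_cycles, half_cycles - 1L), 1L)
      t_r <- centers[sp_assign[i]] + theta / (2 * pi * params$spindle_freq) +
        k_off / params$spindle_freq
      placed <- FALSE
      for (m in mtl) {
        upd <- add_burst(dat, m, t_r, rip_wave, fs)
        if (!is.null(upd)) { dat <- upd; placed <- TRUE }
      }
      if (placed) {
        ev[[length(ev) + 1L]] <- data.frame(
          channel = rec$labels[mtl], type = "ripple",
          onset_s = t_r - params$ripple_dur / 2, peak_s = t_r,
          duration_s = params$ripple_dur, angle = wrap_angle(theta),
          trial = NA_integer_
        )
      }
    }
  }

  out_rec <- recording(dat, fs, rec$labels, rec$roles)
  gt <- ground_truth(
    events = if (length(ev)) do.call(rbind, ev) else NULL,
    labels = NULL, pattern_window = NULL, params = params
  )
  list(recording = out_rec, ground_truth = gt)
}

#' Ground-truth record for synthetic data
#'
#' @param events data.frame of injected events (`channel`, `type`, `onset_s`,
#'   `peak_s`, `duration_s`, `angle` in (-pi, pi] for ripples, `trial`).
#' @param labels per-trial label data.frame or `NULL`.
#' @param pattern_window time window (s) carrying the class pattern.
#' @param params the generating [sim_params()].
#' @param templates list of per-class channel templates.
#' @return object of class `"ground_truth"`.
#' @export
ground_truth <- function(events = NULL, labels = NULL, pattern_window = NULL,
                         params = NULL, templates = NULL) {
  if (is.null(events)) {
    events <- data.frame(channel = character(), type = character(),
                         onset_s = numeric(), peak_s = numeric(),
                         duration_s = numeric(), angle = numeric(),
                         trial = integer())
  }
  structure(list(events = events, labels = labels,
                 pattern_window = pattern_window, params = params,
                 templates = templates),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d injected event(s)", nrow(x$events)))
  if (nrow(x$events))
    cat(":", paste(sprintf("%s=%d", names(table(x$events$type)),
                           as.integer(table(x$events$type))), collapse = ", "))
  cat("\n")
  if (!is.null(x$labels))
    cat(sprintf("  %d trial label(s)\n", nrow(x$labels)))
  invisible(x)
}

#' Fixed class-specific multichannel templates
#'
#' One template per class, shared across retrieval and TMR data (the premise
#' of cross-task classification). Each template is a unit-RMS channel vector
#' drawn once from a seeded generator, independent of the trial noise.
#'
#' @param n_channels number of channels.
#' @param classes character vector of class names.
#' @param seed integer seed.
#' @return named list of numeric channel vectors.
#' @export
class_templates <- function(n_channels, classes = c("left", "right"), seed = 1L) {
  set.seed(seed + 1000L)
  out <- lapply(classes, function(cl) {
    v <- stats::rnorm(n_channels)
    v / sqrt(mean(v^2))
  })
  names(out) <- classes
  out
}

#' Inject a class-specific multichannel pattern into epochs
#'
#' Adds `template[class] * snr * scale * w(t)` to every sample of each trial
#' inside `window` - `w(t)` is a Tukey(0.5) envelope (flat over the central
#' half, cosine tapers to the edges), so the pattern is at full strength
#' through most of its nominal window - and leaves every sample outside
#' `window` bit-exactly unchanged. With `snr = 0` the input is returned
#' unchanged.
#'
#' @param ep an [epochs()] object.
#' @param classes character vector, one class per trial (`NA` or classes
#'   missing from `templates` are skipped).
#' @param window length-2 numeric, time window (s) inside the epoch axis.
#' @param snr pattern amplitude as a multiple of `scale`.
#' @param templates list of channel templates from [class_templates()].
#' @param scale amplitude unit (defaults to 1; pass the generator's
#'   `background_sd` so `snr` reads as a signal-to-background ratio).
#' @return the modified `epochs` object.
#' @export
inject_class_pattern <- function(ep, classes, window, snr, templates,
                                 scale = 1) {
  stopifnot(inherits(ep, "epochs"))
  if (window[1L] < min(ep$times) - 1e-9 || window[2L] > max(ep$times) + 1e-9)
    stop("pattern window outside the epoch time axis", call. = FALSE)
  if (snr == 0) return(ep)
  idx <- which(ep$times >= window[1L] & ep$times <= window[2L])
  if (!length(idx)) return(ep)
  tw <- ep$times[idx]
  env <- tukey_env(length(idx))
  for (tr in seq_len(n_trials(ep))) {
    cl <- classes[tr]
    if (is.na(cl) || !cl %in% names(templates)) next
    add <- outer(templates[[cl]] * snr * scale, env)   # channels x window
    ep$data[tr, , idx] <- ep$data[tr, , idx] + add
  }
  ep
}
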