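# Task-structured synthetic datasets: retrieval and TMR epoch sets with
# known ground truth.

# one channel's worth of 1/f^slope noise (zero mean, sd = `sd`); generated
# at a composite FFT length and truncated, so prime sample counts stay fast
shaped_noise <- function(n, fs, slope, sd) {
  m <- stats::nextn(n, c(2L, 3L, 5L))
  freq <- seq(0, fs * (m - 1) / m, length.out = m)
  fold <- pmin(freq, fs - freq)
  amp_scale <- c(0, fold[-1L]^(-slope / 2))
  w <- stats::rnorm(m)
  x <- Re(stats::fft(stats::fft(w) * amp_scale, inverse = TRUE))[seq_len(n)] / m
  x <- x - mean(x)
  x / stats::sd(x) * sd
}

# trials x channels x time array of background noise (draws: trial-major,
# channel-minor)
epoch_noise <- function(n_tr, n_ch, n_time, fs, slope, sd) {
  arr <- array(0, c(n_tr, n_ch, n_time))
  for (tr in seq_len(n_tr))
    for (ch in seq_len(n_ch))
      arr[tr, ch, ] <- shaped_noise(n_time, fs, slope, sd)
  arr
}

# add `wave` centered at epoch time `center_s` to one trial/channel of an
# epochs array; returns NULL if the wave does not fit inside the epoch
add_burst_epoch <- function(data, tr, ch, center_s, wave, times, fs) {
  n <- length(wave)
  c_idx <- which.min(abs(times - center_s))
  lo <- c_idx - (n - 1L) %/% 2L
  hi <- lo + n - 1L
  if (lo < 1L || hi > length(times)) return(NULL)
  data[tr, ch, lo:hi] <- data[tr, ch, lo:hi] + wave
  data
}

#' Generate a synthetic TMR study: retrieval and TMR epoch sets
#'
#' Builds the two epoched datasets the decoding pipeline consumes, with
#' complete ground truth.
#'
#' **Retrieval set** (`n_trials` trials, classes balanced left/right): 1/f
#' background; remembered trials (fraction `remembered_frac` per class) carry
#' the class-specific multichannel template inside `pattern_window`;
#' not-remembered trials carry no pattern. MTL channels receive ripple bursts:
#' two per remembered trial centered uniformly in [0.3, 0.7] s (ripples
#' cluster after the memory prompt when retrieval succeeds), one per
#' not-remembered trial uniformly in [-0.5, 2.5] s.
#'
#' **TMR set** (`n_trials` learning-cue trials balanced left/right plus
#' `n_trials / 2` control-cue trials): learning trials with the
#' SO-spindle-ripple complex (fraction `tmr_event_frac` per class, the
#' "reactivation" trials) receive a cue-evoked slow wave at ~0.4 s, a spindle
#' burst centered uniformly in [0.95, 1.15] s on the cortical channels,
#' MTL ripples placed at a von Mises(`coupling_mu`, `coupling_kappa`) phase of
#' the spindle, and the class template injected for `pattern_dur` s centered
#' on each ripple. Remaining learning trials and all control trials are
#' background only.
#'
#' Trials are spaced `iti` +/- `iti_jitter` s apart (the nominal cue onsets
#' are recorded in the label tables as `onset_s`), and epochs span [-1, 3] s
#' around the locked event.
#'
#' All randomness comes from one generator seeded with `params$seed + 2`;
#' draws occur in this order: retrieval noise (trial-major), retrieval ripple
#' times, TMR noise, TMR spindle centers, TMR ripple angles and cycle
#' offsets, cue onset jitter.
#'
#' @param params a [sim_params()] object.
#' @return list with `retrieval` and `tmr` ([epochs()] objects) and
#'   `ground_truth` (a [ground_truth()]; `events$trial` indexes into the
#'   respective epoch set, `events$set` names it).
#' @export
make_task_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  fs <- params$fs
  times <- seq(-1, 3, by = 1 / fs)
  n_time <- length(times)
  n_ch <- params$n_channels
  roles <- params$channel_roles
  ch_labels <- sprintf("%s%02d", ifelse(roles == "mtl", "M", "C"), seq_len(n_ch))
  cort <- which(roles %in% c("cortical", "scalp"))
  mtl <- which(roles == "mtl")
  bg <- params$background_sd
  classes <- c("left", "right")

  n_per_class <- params$n_trials %/% 2L
  if (params$n_trials %% 2L != 0L)
    warning("odd trial count; truncating to ", 2L * n_per_class,
            " trials to balance classes")
  templates <- class_templates(n_ch, classes, params$seed)

  set.seed(params$seed + 2L)

  ## ---- retrieval set -----------------------------------------------------
  n_ret <- 2L * n_per_class
  ret_class <- rep(classes, each = n_per_class)
  n_rem <- round(params$remembered_frac * n_per_class)
  ret_rem <- as.vector(vapply(classes, function(cl)
    c(rep(TRUE, n_rem), rep(FALSE, n_per_class - n_rem)), logical(n_per_class)))
  ret_session <- rep_len(c("pre", "post"), n_ret)
  ret_data <- epoch_noise(n_ret, n_ch, n_time, fs, params$background_slope, bg)

  ev <- list()
  rip_wave <- burst_wave(params$ripple_freq, params$ripple_dur, fs,
                         params$ripple_amp * bg, polarity = -1)
  for (tr in seq_len(n_ret)) {
    rip_t <- if (ret_rem[tr]) stats::runif(2L, 0.3, 0.7)
             else stats::runif(1L, -0.5, 2.5)
    for (t_r in rip_t) {
      placed <- FALSE
      for (m in mtl) {
        upd <- add_burst_epoch(ret_data, tr, m, t_r, rip_wave, times, fs)
        if (!is.null(upd)) { ret_data <- upd; placed <- TRUE }
      }
      if (placed)
        ev[[length(ev) + 1L]] <- data.frame(
          set = "retrieval", trial = tr, channel = ch_labels[mtl],
          type = "ripple", onset_s = t_r - params$ripple_dur / 2,
          peak_s = t_r, duration_s = params$ripple_dur, angle = NA_real_)
    }
  }

  ret_labels <- data.frame(class = ret_class, condition = "retrieval",
                           remembered = ret_rem, session = ret_session,
                           stringsAsFactors = FALSE)
  retrieval <- epochs(ret_data, times, fs, ret_labels, ch_labels, roles)
  retrieval <- inject_class_pattern(
    retrieval, ifelse(ret_rem, ret_class, NA_character_),
    params$pattern_window, params$pattern_snr, templates, scale = bg)

  ## ---- TMR set -----------------------------------------------------------
  n_ctrl <- n_per_class
  n_tmr <- 2L * n_per_class + n_ctrl
  tmr_class <- c(rep(classes, each = n_per_class), rep("control", n_ctrl))
  n_react <- round(params$tmr_event_frac * n_per_class)
  tmr_react <- c(as.vector(vapply(classes, function(cl)
    c(rep(TRUE, n_react), rep(FALSE, n_per_class - n_react)),
    logical(n_per_class))), rep(FALSE, n_ctrl))
  tmr_data <- epoch_noise(n_tmr, n_ch, n_time, fs, params$background_slope, bg)

  sp_scale <- seq(1.4, 0.6, length.out = length(cort))
  sp_wave_unit <- spindle_burst_wave(params$spindle_freq, params$spindle_dur, fs, 1)
  so_unit <- so_wave(params$so_freq, fs, params$so_amp * bg)
  half_cycles <- 2L
  pat_idx_half <- round(params$pattern_dur / 2 * fs)

  for (tr in seq_len(n_tmr)) {
    if (!tmr_react[tr]) next
    sp_c <- stats::runif(1L, 0.95, 1.15)
    # cue-evoked low-frequency burst, then the spindle burst
    for (k in seq_along(cort)) {
      upd <- add_burst_epoch(tmr_data, tr, cort[k], 0.4, so_unit, times, fs)
      if (!is.null(upd)) tmr_data <- upd
      w <- sp_wave_unit * params$spindle_amp * bg * sp_scale[k]
      upd <- add_burst_epoch(tmr_data, tr, cort[k], sp_c, w, times, fs)
      if (!is.null(upd)) tmr_data <- upd
    }
    ev[[length(ev) + 1L]] <- data.frame(
      set = "tmr", trial = tr, channel = ch_labels[cort], type = "spindle",
      onset_s = sp_c - params$spindle_dur / 2, peak_s = sp_c,
      duration_s = params$spindle_dur, angle = NA_real_)

    n_rip <- max(1L, round(params$ripple_rate))
    for (r in seq_len(n_rip)) {
      theta <- rvonmises(1L, params$coupling_mu, params$coupling_kappa)
      k_off <- sample(seq(-half_cycles, half_cycles), 1L)
      t_r <- sp_c + theta / (2 * pi * params$spindle_freq) +
        k_off / params$spindle_freq
      placed <- FALSE
      for (m in mtl) {
        upd <- add_burst_epoch(tmr_data, tr, m, t_r, rip_wave, times, fs)
        if (!is.null(upd)) { tmr_data <- upd; placed <- TRUE }
      }
      if (!placed) next
      ev[[length(ev) + 1L]] <- data.frame(
        set = "tmr", trial = tr, channel = ch_labels[mtl], type = "ripple",
        onset_s = t_r - params$ripple_dur / 2, peak_s = t_r,
        duration_s = params$ripple_dur, angle = wrap_angle(theta))
      # reactivated class pattern, time-locked to the ripple
      c_idx <- which.min(abs(times - t_r))
      lo <- max(1L, c_idx - pat_idx_half)
      hi <- min(n_time, c_idx + pat_idx_half)
      env <- tukey_env(hi - lo + 1L)
      add <- outer(templates[[tmr_class[tr]]] * params$pattern_snr * bg, env)
      tmr_data[tr, , lo:hi] <- tmr_data[tr, , lo:hi] + add
    }
  }

  tmr_labels <- data.frame(class = tmr_class, condition = "tmr",
                           remembered = NA, session = NA_character_,
                           reactivation = tmr_react, stringsAsFactors = FALSE)
  # nominal cue onsets on the session clock (5.5 +/- jitter apart)
  onset_ret <- cumsum(c(2, rep(6, n_ret - 1L)))
  onset_tmr <- cumsum(c(2, params$iti +
                          stats::runif(n_tmr - 1L, -params$iti_jitter,
                                       params$iti_jitter)))
  ret_labels$onset_s <- onset_ret
  tmr_labels$onset_s <- onset_tmr
  retrieval$labels <- ret_labels
  tmr <- epochs(tmr_data, times, fs, tmr_labels, ch_labels, roles)

  gt_events <- if (length(ev)) do.call(rbind, ev) else NULL
  gt <- ground_truth(events = gt_events,
                     labels = list(retrieval = ret_labels, tmr = tmr_labels),
                     pattern_window = params$pattern_window,
                     params = params, templates = templates)
  list(retrieval = retrieval, tmr = tmr, ground_truth = gt)
}

#' Write ground truth and labels as tab-separated tables
#'
#' Events go to `<stem>_events.tsv` (columns `onset_s`, `channel`, `type`,
#' `class`, `remembered`, plus bookkeeping columns) and trial labels to
#' `<stem>_labels_<set>.tsv`.
#'
#' @param gt a [ground_truth()] object.
#' @param stem output path stem.
#' @return character vector of written paths, invisibly.
#' @export
write_ground_truth <- function(gt, stem) {
  ev <- gt$events
  ev$class <- NA_character_
  ev$remembered <- NA
  if (!is.null(gt$labels) && !is.null(ev$trial) && !is.null(ev$set)) {
    for (s in names(gt$labels)) {
      sel <- which(ev$set == s & !is.na(ev$trial))
      if (length(sel)) {
        ev$class[sel] <- gt$labels[[s]]$class[ev$trial[sel]]
        if ("remembered" %in% names(gt$labels[[s]]))
          ev$remembered[sel] <- gt$labels[[s]]$remembered[ev$trial[sel]]
      }
    }
  }
  paths <- paste0(stem, "_events.tsv")
  write_event_table(ev, paths)
  if (!is.null(gt$labels)) {
    for (s in names(gt$labels)) {
      p <- paste0(stem, "_labels_", s, ".tsv")
      write_event_table(gt$labels[[s]], p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
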