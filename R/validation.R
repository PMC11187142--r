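# Simulation-based validation drivers: parameter-recovery and calibration
# experiments that exercise the full pipeline on data with known ground
# truth. Used by the analysis scripts and the acceptance checks.

#' Ripple-detector recovery on synthetic iEEG
#'
#' Generates a continuous 1/f recording (7 cortical + 1 MTL channel) with
#' `n_events` SO-spindle-ripple complexes, runs [detect_ripples()] on the MTL
#' contact and scores detections against the injected ground truth with a
#' `tol_s` matching window.
#'
#' @param seed integer seed.
#' @param duration_s recording length (s).
#' @param n_events injected ripple count.
#' @param fs sampling rate (Hz).
#' @param tol_s peak matching tolerance (s).
#' @return list with `recall`, `precision`, `median_peak_error_s`,
#'   `n_detected`, `n_injected`.
#' @export
evaluate_ripple_detection <- function(seed = 1, duration_s = 600,
                                      n_events = 50, fs = 1000,
                                      tol_s = 0.050) {
  p <- sim_params(fs = fs, n_channels = 8,
                  channel_roles = c(rep("cortical", 7), "mtl"),
                  duration_s = duration_s,
                  spindle_rate = n_events / duration_s, ripple_rate = 1,
                  seed = seed)
  inj <- inject_coupled_events(make_background(p), p)
  gt <- inj$ground_truth$events
  truth <- gt$peak_s[gt$type == "ripple" & gt$channel == "M08"]
  det <- detect_ripples(inj$recording, channels = "M08")
  hit <- vapply(truth, function(tp) any(abs(det$peak_s - tp) <= tol_s),
                logical(1L))
  matched <- vapply(det$peak_s, function(pk) any(abs(truth - pk) <= tol_s),
                    logical(1L))
  err <- vapply(truth[hit], function(tp) min(abs(det$peak_s - tp)),
                numeric(1L))
  list(recall = mean(hit),
       precision = if (nrow(det)) mean(matched) else NA_real_,
       median_peak_error_s = stats::median(err),
       n_detected = nrow(det), n_injected = length(truth))
}

#' Synthetic phase-amplitude-coupled segments
#'
#' Segments in which the phase of a slow oscillation (`f_phase`) modulates
#' the amplitude of a fast oscillation (`f_amp`): the fast envelope is
#' `(1 + depth * cos(phi - pi)) / 2`, i.e. maximal at the slow trough.
#' `depth = 0` gives uncoupled segments; Gaussian noise is added to both
#' sources.
#'
#' @param n_seg number of segments (trials).
#' @param dur segment duration (s).
#' @param fs sampling rate (Hz).
#' @param f_phase,f_amp slow and fast frequencies (Hz).
#' @param depth modulation depth in `[0, 1]`.
#' @param noise noise SD relative to the unit-amplitude oscillations.
#' @param seed integer seed.
#' @return list with matrices `phase_src` and `amp_src` (segments x time).
#' @export
make_pac_segments <- function(n_seg = 12, dur = 1, fs = 500, f_phase = 14,
                              f_amp = 90, depth = 0.9, noise = 0.5,
                              seed = 1) {
  set.seed(seed)
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  nt <- length(t)
  phase_src <- matrix(0, n_seg, nt)
  amp_src <- matrix(0, n_seg, nt)
  for (i in seq_len(n_seg)) {
    phi0 <- stats::runif(1, 0, 2 * pi)
    slow_phase <- 2 * pi * f_phase * t + phi0
    phase_src[i, ] <- cos(slow_phase)
    env <- (1 + depth * cos(slow_phase - pi)) / 2
    amp_src[i, ] <- env * sin(2 * pi * f_amp * t)
  }
  list(phase_src = phase_src + noise * matrix(stats::rnorm(n_seg * nt), n_seg),
       amp_src = amp_src + noise * matrix(stats::rnorm(n_seg * nt), n_seg))
}

#' Comodulogram peak localization on coupled segments
#'
#' @param seed integer seed.
#' @param depth modulation depth.
#' @param n_seg segments.
#' @return list with `peak_low_hz`, `peak_high_hz`, `peak_mi`.
#' @export
comodulogram_localization <- function(seed = 1, depth = 0.9, n_seg = 12) {
  sg <- make_pac_segments(n_seg = n_seg, depth = depth, seed = seed)
  cm <- comodulogram(sg$phase_src, sg$amp_src, fs = 500,
                     low_freqs = seq(4, 20, by = 2),
                     high_freqs = seq(30, 130, by = 10))
  pk <- arrayInd(which.max(cm$mi), dim(cm$mi))
  list(peak_low_hz = cm$low_freqs[pk[1L]],
       peak_high_hz = cm$high_freqs[pk[2L]],
       peak_mi = max(cm$mi))
}

#' False-positive calibration of the comodulogram surrogate test
#'
#' On uncoupled noise segments, compares the maximum observed MI against the
#' 95th percentile of the max-statistic surrogate null (the maximum MI over
#' cells within each trial-shuffle repetition, the standard correction for
#' selecting the peak cell). Returns the fraction of seeds in which the
#' observed maximum stays below the null quantile (expected ~0.95).
#'
#' @param n_seeds number of independent noise datasets.
#' @param base_seed offset for the per-dataset seeds.
#' @param n_surrogates trial shuffles per dataset.
#' @return fraction of seeds below the 95th null percentile.
#' @export
comodulogram_noise_calibration <- function(n_seeds = 50, base_seed = 0,
                                           n_surrogates = 100) {
  below <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    sg <- make_pac_segments(n_seg = 10, depth = 0, noise = 1,
                            seed = base_seed + s)
    cm <- comodulogram(sg$phase_src, sg$amp_src, fs = 500,
                       low_freqs = seq(4, 20, by = 2),
                       high_freqs = seq(30, 130, by = 10),
                       n_surrogates = n_surrogates,
                       seed = base_seed + s + 10000L)
    null_max <- apply(cm$surrogate_mi, 1L, max)
    below[s] <- max(cm$mi) < stats::quantile(null_max, 0.95)
  }
  mean(below)
}

#' Recovery of a von Mises coupling direction
#'
#' Draws `n` angles from von Mises(`mu`, `kappa`) per seed and scores how
#' often the circular-mean direction lands within `tol_deg` of `mu`.
#'
#' @param n_seeds number of simulated samples.
#' @param n angles per sample.
#' @param kappa concentration.
#' @param mu true direction (rad).
#' @param tol_deg tolerance (degrees).
#' @param base_seed seed offset.
#' @return fraction of seeds within tolerance.
#' @export
coupling_direction_recovery <- function(n_seeds = 200, n = 30, kappa = 2,
                                        mu = pi, tol_deg = 20,
                                        base_seed = 0) {
  hits <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    set.seed(base_seed + s)
    d <- circular_mean(rvonmises(n, mu, kappa))$direction
    hits[s] <- abs(wrap_angle(d - mu)) <= tol_deg * pi / 180
  }
  mean(hits)
}

#' Type-I calibration of the V test under circular uniformity
#'
#' @param n_seeds simulated samples.
#' @param n angles per sample.
#' @param mu tested direction (rad).
#' @param alpha nominal level.
#' @param base_seed seed offset.
#' @return observed rejection rate.
#' @export
vtest_null_calibration <- function(n_seeds = 500, n = 30, mu = pi,
                                   alpha = 0.05, base_seed = 0) {
  rej <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    set.seed(base_seed + s)
    rej[s] <- v_test(rvonmises(n, 0, 0), mu)$p <= alpha
  }
  mean(rej)
}

#' Chance-level calibration of the decoding time course
#'
#' Pattern-free 1/f epochs decoded under shuffled labels. A single label
#' draw shared across all time points leaves substantial variance in the
#' time-mean AUC, so the calibration averages over `n_shuffles` independent
#' label assignments (the usual permutation-null estimate); the result is
#' expected to sit at 0.5.
#'
#' @param seed integer seed.
#' @param n_trials trials (labels balanced).
#' @param n_channels channels.
#' @param fs sampling rate (Hz).
#' @param n_shuffles independent label shuffles averaged over.
#' @return shuffle-averaged time-mean AUC.
#' @export
decoding_chance_calibration <- function(seed = 1, n_trials = 100,
                                        n_channels = 8, fs = 200,
                                        n_shuffles = 5) {
  set.seed(seed)
  times <- seq(-0.5, 1.5, by = 1 / fs)
  dat <- array(0, c(n_trials, n_channels, length(times)))
  for (tr in seq_len(n_trials)) for (ch in seq_len(n_channels))
    dat[tr, ch, ] <- shaped_noise(length(times), fs, 1, 1)
  ep <- epochs(dat, times, fs, data.frame(trial = seq_len(n_trials)))
  red <- suppressWarnings(pca_reduce(zscore_across_trials(ep), 30))
  red <- smooth_reduced(red, 0.150)
  auc_means <- vapply(seq_len(n_shuffles), function(k) {
    y <- sample(rep(c("left", "right"), length.out = n_trials))
    mean(crossval_timecourse(red, y, seed = seed + k, step = 0.05)$auc)
  }, numeric(1L))
  mean(auc_means)
}

#' Recovery of the injected retrieval pattern window
#'
#' Runs the retrieval decoding chain (CAR, z-score, PCA, smoothing, repeated
#' cross-validated LDA, cluster test against chance) on a default synthetic
#' study and scores AUC inside/outside the true pattern window plus the
#' overlap of the supra-chance cluster with that window.
#'
#' @param seed integer seed (study and analysis).
#' @param n_perm cluster permutations.
#' @return list with `auc_inside`, `auc_outside`, `cluster_overlap`.
#' @export
pattern_recovery_validation <- function(seed = 1, n_perm = 500) {
  p <- sim_params(seed = seed)
  st <- make_task_dataset(p)
  ep <- zscore_across_trials(common_average_reference(st$retrieval))
  red <- suppressWarnings(pca_reduce(ep, 30))
  red <- smooth_reduced(red, 0.150)
  rem <- which(st$retrieval$labels$remembered)
  y <- st$retrieval$labels$class[rem]
  dec <- crossval_timecourse(subset_trials_red(red, rem), y, seed = seed,
                             step = 0.05, window = c(-0.5, 1.5))
  tt <- dec$test_times
  win <- p$pattern_window
  inside <- tt >= win[1L] + 0.1 & tt <= win[2L] - 0.1   # past taper edges
  outside <- tt < win[1L] - 0.2 | tt > win[2L] + 0.2
  units <- matrix(dec$per_fold, dec$n_reps * dec$n_folds, length(tt))
  cl <- cluster_permutation_test(units, reference = 0.5, n_perm = n_perm,
                                 seed = seed)
  msk <- cluster_mask(cl, sign = 1)
  true_win <- tt >= win[1L] & tt <= win[2L]
  list(auc_inside = mean(dec$auc[, inside]),
       auc_outside = mean(dec$auc[, outside]),
       cluster_overlap = sum(msk & true_win) / sum(true_win))
}

#' Ripple-locked decoding gain over the non-ripple surrogate baseline
#'
#' For each seed: generate a study, preprocess both sets into the pooled PCA
#' space, classify TMR segments centered on the ground-truth ripples of one
#' MTL contact, compute the surrogate baseline, and record the AUC difference
#' at ripple lag 0 (averaged over retrieval training times inside the
#' pattern window).
#'
#' @param n_seeds independent studies.
#' @param base_seed seed offset.
#' @param n_trials study size per class pair.
#' @param n_surrogates surrogate repetitions per study.
#' @return list with `gain_positive_frac`, `mean_gain`, `gains`.
#' @export
ripple_locked_validation <- function(n_seeds = 20, base_seed = 100,
                                     n_trials = 24, n_surrogates = 10) {
  gains <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    p <- sim_params(n_trials = n_trials, seed = base_seed + s)
    st <- make_task_dataset(p)
    ret_z <- zscore_across_trials(
      baseline_whole_trial(common_average_reference(st$retrieval)))
    tmr_z <- zscore_across_trials(
      baseline_whole_trial(common_average_reference(st$tmr)))
    model <- suppressWarnings(pca_fit(list(ret_z, tmr_z), 30))
    tr_red <- smooth_reduced(pca_apply(model, ret_z), 0.150)
    te_red <- smooth_reduced(pca_apply(model, tmr_z), 0.150)
    rem <- which(st$retrieval$labels$remembered)
    tr_red <- subset_trials_red(tr_red, rem)
    y_tr <- st$retrieval$labels$class[rem]
    gt <- st$ground_truth$events
    rip <- gt[gt$set == "tmr" & gt$type == "ripple" & gt$channel == "M07", ]
    rl <- ripple_locked_classify(tr_red, y_tr, te_red, rip,
                                 train_window = c(0.1, 0.6), step = 0.05)
    su <- surrogate_ripple_baseline(tr_red, y_tr, te_red, rip,
                                    n = n_surrogates, seed = base_seed + s,
                                    train_window = c(0.1, 0.6), step = 0.05)
    lag0 <- which.min(abs(rl$test_times))
    gains[s] <- mean(rl$auc[, lag0]) - mean(su$auc[, lag0])
  }
  list(gain_positive_frac = mean(gains > 0), mean_gain = mean(gains),
       gains = gains)
}

#' Family-wise error calibration of the cluster permutation test
#'
#' Null datasets of AR(1) noise (no effect anywhere); the family-wise error
#' is the fraction of datasets in which any cluster reaches p <= alpha.
#'
#' @param n_datasets simulated datasets.
#' @param n_units,n_time dataset dimensions.
#' @param n_perm permutations per dataset.
#' @param ar1 lag-one autocorrelation of the noise.
#' @param alpha cluster-level threshold.
#' @param base_seed seed offset.
#' @return observed family-wise error rate.
#' @export
cluster_test_fwer <- function(n_datasets = 500, n_units = 15, n_time = 100,
                              n_perm = 200, ar1 = 0.5, alpha = 0.05,
                              base_seed = 0) {
  fp <- logical(n_datasets)
  for (d in seq_len(n_datasets)) {
    set.seed(base_seed + d)
    dat <- t(vapply(seq_len(n_units), function(u)
      as.numeric(stats::arima.sim(list(ar = ar1), n_time)), numeric(n_time)))
    res <- cluster_permutation_test(dat, reference = 0, n_perm = n_perm,
                                    seed = base_seed + d)
    fp[d] <- length(res$clusters) > 0 &&
      any(vapply(res$clusters, `[[`, 0, "p") <= alpha)
  }
  mean(fp)
}
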