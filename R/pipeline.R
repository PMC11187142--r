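# End-to-end orchestration of the retrieval and TMR analyses on synthetic
# (or pre-epoched real) data, with config, logging and provenance.

#' Pipeline configuration
#'
#' Every parameter defaults to the published value where one exists (bands,
#' thresholds, windows, counts); the remaining knobs default to the synthetic
#' study conditions of [sim_params()].
#'
#' @param sim a [sim_params()] object describing the synthetic study.
#' @param tfr_freqs TFR frequency grid (Hz).
#' @param tfr_step TFR sliding-window step (s).
#' @param tfr_zscore_window window (s) supplying TFR normalization statistics.
#' @param fallback_mask_freqs,fallback_mask_times rectangular cluster-mask
#'   fallback (spindle band x post-cue window) used when the TFR contrast
#'   yields no significant cluster.
#' @param ripple,spindle detector parameter objects.
#' @param qualify_window post-cue window (s) of preferred spindle-ripple
#'   interactions.
#' @param comod_low,comod_high comodulogram frequency grids (Hz).
#' @param comod_segment_half half length (s) of ripple-centered segments.
#' @param n_mi_surrogates trial shuffles for the MI null.
#' @param n_decoding_surrogates repetitions of the non-ripple baseline.
#' @param pca_n retained principal components.
#' @param smooth_width running-average width (s).
#' @param decode_step classified time step (s).
#' @param train_window,test_window decoding windows (s).
#' @param ripple_segment_window ripple-centered decoding window (s).
#' @param cv_folds,cv_reps cross-validation folds and repetitions.
#' @param n_perm cluster-permutation randomizations.
#' @param peri_bin peri-event histogram bin (s).
#' @param seed master seed for all stochastic stages.
#' @param out_dir optional output directory for tables and provenance.
#' @param verbose print stage progress.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_params(),
                            tfr_freqs = 1:25,
                            tfr_step = 0.050,
                            tfr_zscore_window = c(-1, 3),
                            fallback_mask_freqs = c(12, 16),
                            fallback_mask_times = c(0.5, 1.5),
                            ripple = ripple_params(),
                            spindle = spindle_params(),
                            qualify_window = c(0.7, 1.4),
                            comod_low = seq(4, 20, by = 2),
                            comod_high = seq(30, 130, by = 10),
                            comod_segment_half = 0.75,
                            n_mi_surrogates = 100,
                            n_decoding_surrogates = 100,
                            pca_n = 30,
                            smooth_width = 0.150,
                            decode_step = 0.020,
                            train_window = c(-0.5, 1),
                            test_window = c(-0.5, 1.5),
                            ripple_segment_window = c(-0.25, 0.25),
                            cv_folds = 5, cv_reps = 5,
                            n_perm = 1000,
                            peri_bin = 0.050,
                            seed = 1L,
                            out_dir = NULL,
                            verbose = TRUE) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

.log <- function(cfg, ...) {
  if (isTRUE(cfg$verbose)) message("[ripplecue] ", ...)
  invisible(NULL)
}

# deterministic checksum of the configuration for the provenance record
config_checksum <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  b <- utf8ToInt(s)
  sprintf("%08x", sum(b * (seq_along(b) %% 997)) %% 2^31)
}

#' Provenance record for a pipeline run
#'
#' Enough to reproduce the run bit-exactly for deterministic stages and
#' statistically for stochastic ones: seed, config checksum, package and R
#' versions.
#'
#' @param cfg a [pipeline_config()].
#' @return named list.
#' @export
provenance_record <- function(cfg) {
  list(package = "ripplecue",
       version = as.character(utils::packageVersion("ripplecue")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       seed = cfg$seed,
       config_checksum = config_checksum(cfg),
       created = format(Sys.time(), "%Y-%m-%d %H:%M:%S", tz = "UTC"))
}

# smoothing applied in component space (moving average is linear, so this
# equals projecting the smoothed channel data)
smooth_reduced <- function(red, width) {
  n_win <- odd_window(width, red$fs)
  d <- dim(red$scores)
  for (tr in seq_len(d[1L])) for (cp in seq_len(d[2L]))
    red$scores[tr, cp, ] <- moving_average(red$scores[tr, cp, ], n_win)
  red
}

# per-trial ripple peak times (list over all trials of an epoch set)
.ripples_by_trial <- function(ripples, n_tr, channel = NULL) {
  if (!is.null(channel)) ripples <- ripples[ripples$channel == channel, ]
  lapply(seq_len(n_tr), function(tr)
    ripples$peak_s[!is.na(ripples$trial) & ripples$trial == tr])
}

#' Within-retrieval analysis
#'
#' Runs the retrieval arm on a synthetic study: CAR, z-scoring across trials,
#' PCA, smoothing, repeated cross-validated LDA decoding of remembered-trial
#' head orientation against chance (cluster test over fold x repetition AUC
#' time courses), MTL ripple detection, and the remembered vs not-remembered
#' peri-event ripple-rate comparison (two-sample cluster test over trials).
#'
#' @param study list with `retrieval` epochs (e.g. from [make_task_dataset()]).
#' @param cfg a [pipeline_config()].
#' @return list with `decoding`, `decoding_cluster`, `ripples`, `rate_hist`
#'   (remembered / not_remembered), `rate_cluster`, `provenance`.
#' @export
run_retrieval_analysis <- function(study, cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  ret <- study$retrieval
  .log(cfg, "retrieval: preprocessing ", n_trials(ret), " trials")
  ep <- common_average_reference(ret)
  ep <- zscore_across_trials(ep)
  red <- pca_reduce(ep, cfg$pca_n)
  red <- smooth_reduced(red, cfg$smooth_width)

  rem <- which(ret$labels$remembered)
  red_rem <- subset_trials_red(red, rem)
  y <- ret$labels$class[rem]
  .log(cfg, "retrieval: decoding ", length(rem), " remembered trials")
  dec <- crossval_timecourse(red_rem, y, k = cfg$cv_folds, reps = cfg$cv_reps,
                             seed = cfg$seed, step = cfg$decode_step,
                             window = cfg$test_window)
  units <- matrix(dec$per_fold, dec$n_reps * dec$n_folds,
                  length(dec$test_times))
  dec_cluster <- cluster_permutation_test(units, reference = 0.5,
                                          n_perm = cfg$n_perm,
                                          seed = cfg$seed)

  mtl <- ret$ch_labels[ret$roles == "mtl"]
  rate_hist <- NULL; rate_cluster <- NULL; ripples <- empty_event_table()
  if (length(mtl)) {
    .log(cfg, "retrieval: detecting ripples on ", length(mtl), " MTL channel(s)")
    ripples <- detect_ripples(ret, channels = mtl, params = cfg$ripple)
    if (is.null(ret$labels$remembered) || all(is.na(ret$labels$remembered))) {
      .log(cfg, "retrieval: no remembered labels; skipping rate comparison")
    } else {
      per_trial <- .ripples_by_trial(ripples, n_trials(ret), channel = mtl[1L])
      win <- range(ret$times)
      h_rem <- peri_event_histogram(per_trial[ret$labels$remembered], win,
                                    cfg$peri_bin)
      h_forg <- peri_event_histogram(per_trial[!ret$labels$remembered], win,
                                     cfg$peri_bin)
      rate_hist <- list(remembered = h_rem, not_remembered = h_forg)
      rates <- rbind(h_rem$trial_counts, h_forg$trial_counts) / cfg$peri_bin
      grp <- rep(c("remembered", "not_remembered"),
                 c(nrow(h_rem$trial_counts), nrow(h_forg$trial_counts)))
      rate_cluster <- cluster_permutation_test(
        rates, n_perm = cfg$n_perm, seed = cfg$seed, type = "two.sample",
        groups = factor(grp, c("remembered", "not_remembered")))
    }
  }
  list(decoding = dec, decoding_cluster = dec_cluster, ripples = ripples,
       rate_hist = rate_hist, rate_cluster = rate_cluster,
       provenance = provenance_record(cfg))
}

#' TMR (sleep) analysis chain
#'
#' Executes, in dependency order: TFR of TMR trials and learning-vs-control
#' contrast (two-sample cluster test over trials) -> SO-spindle cluster mask
#' (rectangular fallback when no cluster survives) -> per-trial cluster power
#' and median split -> ripple detection and high/low peri-event histograms ->
#' spindle detection on the strongest spindle contact -> ripple-centered
#' comodulogram with trial-shuffle surrogates -> spindle-phase/ripple
#' coupling with the V test against the trough -> high/low split temporal
#' generalization contrast -> ripple-locked classification vs the non-ripple
#' surrogate baseline. A stage failure is logged and its dependents are
#' skipped (`NULL` outputs).
#'
#' @param study list with `retrieval` and `tmr` epoch sets.
#' @param cfg a [pipeline_config()].
#' @return list with stage outputs: `tfr_cluster`, `cluster_mask_used`,
#'   `power_scores`, `split`, `ripples`, `spindles`, `ref_channel`,
#'   `rate_hist`, `comodulogram`, `phase_stats`, `split_contrast`,
#'   `ripple_locked`, `ripple_surrogate`, `ripple_locked_cluster`,
#'   `provenance`, `errors`.
#' @export
run_tmr_analysis <- function(study, cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  tmr <- study$tmr
  ret <- study$retrieval
  out <- list(provenance = provenance_record(cfg), errors = character())
  fail <- function(stage, e) {
    out$errors <<- c(out$errors, paste0(stage, ": ", conditionMessage(e)))
    .log(cfg, "stage '", stage, "' failed: ", conditionMessage(e))
    NULL
  }

  learning <- which(tmr$labels$class %in% c("left", "right"))
  control <- which(tmr$labels$class == "control")

  ## 1. TFR + learning-vs-control contrast -> cluster mask
  .log(cfg, "tmr: time-frequency decomposition")
  mask <- NULL
  out$tfr_cluster <- tryCatch({
    tf <- zscore_tfr(tfr_hanning(tmr, cfg$tfr_freqs, cfg$tfr_step),
                     cfg$tfr_zscore_window)
    out$tfr <- tf
    chm <- apply(tf$power, c(1L, 3L, 4L), mean)   # trials x freq x time
    valid <- !apply(chm, c(2L, 3L), function(v) any(is.na(v)))
    chm[is.na(chm)] <- 0
    grp <- ifelse(seq_len(n_trials(tmr)) %in% learning, "learning", "control")
    keep <- c(learning, control)
    # learning first, so positive clusters mean learning > control
    cl <- cluster_permutation_test(chm[keep, , , drop = FALSE],
                                   n_perm = cfg$n_perm, seed = cfg$seed,
                                   type = "two.sample",
                                   groups = factor(grp[keep],
                                                   c("learning", "control")))
    msk <- cluster_mask(cl, sign = 1) & valid
    if (any(msk)) mask <- msk
    cl
  }, error = function(e) fail("tfr_contrast", e))
  if (is.null(mask)) {
    .log(cfg, "tmr: no TFR cluster; using rectangular fallback mask")
    mask <- outer(cfg$tfr_freqs >= cfg$fallback_mask_freqs[1L] &
                    cfg$tfr_freqs <= cfg$fallback_mask_freqs[2L],
                  out$tfr$times >= cfg$fallback_mask_times[1L] &
                    out$tfr$times <= cfg$fallback_mask_times[2L], "&")
    out$mask_fallback <- TRUE
  } else out$mask_fallback <- FALSE
  out$cluster_mask_used <- mask

  ## 2. per-trial cluster power and median split (learning trials)
  out$split <- tryCatch({
    sc <- trial_power_score(out$tfr, mask)
    out$power_scores <- sc
    sp <- median_split(sc[learning])
    list(high = learning[sp$high], low = learning[sp$low])
  }, error = function(e) fail("median_split", e))

  ## 3. ripple + spindle detection
  mtl <- tmr$ch_labels[tmr$roles == "mtl"]
  out$ripples <- tryCatch({
    .log(cfg, "tmr: detecting ripples")
    detect_ripples(tmr, channels = mtl, params = cfg$ripple)
  }, error = function(e) fail("ripple_detection", e))
  out$ref_channel <- tryCatch(
    select_spindle_contact(subset_trials(tmr, learning),
                           band = cfg$spindle$band),
    error = function(e) fail("spindle_contact", e))
  out$spindles <- tryCatch({
    .log(cfg, "tmr: detecting spindles on ", out$ref_channel)
    detect_spindles(tmr, channels = out$ref_channel, params = cfg$spindle)
  }, error = function(e) fail("spindle_detection", e))

  ## 4. peri-event ripple histograms, high vs low SO-spindle power
  out$rate_hist <- tryCatch({
    if (is.null(out$split) || is.null(out$ripples)) NULL else {
      per_trial <- .ripples_by_trial(out$ripples, n_trials(tmr),
                                     channel = mtl[1L])
      win <- range(tmr$times)
      list(high = peri_event_histogram(per_trial[out$split$high], win,
                                       cfg$peri_bin),
           low = peri_event_histogram(per_trial[out$split$low], win,
                                      cfg$peri_bin))
    }
  }, error = function(e) fail("peri_event", e))

  ## 5. ripple-centered comodulogram with surrogates
  out$comodulogram <- tryCatch({
    if (is.null(out$ripples) || is.null(out$ref_channel)) NULL else {
      q <- .qualifying_ripples(out$ripples, cfg$qualify_window,
                               out$spindles, out$ref_channel)
      q <- q[out$ripples$channel[q] == mtl[1L]]
      if (!length(q)) stop("no qualifying ripples for coupling analyses")
      half <- cfg$comod_segment_half
      ok <- out$ripples$peak_s[q] - half >= min(tmr$times) &
        out$ripples$peak_s[q] + half <= max(tmr$times)
      q <- q[ok]
      n_half <- round(half * tmr$fs)
      ph_idx <- match(out$ref_channel, tmr$ch_labels)
      am_idx <- match(mtl[1L], tmr$ch_labels)
      seg_ph <- t(vapply(q, function(i) {
        c0 <- which.min(abs(tmr$times - out$ripples$peak_s[i]))
        tmr$data[out$ripples$trial[i], ph_idx, (c0 - n_half):(c0 + n_half)]
      }, numeric(2L * n_half + 1L)))
      seg_am <- t(vapply(q, function(i) {
        c0 <- which.min(abs(tmr$times - out$ripples$peak_s[i]))
        tmr$data[out$ripples$trial[i], am_idx, (c0 - n_half):(c0 + n_half)]
      }, numeric(2L * n_half + 1L)))
      out$qualifying_ripples <- length(q)
      .log(cfg, "tmr: comodulogram over ", length(q), " ripple segments")
      comodulogram(seg_ph, seg_am, tmr$fs, cfg$comod_low, cfg$comod_high,
                   n_surrogates = cfg$n_mi_surrogates, seed = cfg$seed)
    }
  }, error = function(e) fail("comodulogram", e))

  ## 6. spindle-phase / ripple coupling + V test against the trough
  out$phase_stats <- tryCatch({
    if (is.null(out$ripples) || is.null(out$ref_channel)) NULL else {
      q <- .qualifying_ripples(out$ripples, cfg$qualify_window,
                               out$spindles, out$ref_channel)
      q <- q[out$ripples$channel[q] == mtl[1L]]
      if (!length(q)) stop("no qualifying ripples for phase coupling")
      ph_idx <- match(out$ref_channel, tmr$ch_labels)
      angles <- vapply(q, function(i) {
        ph <- instantaneous_phase(tmr$data[out$ripples$trial[i], ph_idx, ],
                                  cfg$spindle$band, tmr$fs)
        phase_at_events(ph, out$ripples$peak_s[i], tmr$fs, t0 = tmr$times[1L])
      }, numeric(1L))
      cm <- circular_mean(angles)
      vt <- v_test(angles, pi)
      list(angles = angles, mean_direction = cm$direction, R = cm$R,
           V = vt$V, p = vt$p, n = length(angles))
    }
  }, error = function(e) fail("phase_coupling", e))

  ## 7. decoding preprocessing shared by the cross-task analyses
  dec_pre <- tryCatch({
    ret_b <- baseline_whole_trial(common_average_reference(ret))
    tmr_b <- baseline_whole_trial(common_average_reference(tmr))
    ret_z <- zscore_across_trials(ret_b)
    tmr_z <- zscore_across_trials(tmr_b)
    model <- pca_fit(list(ret_z, tmr_z), cfg$pca_n)
    ret_red <- smooth_reduced(pca_apply(model, ret_z), cfg$smooth_width)
    tmr_red <- smooth_reduced(pca_apply(model, tmr_z), cfg$smooth_width)
    list(ret_red = ret_red, tmr_red = tmr_red)
  }, error = function(e) fail("decoding_preprocess", e))

  rem <- which(ret$labels$remembered)
  if (!is.null(dec_pre)) {
    train_red <- subset_trials_red(dec_pre$ret_red, rem)
    train_y <- ret$labels$class[rem]

    ## 8. high/low SO-spindle split contrast
    out$split_contrast <- tryCatch({
      if (is.null(out$split)) NULL else {
        .log(cfg, "tmr: split-contrast temporal generalization")
        split_condition_contrast(
          train_red, train_y,
          subset_trials_red(dec_pre$tmr_red, out$split$high),
          tmr$labels$class[out$split$high],
          subset_trials_red(dec_pre$tmr_red, out$split$low),
          tmr$labels$class[out$split$low],
          train_window = cfg$train_window, test_window = cfg$test_window,
          step = cfg$decode_step)
      }
    }, error = function(e) fail("split_contrast", e))

    ## 9. ripple-locked classification vs non-ripple surrogate
    out$ripple_locked <- tryCatch({
      if (is.null(out$ripples)) NULL else {
        .log(cfg, "tmr: ripple-locked classification")
        rip1 <- out$ripples[out$ripples$channel == mtl[1L], , drop = FALSE]
        ripple_locked_classify(train_red, train_y, dec_pre$tmr_red, rip1,
                               out$spindles, out$ref_channel,
                               window = cfg$ripple_segment_window,
                               qualify_window = cfg$qualify_window,
                               train_window = cfg$train_window,
                               step = cfg$decode_step)
      }
    }, error = function(e) fail("ripple_locked", e))
    out$ripple_surrogate <- tryCatch({
      if (is.null(out$ripple_locked)) NULL else {
        .log(cfg, "tmr: surrogate baseline (", cfg$n_decoding_surrogates,
             " repetitions)")
        rip1 <- out$ripples[out$ripples$channel == mtl[1L], , drop = FALSE]
        surrogate_ripple_baseline(train_red, train_y, dec_pre$tmr_red, rip1,
                                  out$spindles, out$ref_channel,
                                  n = cfg$n_decoding_surrogates,
                                  seed = cfg$seed,
                                  window = cfg$ripple_segment_window,
                                  qualify_window = cfg$qualify_window,
                                  train_window = cfg$train_window,
                                  step = cfg$decode_step)
      }
    }, error = function(e) fail("ripple_surrogate", e))
  }
  out
}

#' Run the full synthetic study
#'
#' Generates the task dataset from `cfg$sim`, runs [run_retrieval_analysis()]
#' and [run_tmr_analysis()], and (when `cfg$out_dir` is set) writes event
#' tables and the provenance record.
#'
#' @param cfg a [pipeline_config()].
#' @return list with `study`, `retrieval`, `tmr`, `provenance`.
#' @export
run_study <- function(cfg = pipeline_config()) {
  study <- make_task_dataset(cfg$sim)
  res <- list(study = study,
              retrieval = run_retrieval_analysis(study, cfg),
              tmr = run_tmr_analysis(study, cfg),
              provenance = provenance_record(cfg))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ground_truth(study$ground_truth,
                       file.path(cfg$out_dir, "ground_truth"))
    if (nrow(res$tmr$ripples %||% empty_event_table()))
      write_event_table(res$tmr$ripples,
                        file.path(cfg$out_dir, "tmr_ripples.tsv"))
    prov <- res$provenance
    writeLines(paste(names(prov), unlist(prov), sep = "\t"),
               file.path(cfg$out_dir, "provenance.tsv"))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a small synthetic fixture study to disk
#'
#' Generates a <= 2-minute continuous recording with injected SO-spindle
#' -ripple complexes plus the task-dataset label tables, and writes: the
#' recording as EDF, the injected events and labels as tab-separated tables,
#' and a provenance record. Regeneration with the same parameters is
#' bit-identical.
#'
#' @param cfg a [pipeline_config()]; `cfg$sim$duration_s` is capped at 120 s.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
make_fixture <- function(cfg = pipeline_config(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- cfg$sim
  sim$duration_s <- min(sim$duration_s, 120)
  rec <- make_background(sim)
  inj <- inject_coupled_events(rec, sim)
  paths <- c(edf = file.path(dir, "fixture.edf"))
  write_edf(inj$recording, paths[["edf"]])
  ev_path <- file.path(dir, "fixture_events.tsv")
  write_event_table(inj$ground_truth$events, ev_path)
  paths <- c(paths, events = ev_path)
  study <- make_task_dataset(sim)
  lab_paths <- write_ground_truth(study$ground_truth,
                                  file.path(dir, "fixture_task"))
  prov <- provenance_record(cfg)
  prov_path <- file.path(dir, "provenance.tsv")
  writeLines(paste(names(prov), unlist(prov), sep = "\t"), prov_path)
  invisible(c(paths, task = lab_paths[1L], provenance = prov_path))
}
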