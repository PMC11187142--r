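#!/usr/bin/env Rscript
# TMR (sleep) arm, end to end: TFR learning-vs-control contrast and
# SO-spindle cluster mask, median split by cluster power, peri-event ripple
# histograms, ripple-centered comodulogram with trial-shuffle surrogates,
# spindle-phase/ripple coupling with the V test against the trough, high/low
# split generalization contrast, and ripple-locked classification against
# the non-ripple surrogate baseline.

library(ripplecue)

seed <- 1L
out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- pipeline_config(sim = sim_params(seed = seed), seed = seed,
                       n_perm = 1000, n_mi_surrogates = 100,
                       n_decoding_surrogates = 100,
                       out_dir = file.path(out, "tmr_run"), verbose = TRUE)
st <- make_task_dataset(cfg$sim)
res <- suppressWarnings(run_tmr_analysis(st, cfg))
stopifnot(length(res$errors) == 0)

# TFR contrast / mask
sig <- Filter(function(cl) cl$p <= 0.05 & cl$sign > 0, res$tfr_cluster$clusters)
message(sprintf("TFR contrast: %d significant positive cluster(s); %s mask",
                length(sig), if (res$mask_fallback) "fallback" else "data-driven"))

# coupling
ps <- res$phase_stats
message(sprintf(
  "spindle-ripple coupling: n = %d, direction %.1f deg, R = %.2f, V = %.2f, p = %.4g",
  ps$n, ps$mean_direction * 180 / pi, ps$R, ps$V, ps$p))
write_event_table(data.frame(angle_rad = ps$angles),
                  file.path(out, "04_coupling_angles.tsv"))

cm <- res$comodulogram
i <- which.min(abs(cm$low_freqs - 13.5)); j <- which.min(abs(cm$high_freqs - 90))
message(sprintf(
  "comodulogram: MI(spindle, ripple) = %.4g vs surrogate median %.4g",
  cm$mi[i, j], median(cm$surrogate_mi[, i, j])))
write.table(cm$mi, file.path(out, "04_comodulogram_mi.tsv"), sep = "\t",
            col.names = NA)

# ripple-locked classification vs surrogate
lag0 <- which.min(abs(res$ripple_locked$test_times))
tw <- res$ripple_locked$train_times >= 0.1 & res$ripple_locked$train_times <= 0.6
obs <- mean(res$ripple_locked$auc[tw, lag0])
sur <- mean(res$ripple_surrogate$auc[tw, lag0])
message(sprintf(
  "ripple-locked decoding: AUC %.3f at ripple lag 0 vs surrogate %.3f (%d segments)",
  obs, sur, res$ripple_locked$n_events))
write.table(res$ripple_locked$auc, file.path(out, "04_ripple_locked_auc.tsv"),
            sep = "\t", col.names = NA)
write.table(res$ripple_surrogate$auc,
            file.path(out, "04_ripple_surrogate_auc.tsv"), sep = "\t",
            col.names = NA)

# split contrast
message(sprintf(
  "high-vs-low SO-spindle split: mean AUC contrast %.3f over the test window",
  mean(res$split_contrast$contrast)))
write.table(res$split_contrast$contrast,
            file.path(out, "04_split_contrast.tsv"), sep = "\t",
            col.names = NA)
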