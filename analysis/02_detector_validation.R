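#!/usr/bin/env Rscript
# Validate the ripple detector against ground truth on a long synthetic
# recording (10 min, 50 injected ripples at 4x the background SD), and check
# that detected ripples on the task data fall inside detected spindles.

library(ripplecue)

seed <- 1L
out <- "results"
dir.create(out, showWarnings = FALSE)

det <- evaluate_ripple_detection(seed = seed, duration_s = 600, n_events = 50)
message(sprintf(
  "detector recovery: recall %.2f, precision %.2f, median peak error %.1f ms",
  det$recall, det$precision, det$median_peak_error_s * 1000))

st <- make_task_dataset(sim_params(seed = seed))
rip <- detect_ripples(st$tmr, channels = "M07")
spd <- detect_spindles(st$tmr, channels = "C01")
q <- rip$peak_s >= 0.7 & rip$peak_s <= 1.4
inside <- vapply(which(q), function(i) {
  s <- spd[spd$trial == rip$trial[i], , drop = FALSE]
  nrow(s) > 0 && any(s$onset_s <= rip$peak_s[i] & rip$peak_s[i] <= s$offset_s)
}, logical(1L))
message(sprintf(
  "task data: %d ripples (%d in the 0.7-1.4 s window, %.0f%% inside a detected spindle), %d spindles",
  nrow(rip), sum(q), 100 * mean(inside), nrow(spd)))

write_event_table(rip, file.path(out, "02_tmr_ripples.tsv"))
write_event_table(spd, file.path(out, "02_tmr_spindles.tsv"))
write_event_table(
  data.frame(metric = c("recall", "precision", "median_peak_error_ms",
                        "ripples_in_window_inside_spindle_frac"),
             value = c(det$recall, det$precision,
                       det$median_peak_error_s * 1000, mean(inside))),
  file.path(out, "02_detector_validation.tsv"))
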