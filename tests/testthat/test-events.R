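# Ripple and spindle detection, cycle counting, spindle-contact selection.

test_that("constant or zero-variance signals yield zero events", {
  rec <- recording(matrix(0, 1, 5000), 1000, roles = "mtl")
  expect_identical(nrow(detect_ripples(rec)), 0L)
  rec2 <- recording(matrix(3, 1, 5000), 1000)
  expect_identical(nrow(detect_spindles(rec2)), 0L)
})

test_that("a single injected burst is found with correct peak localization", {
  rec <- pink_recording(duration_s = 10, fs = 1000, seed = 8)
  rec <- with_burst(rec, ch = 1, center_s = 5.0, freq = 90, dur = 0.1,
                    amp = 4 * sd(rec$data[1, ]))     # 4x background RMS
  ev <- detect_ripples(rec)
  expect_identical(nrow(ev), 1L)
  expect_gte(ev$peak_s, 4.95)
  expect_lte(ev$peak_s, 5.15)
  expect_gte(ev$n_cycles, 3L)
  expect_true(ev$onset_s <= ev$peak_s & ev$peak_s <= ev$offset_s)
  # independent brute-force scan of the smoothed RMS confirms a single
  # duration-valid supra-threshold run
  fr <- ripplecue:::.filter_rms(rec$data[1, ], 1000, ripple_params())
  thr <- mean(fr$rms) + 2 * sd(fr$rms)
  r <- rle(fr$rms > thr)
  runs <- sum(r$values & r$lengths >= 25 & r$lengths <= 300)
  expect_identical(runs, 1L)
})

test_that("detector recalls well-separated injected bursts with high precision", {
  rec <- pink_recording(duration_s = 30, fs = 1000, seed = 9)
  centers <- seq(2, 29, by = 3)                       # 10 bursts, >= 1 s apart
  amp <- 4 * sd(rec$data[1, ])
  for (cc in centers) rec <- with_burst(rec, 1, cc, 90, 0.1, amp)
  ev <- detect_ripples(rec)
  hits <- vapply(centers, function(cc) any(abs(ev$peak_s - cc) <= 0.05),
                 logical(1L))
  expect_gte(sum(hits), 9L)
  false_alarms <- vapply(ev$peak_s, function(pk)
    all(abs(centers - pk) > 0.05), logical(1L))
  expect_lte(sum(false_alarms), 2L)
})

test_that("cycle counting matches the analytic zero-crossing count", {
  fs <- 1000
  seg50 <- sin(2 * pi * 90 * seq(0, 0.05, by = 1 / fs))   # 4.5 cycles
  expect_identical(count_cycles(seg50, c(80, 120), fs), 4L)
  seg25 <- sin(2 * pi * 90 * seq(0, 0.025, by = 1 / fs))  # 2.25 cycles
  expect_identical(count_cycles(seg25, c(80, 120), fs), 2L)
  expect_identical(count_cycles(rep(2, 100), c(80, 120), fs), 0L)
  expect_identical(count_cycles(numeric(1), c(80, 120), fs), 0L)
})

test_that("short low-cycle bursts are rejected by the cycle criterion", {
  # smooth (1/f^2) background so the raw signal carries few fast crossings
  # and the cycle criterion sees the burst itself
  p <- sim_params(fs = 1000, n_channels = 1, channel_roles = "mtl",
                  duration_s = 10, background_slope = 2, seed = 10)
  rec <- make_background(p)
  amp <- 4 * sd(rec$data[1, ])
  rec_short <- with_burst(rec, 1, 5.0, 90, 0.025, amp)   # ~2 visible cycles
  rec_long <- with_burst(rec, 1, 5.0, 90, 0.1, amp)      # ~8 visible cycles
  p_strict <- ripple_params(min_cycles = 3, min_dur = 0.01)
  p_loose <- ripple_params(min_cycles = 0, min_dur = 0.01)
  near <- function(ev) sum(abs(ev$peak_s - 5) < 0.1)
  expect_gte(near(detect_ripples(rec_short, params = p_loose)), 1L)
  expect_identical(near(detect_ripples(rec_short, params = p_strict)), 0L)
  expect_gte(near(detect_ripples(rec_long, params = p_strict)), 1L)
})

test_that("detection is invariant to DC offset and amplitude scaling", {
  rec <- pink_recording(duration_s = 20, fs = 1000, seed = 11)
  amp <- 4 * sd(rec$data[1, ])
  for (cc in c(4, 9, 14)) rec <- with_burst(rec, 1, cc, 90, 0.1, amp)
  ev <- detect_ripples(rec)
  rec_dc <- rec; rec_dc$data <- rec_dc$data + 100
  rec_sc <- rec; rec_sc$data <- rec_sc$data * 2
  ev_dc <- detect_ripples(rec_dc)
  ev_sc <- detect_ripples(rec_sc)
  expect_equal(ev_dc$peak_s, ev$peak_s, tolerance = 1e-9)
  expect_equal(ev_sc$peak_s, ev$peak_s, tolerance = 1e-9)
  expect_equal(ev_sc$peak_amp, 2 * ev$peak_amp, tolerance = 1e-9)
})

test_that("spindle detector finds a 13 Hz burst with plausible duration", {
  p <- sim_params(fs = 1000, n_channels = 1, channel_roles = "cortical",
                  duration_s = 20, seed = 12)
  rec <- make_background(p)
  # 0.75 s spindle burst at 3x the background SD (the generator's scaling)
  wave <- ripplecue:::spindle_burst_wave(13, 0.75, 1000, 3 * sd(rec$data[1, ]))
  idx <- round(10 * 1000) + seq_along(wave)
  rec$data[1, idx] <- rec$data[1, idx] + wave
  ev <- detect_spindles(rec)
  expect_identical(nrow(ev), 1L)
  expect_gte(ev$duration_s, 0.5)
  expect_lte(ev$duration_s, 1.0)
  # two bursts 5 s apart -> two non-overlapping events
  rec2 <- rec
  rec2$data[1, idx + 5000] <- rec2$data[1, idx + 5000] + wave
  ev2 <- detect_spindles(rec2)
  expect_identical(nrow(ev2), 2L)
  expect_lte(ev2$offset_s[1L], ev2$onset_s[2L])
})

test_that("empty scope mask is rejected", {
  rec <- pink_recording(duration_s = 5, fs = 1000, seed = 13)
  expect_error(detect_ripples(rec, scope_mask = rep(FALSE, 5000)), "scope")
})

test_that("spindle-contact selection finds the injected channel and tie-breaks", {
  p <- sim_params(fs = 500, n_channels = 3,
                  channel_roles = rep("cortical", 3), duration_s = 8,
                  seed = 14)
  rec <- make_background(p)
  ep <- epoch_recording(rec, onsets = c(2, 5), window = c(-1, 2))
  # inject spindle band power into channel 2 ("C02") after the lock
  idx <- which(ep$times >= 0.2 & ep$times <= 1.2)
  for (tr in 1:2)
    ep$data[tr, 2, idx] <- ep$data[tr, 2, idx] +
      30 * sin(2 * pi * 13 * ep$times[idx])
  expect_identical(select_spindle_contact(ep), "C02")
  # invariance to trial order
  expect_identical(select_spindle_contact(subset_trials(ep, 2:1)), "C02")
  # identical channels tie-break to the first
  ep$data[, 1, ] <- ep$data[, 2, ]
  ep$data[, 3, ] <- ep$data[, 2, ]
  expect_identical(select_spindle_contact(ep), "C01")
})

test_that("coupled synthetic ripples mostly fall inside detected spindles", {
  cs <- cached_study()
  tmr <- cs$study$tmr
  spd <- detect_spindles(tmr, channels = "C01")
  rip <- detect_ripples(tmr, channels = "M07")
  q <- rip$peak_s >= 0.7 & rip$peak_s <= 1.4
  inside <- vapply(which(q), function(i) {
    s <- spd[spd$trial == rip$trial[i], , drop = FALSE]
    nrow(s) > 0 && any(s$onset_s <= rip$peak_s[i] & rip$peak_s[i] <= s$offset_s)
  }, logical(1L))
  expect_gte(mean(inside), 0.8)
})
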