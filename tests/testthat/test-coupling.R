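# Phase extraction, Modulation Index, comodulogram, surrogates, event-locked
# phase statistics and peri-event histograms.

test_that("phase convention anchors 0 at peaks and +-pi at troughs", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)
  ph <- instantaneous_phase(cos(2 * pi * 13 * t), c(12, 15), fs)
  i0 <- round(2 * fs) + 1L                      # t = 2 s, cos peak (26 cycles)
  expect_lt(abs(ph[i0]), 0.1)
  ph_neg <- instantaneous_phase(-cos(2 * pi * 13 * t), c(12, 15), fs)
  expect_gt(abs(ph_neg[i0]), pi - 0.1)
  # unwrapped phase advances at 2*pi*13 rad/s mid-signal
  mid <- (fs):(3 * fs)
  dphi <- diff(ph[mid])
  dphi[dphi < -pi] <- dphi[dphi < -pi] + 2 * pi
  expect_equal(mean(dphi) * fs, 2 * pi * 13, tolerance = 0.05 * 2 * pi * 13)
  expect_error(instantaneous_phase(t, c(400, 600), fs), "Nyquist")
})

test_that("Modulation Index matches analytic cases exactly", {
  set.seed(1)
  ph <- runif(5000, -pi, pi)
  expect_equal(modulation_index(ph, rep(2, 5000)), 0, tolerance = 1e-12)
  # all amplitude mass in one bin -> MI = 1
  ph_one <- rep(0.1, 300)
  expect_equal(modulation_index(ph_one, rep(1, 300)), 1, tolerance = 1e-12)
  # P = (0.5, 0.5, 0, ...) over 18 bins -> log(9)/log(18)
  centers <- -pi + (c(1, 2) - 0.5) * 2 * pi / 18
  ph2 <- rep(centers, each = 100)
  expect_equal(modulation_index(ph2, rep(1, 200)), log(9) / log(18),
               tolerance = 1e-12)
  expect_warning(mi0 <- modulation_index(ph, rep(0, 5000)), "zero")
  expect_identical(mi0, 0)
})

test_that("Modulation Index equals the brute-force oracle on random inputs", {
  set.seed(7)
  for (rep in 1:5) {
    ph <- runif(800, -pi, pi)
    amp <- abs(rnorm(800)) * (1 + 0.5 * cos(ph - pi / 3))
    expect_equal(modulation_index(ph, amp), mi_oracle(ph, amp),
                 tolerance = 1e-12)
  }
})

test_that("MI is invariant to amplitude rescaling and bounded in [0, 1]", {
  set.seed(8)
  ph <- runif(2000, -pi, pi)
  amp <- abs(rnorm(2000))
  mi <- modulation_index(ph, amp)
  expect_equal(modulation_index(ph, 3.7 * amp), mi, tolerance = 1e-12)
  expect_gte(mi, 0); expect_lte(mi, 1)
})

# 14 Hz phase modulating 90 Hz amplitude, segment matrix trials x time
coupled_segments <- function(n_seg = 12, dur = 1, fs = 500, depth = 0.9,
                             noise = 0.5, seed = 1) {
  set.seed(seed)
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  ph_sig <- t(replicate(n_seg, cos(2 * pi * 14 * t + runif(1, 0, 2 * pi))))
  carrier <- matrix(0, n_seg, length(t))
  for (i in seq_len(n_seg)) {
    lowphase <- 2 * pi * 14 * t + acos(ph_sig[i, 1])  # same starting phase
    env <- (1 + depth * cos(lowphase - pi)) / 2
    carrier[i, ] <- env * sin(2 * pi * 90 * t)
  }
  list(phase_src = ph_sig + noise * matrix(rnorm(n_seg * length(t)), n_seg),
       amp_src = carrier + noise * matrix(rnorm(n_seg * length(t)), n_seg))
}

test_that("comodulogram localizes 14 Hz -> 90 Hz coupling", {
  sg <- coupled_segments(seed = 2)
  cm <- comodulogram(sg$phase_src, sg$amp_src, fs = 500,
                     low_freqs = seq(4, 20, 2), high_freqs = seq(30, 130, 10))
  pk <- arrayInd(which.max(cm$mi), dim(cm$mi))
  expect_lte(abs(cm$low_freqs[pk[1]] - 14), 2)
  expect_lte(abs(cm$high_freqs[pk[2]] - 90), 10)
  # doubling the modulation depth increases the peak MI
  sg_weak <- coupled_segments(depth = 0.45, seed = 2)
  cm_weak <- comodulogram(sg_weak$phase_src, sg_weak$amp_src, fs = 500,
                          low_freqs = 14, high_freqs = 90)
  cm_strong <- comodulogram(sg$phase_src, sg$amp_src, fs = 500,
                            low_freqs = 14, high_freqs = 90)
  expect_gt(cm_strong$mi[1, 1], cm_weak$mi[1, 1])
})

test_that("surrogates reproduce the observed MI for identical trials and are seeded", {
  t <- seq(0, 0.5, by = 1 / 500)
  seg <- matrix(rep(sin(2 * pi * 14 * t), 4), 4, byrow = TRUE)
  ph <- t(apply(seg, 1, instantaneous_phase, band = c(12, 16), fs = 500))
  am <- t(apply(seg, 1, instantaneous_amplitude, band = c(80, 100), fs = 500))
  am <- am + 1                                   # non-degenerate amplitude
  s1 <- mi_surrogates(ph, am, n = 8, seed = 3)
  obs <- modulation_index(as.vector(t(ph)), as.vector(t(am)))
  expect_equal(s1, rep(obs, 8), tolerance = 1e-12)
  s2 <- mi_surrogates(ph, am, n = 8, seed = 3)
  expect_identical(s1, s2)
  expect_error(mi_surrogates(ph[1:2, ], am[1:2, ], n = 8), ">= 3")
})

test_that("coupled MI beats its trial-shuffle null; null calibrates on noise", {
  sg <- coupled_segments(n_seg = 10, seed = 4, noise = 0.3)
  cm <- comodulogram(sg$phase_src, sg$amp_src, fs = 500, low_freqs = 14,
                     high_freqs = 90, n_surrogates = 50, seed = 5)
  expect_gt(cm$mi[1, 1], max(cm$surrogate_mi[, 1, 1]))
})

test_that("phase at events recovers the injected coupling angle", {
  fs <- 1000
  t <- seq(0, 3, by = 1 / fs)
  x <- cos(2 * pi * 13 * t)
  ph <- instantaneous_phase(x, c(12, 15), fs)
  # peaks of the oscillation (phase 0) at multiples of 1/13
  peaks <- (13:26) / 13
  ang_peak <- phase_at_events(ph, peaks, fs)
  expect_lt(max(abs(ang_peak)), 10 * pi / 180)
  # troughs at half-cycle offsets -> +-pi
  troughs <- peaks + 1 / 26
  ang_trough <- phase_at_events(ph, troughs, fs)
  expect_lt(max(pi - abs(ang_trough)), 10 * pi / 180)
  # window restriction and empty results
  expect_identical(length(phase_at_events(ph, peaks, fs,
                                          window = c(1.95, 2.05))), 1L)
  expect_identical(phase_at_events(ph, numeric(0), fs), numeric(0))
})

test_that("circular mean matches vector summation", {
  cm <- circular_mean(rep(pi / 2, 5))
  expect_equal(cm$direction, pi / 2, tolerance = 1e-12)
  expect_equal(cm$R, 1, tolerance = 1e-12)
  cm2 <- circular_mean(c(0, pi))                    # antipodal
  expect_identical(cm2$R, 0)
  expect_true(is.na(cm2$direction))
  cm3 <- circular_mean(c(0, pi / 2))
  expect_equal(cm3$direction, pi / 4, tolerance = 1e-12)
  expect_equal(cm3$R, cos(pi / 4), tolerance = 1e-12)
  # oracle: explicit resultant vector
  set.seed(9)
  ang <- runif(50, -pi, pi)
  cm4 <- circular_mean(ang)
  expect_equal(cm4$direction, atan2(mean(sin(ang)), mean(cos(ang))),
               tolerance = 1e-12)
  expect_equal(cm4$R, sqrt(mean(sin(ang))^2 + mean(cos(ang))^2),
               tolerance = 1e-12)
})

test_that("circular mean is rotation-equivariant", {
  set.seed(10)
  ang <- rvonmises(40, 1, 2)
  base <- circular_mean(ang)
  for (delta in c(0.5, -2, pi)) {
    rot <- circular_mean(wrap_angle(ang + delta))
    d <- (rot$direction - base$direction - delta) %% (2 * pi)
    expect_lt(min(d, 2 * pi - d), 1e-10)
    expect_equal(rot$R, base$R, tolerance = 1e-12)
  }
})

test_that("peri-event histogram rates satisfy the conservation identity", {
  h <- peri_event_histogram(list(0.01, numeric(0)), c(0, 1), bin = 0.05)
  expect_equal(h$rate[1L], 10)                      # 1 / (2 trials * 0.05 s)
  expect_true(all(h$rate[-1L] == 0))
  # conservation: sum(rate) * bin * n_trials = total in-window events
  set.seed(11)
  evs <- replicate(7, sort(runif(rpois(1, 3), 0, 2)), simplify = FALSE)
  h2 <- peri_event_histogram(evs, c(0, 2), bin = 0.05)
  expect_equal(sum(h2$rate) * 0.05 * 7, sum(lengths(evs)), tolerance = 1e-12)
  expect_error(peri_event_histogram(list(0.1), c(0, 0.5), bin = 1), "bin")
})

test_that("ripple-spindle onset cross-histogram recovers the injected lag", {
  sp <- c(5, 15, 25)
  rp <- sp + 0.37
  h <- event_onset_cross_histogram(rp, sp, half_window = 1, bin = 0.05)
  expect_equal(sum(h$pct), 100)
  expect_equal(h$lag_mid[which.max(h$pct)], 0.375, tolerance = 1e-9)
  h0 <- event_onset_cross_histogram(1, 1)
  expect_equal(h0$pct[which.min(abs(h0$lag_mid - 0.025))], 100)
  expect_error(event_onset_cross_histogram(numeric(0), sp), "non-empty")
})
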