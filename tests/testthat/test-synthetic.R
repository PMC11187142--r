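# Synthetic-data generator: backgrounds, coupled events, task datasets,
# class patterns.

test_that("background noise is zero-mean, scaled, and deterministic", {
  p <- sim_params(n_channels = 2, channel_roles = rep("cortical", 2),
                  duration_s = 10, fs = 200, background_slope = 0, seed = 5)
  rec <- make_background(p)
  n <- ncol(rec$data)
  for (ch in 1:2) {
    expect_lt(abs(mean(rec$data[ch, ])), 3 * 10 / sqrt(n))
    expect_equal(sd(rec$data[ch, ]), 10, tolerance = 1e-12)
  }
  expect_identical(rec$data, make_background(p)$data)
})

test_that("1/f slope of the background PSD matches the requested exponent", {
  p <- sim_params(n_channels = 1, channel_roles = "cortical",
                  duration_s = 30, fs = 200, background_slope = 1, seed = 2)
  rec <- make_background(p)
  sp <- spec.pgram(ts(rec$data[1, ], frequency = p$fs), plot = FALSE,
                   taper = 0)
  sel <- sp$freq >= 1 & sp$freq <= 40
  slope <- unname(coef(lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[2L])
  expect_gt(slope, -1.3)
  expect_lt(slope, -0.7)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(sim_params(duration_s = -1), "positive")
  expect_error(sim_params(fs = 150), "Nyquist|ripple band")
  expect_error(sim_params(coupling_kappa = -1), "kappa")
  expect_error(sim_params(ripple_dur = 0.4), "ripple_dur")
})

test_that("degenerate von Mises concentration pins all ripple angles to mu", {
  p <- sim_params(duration_s = 40, coupling_kappa = 1e9, coupling_mu = pi,
                  spindle_rate = 0.1, seed = 3)
  inj <- inject_coupled_events(make_background(p), p)
  ang <- inj$ground_truth$events$angle
  ang <- ang[!is.na(ang)]
  expect_gt(length(ang), 0)
  # concentration is capped, so draws scatter by ~1/sqrt(kappa_max)
  expect_true(all(abs(abs(ang) - pi) < 0.01))
})

test_that("zero concentration yields circularly uniform ripple angles", {
  hits <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    p <- sim_params(duration_s = 60, coupling_kappa = 0, spindle_rate = 0.2,
                    ripple_rate = 2, seed = s)
    inj <- inject_coupled_events(make_background(p), p)
    ev <- inj$ground_truth$events
    # one angle per burst (rows are duplicated across MTL channels)
    ang <- ev$angle[!is.na(ev$angle) & ev$channel == "M07"]
    if (rayleigh_test(ang)$p > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 0.9 * n_seeds)
})

test_that("ripple count scales exactly with the rate", {
  count_for <- function(rate) {
    p <- sim_params(duration_s = 40, ripple_rate = rate, spindle_rate = 0.1,
                    seed = 4)
    inj <- inject_coupled_events(make_background(p), p)
    ev <- inj$ground_truth$events
    sum(ev$type == "ripple" & ev$channel == "M07")
  }
  expect_identical(count_for(2) , 2L * count_for(1))
})

test_that("event bookkeeping: angles wrapped, events inside the recording", {
  p <- sim_params(duration_s = 40, seed = 6)
  inj <- inject_coupled_events(make_background(p), p)
  ev <- inj$ground_truth$events
  ang <- ev$angle[!is.na(ev$angle)]
  expect_true(all(ang > -pi & ang <= pi))
  expect_true(all(ev$onset_s >= 0))
  expect_true(all(ev$onset_s + ev$duration_s <= p$duration_s))
})

test_that("coupled ripples with no spindle opportunity raise an error", {
  p <- sim_params(duration_s = 5, spindle_rate = 0.01, ripple_rate = 1,
                  coupling_kappa = 2, seed = 1)
  expect_error(inject_coupled_events(make_background(p), p), "spindle")
})

test_that("task dataset balances classes and flags remembered trials", {
  cs <- cached_study()
  st <- cs$study; p <- cs$params
  n_pc <- as.integer(p$n_trials %/% 2)
  expect_identical(as.integer(table(st$retrieval$labels$class)),
                   rep(n_pc, 2L))
  expect_identical(sum(st$retrieval$labels$remembered),
                   2L * as.integer(round(p$remembered_frac * n_pc)))
  tt <- table(st$tmr$labels$class)
  expect_identical(as.integer(tt[c("left", "right")]), rep(n_pc, 2L))
  # determinism
  st2 <- make_task_dataset(p)
  expect_identical(st$retrieval$data, st2$retrieval$data)
  expect_identical(st$tmr$data, st2$tmr$data)
  expect_identical(st$ground_truth$events, st2$ground_truth$events)
})

test_that("zero pattern snr leaves retrieval classes statistically identical", {
  p <- sim_params(n_trials = 16, pattern_snr = 0, seed = 9)
  st <- make_task_dataset(p)
  idx <- st$retrieval$times >= 0.1 & st$retrieval$times <= 0.6
  chm <- apply(st$retrieval$data[, , idx], 1L, mean)
  cl <- st$retrieval$labels$class
  expect_gt(t.test(chm[cl == "left"], chm[cl == "right"])$p.value, 0.01)
})

test_that("class pattern is confined to its window and scales with snr", {
  ep <- noise_epochs(n_tr = 8, n_ch = 4, seed = 11)
  tpl <- class_templates(4, seed = 1)
  cls <- ep$labels$class
  out <- inject_class_pattern(ep, cls, c(0, 0.5), snr = 2, tpl)
  outside <- ep$times < 0 | ep$times > 0.5
  expect_identical(out$data[, , outside], ep$data[, , outside])
  expect_false(identical(out$data[, , !outside], ep$data[, , !outside]))
  expect_identical(inject_class_pattern(ep, cls, c(0, 0.5), 0, tpl), ep)
  expect_error(inject_class_pattern(ep, cls, c(0, 2), 1, tpl), "window")
})

test_that("within-class correlation exceeds between-class in the pattern window", {
  cs <- cached_study()
  st <- cs$study
  idx <- st$retrieval$times >= 0.1 & st$retrieval$times <= 0.6
  rem <- which(st$retrieval$labels$remembered)
  vecs <- t(vapply(rem, function(tr) as.vector(st$retrieval$data[tr, , idx]),
                   numeric(sum(idx) * 8)))
  cl <- st$retrieval$labels$class[rem]
  cc <- cor(t(vecs))
  same <- outer(cl, cl, "==") & upper.tri(cc)
  diff <- outer(cl, cl, "!=") & upper.tri(cc)
  expect_gt(mean(cc[same]), mean(cc[diff]))
})

test_that("ground truth exports round-trip through tab-separated tables", {
  cs <- cached_study()
  td <- withr::local_tempdir()
  paths <- write_ground_truth(cs$study$ground_truth, file.path(td, "gt"))
  ev <- read_event_table(file.path(td, "gt_events.tsv"))
  expect_identical(nrow(ev), nrow(cs$study$ground_truth$events))
  expect_true(all(c("onset_s", "channel", "type", "class", "remembered")
                  %in% names(ev)))
})
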