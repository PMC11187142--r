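# PCA reduction, shrinkage LDA, AUC, cross-validated and generalized
# decoding, ripple-locked classification.

test_that("PCA captures low-rank structure and reconstructs completely", {
  set.seed(1)
  n_tr <- 10; n_t <- 50
  s1 <- sin(2 * pi * 3 * seq_len(n_t) / n_t)
  s2 <- cos(2 * pi * 7 * seq_len(n_t) / n_t)
  mix <- matrix(rnorm(8 * 2), 8, 2)
  dat <- array(0, c(n_tr, 8, n_t))
  for (tr in seq_len(n_tr)) {
    a <- rnorm(2)
    dat[tr, , ] <- mix %*% rbind(a[1] * s1, a[2] * s2)
  }
  ep <- epochs(dat, seq(0, length.out = n_t, by = 0.01) - 0.1, 100,
               data.frame(x = seq_len(n_tr)))
  ws <- capture_warnings(red <- pca_reduce(ep, 30))
  expect_true(any(grepl("rank|channel count", ws)))
  expect_gt(sum(red$explained_variance[1:2]), 0.99)
  # full-component reconstruction equals the input
  model <- suppressWarnings(pca_fit(ep, 8))
  red8 <- pca_apply(model, ep)
  rec <- array(0, dim(ep$data))
  for (tr in seq_len(n_tr))
    rec[tr, , ] <- model$rotation %*% red8$scores[tr, , ] + model$center
  expect_equal(rec, ep$data, tolerance = 1e-8)
})

test_that("shrinkage LDA separates Gaussian clouds and matches MASS at gamma 0", {
  set.seed(2)
  X <- rbind(matrix(rnorm(200, 0), 100), matrix(rnorm(200, 6), 100))
  y <- rep(c("a", "b"), each = 100)
  m <- train_lda(X, y)
  expect_equal(auc(lda_scores(m, X), y), 1.0)
  # shuffled labels -> chance
  ysh <- sample(y)
  msh <- train_lda(X, ysh)
  expect_lt(abs(auc(lda_scores(msh, X), ysh) - 0.5), 0.1)
  # duplicating trials leaves the direction unchanged
  m2 <- train_lda(rbind(X, X), c(y, y), gamma = 0.1)
  m1 <- train_lda(X, y, gamma = 0.1)
  cosine <- sum(m1$w * m2$w) / sqrt(sum(m1$w^2) * sum(m2$w^2))
  expect_gt(cosine, 0.999)
  # cross-check against MASS::lda at zero shrinkage
  skip_if_not_installed("MASS")
  m0 <- train_lda(X, y, gamma = 0)
  ml <- MASS::lda(X, grouping = y)
  w_mass <- as.numeric(ml$scaling)
  cosine0 <- abs(sum(m0$w * w_mass)) / sqrt(sum(m0$w^2) * sum(w_mass^2))
  expect_gt(cosine0, 0.999)
  expect_error(train_lda(X, rep("a", 200)), "two classes")
})

test_that("AUC equals the concordant-pair oracle, including ties", {
  expect_equal(auc(c(0.9, 0.8, 0.7, 0.1), c("b", "b", "a", "a"),
                   positive = "b"), 1.0)
  expect_equal(auc(c(0.5, 0.5), c("a", "b"), positive = "b"), 0.5)
  expect_equal(auc(c(0.9, 0.4, 0.6, 0.2), c("b", "b", "a", "a"),
                   positive = "b"), 0.75)
  set.seed(3)
  for (i in 1:10) {
    n <- sample(10:100, 1)
    sc <- round(rnorm(n), 1)                      # coarse grid forces ties
    y <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    expect_identical(auc(sc, y, positive = "b"), auc_oracle(sc, y, "b"))
  }
  skip_if_not_installed("pROC")
  set.seed(4)
  sc <- rnorm(60); y <- sample(c("a", "b"), 60, replace = TRUE)
  expect_equal(auc(sc, y, positive = "b"),
               as.numeric(suppressMessages(pROC::auc(y, sc, levels = c("a", "b"),
                                                     direction = "<"))),
               tolerance = 1e-12)
})

test_that("cross-validated decoding recovers the injected pattern window", {
  cs <- cached_study()
  st <- cs$study
  ep <- zscore_across_trials(common_average_reference(st$retrieval))
  red <- suppressWarnings(pca_reduce(ep, 30))
  red <- ripplecue:::smooth_reduced(red, 0.150)
  rem <- which(st$retrieval$labels$remembered)
  dec <- crossval_timecourse(subset_trials_red(red, rem),
                             st$retrieval$labels$class[rem],
                             seed = 1, step = 0.05, window = c(-0.5, 1.5))
  inwin <- dec$test_times >= 0.2 & dec$test_times <= 0.5
  farout <- dec$test_times < -0.1 | dec$test_times > 1.0
  expect_gt(mean(dec$auc[, inwin]), 0.9)
  expect_lt(abs(mean(dec$auc[, farout]) - 0.5), 0.12)
  # seeded fold assignment reproduces bit-exactly
  dec2 <- crossval_timecourse(subset_trials_red(red, rem),
                              st$retrieval$labels$class[rem],
                              seed = 1, step = 0.05, window = c(-0.5, 1.5))
  expect_identical(dec$per_fold, dec2$per_fold)
  # fold reduction warning on a balanced 3-per-class subset
  lab <- st$retrieval$labels
  sub <- c(which(lab$remembered & lab$class == "left")[1:3],
           which(lab$remembered & lab$class == "right")[1:3])
  expect_warning(
    crossval_timecourse(subset_trials_red(red, sub),
                        st$retrieval$labels$class[sub],
                        k = 5, reps = 1, seed = 1, step = 0.5),
    "folds")
})

test_that("temporal generalization finds the shared pattern and flips with labels", {
  set.seed(5)
  tpl <- class_templates(6, seed = 3)
  mk <- function(n_tr, window, seed) {
    ep <- noise_epochs(n_tr = n_tr, n_ch = 6, fs = 100, window = c(-0.5, 1.5),
                       seed = seed)
    inject_class_pattern(ep, ep$labels$class, window, snr = 1.5, tpl)
  }
  train_ep <- mk(24, c(0.1, 0.3), seed = 6)
  test_ep <- mk(24, c(0.9, 1.1), seed = 7)
  model <- pca_fit(list(train_ep, test_ep), 6)
  tr_red <- pca_apply(model, train_ep)
  te_red <- pca_apply(model, test_ep)
  tg <- temporal_generalization(tr_red, train_ep$labels$class,
                                te_red, test_ep$labels$class,
                                train_window = c(-0.4, 1.4),
                                test_window = c(-0.4, 1.4), step = 0.1)
  at <- function(tt, et) tg$auc[which.min(abs(tg$train_times - tt)),
                                which.min(abs(tg$test_times - et))]
  expect_gt(at(0.2, 1.0), 0.9)
  expect_lt(abs(at(-0.3, -0.3) - 0.5), 0.25)
  # swapping class names flips AUC
  y_sw <- ifelse(test_ep$labels$class == "left", "right", "left")
  tg_sw <- temporal_generalization(tr_red, train_ep$labels$class,
                                   te_red, y_sw,
                                   train_window = c(-0.4, 1.4),
                                   test_window = c(-0.4, 1.4), step = 0.1)
  expect_equal(tg_sw$auc, 1 - tg$auc, tolerance = 1e-12)
  # mismatched component spaces are rejected
  other <- suppressWarnings(pca_reduce(mk(24, c(0.1, 0.3), seed = 8), 6))
  expect_error(temporal_generalization(tr_red, train_ep$labels$class,
                                       other, test_ep$labels$class),
               "space")
})

test_that("split contrast is zero for identical splits and antisymmetric", {
  set.seed(9)
  tpl <- class_templates(5, seed = 4)
  ep <- noise_epochs(n_tr = 16, n_ch = 5, fs = 100, window = c(-0.5, 1),
                     seed = 10)
  ep <- inject_class_pattern(ep, ep$labels$class, c(0.2, 0.6), 1.5, tpl)
  model <- pca_fit(ep, 5)
  red <- pca_apply(model, ep)
  y <- ep$labels$class
  same <- split_condition_contrast(red, y, red, y, red, y,
                                   train_window = c(0, 0.8),
                                   test_window = c(0, 0.8), step = 0.2)
  expect_true(all(same$contrast == 0))
  # antisymmetry under swapping the splits
  hi <- subset_trials_red(red, 1:8); lo <- subset_trials_red(red, 9:16)
  c1 <- split_condition_contrast(red, y, hi, y[1:8], lo, y[9:16],
                                 train_window = c(0, 0.8),
                                 test_window = c(0, 0.8), step = 0.2)
  c2 <- split_condition_contrast(red, y, lo, y[9:16], hi, y[1:8],
                                 train_window = c(0, 0.8),
                                 test_window = c(0, 0.8), step = 0.2)
  expect_equal(c1$contrast, -c2$contrast, tolerance = 1e-12)
})

test_that("ripple-locked decoding beats its non-ripple surrogate at lag 0", {
  cs <- cached_study()
  st <- cs$study
  ret_z <- zscore_across_trials(
    baseline_whole_trial(common_average_reference(st$retrieval)))
  tmr_z <- zscore_across_trials(
    baseline_whole_trial(common_average_reference(st$tmr)))
  model <- suppressWarnings(pca_fit(list(ret_z, tmr_z), 30))
  tr_red <- ripplecue:::smooth_reduced(pca_apply(model, ret_z), 0.15)
  te_red <- ripplecue:::smooth_reduced(pca_apply(model, tmr_z), 0.15)
  rem <- which(st$retrieval$labels$remembered)
  tr_red <- subset_trials_red(tr_red, rem)
  y_tr <- st$retrieval$labels$class[rem]
  gt <- st$ground_truth$events
  rip <- gt[gt$set == "tmr" & gt$type == "ripple" & gt$channel == "M07", ]
  rl <- ripple_locked_classify(tr_red, y_tr, te_red, rip,
                               train_window = c(0.1, 0.6), step = 0.05)
  expect_identical(rl$n_events, nrow(rip))
  su <- surrogate_ripple_baseline(tr_red, y_tr, te_red, rip, n = 8, seed = 2,
                                  train_window = c(0.1, 0.6), step = 0.05)
  lag0 <- which.min(abs(rl$test_times))
  expect_gt(mean(rl$auc[, lag0]), mean(su$auc[, lag0]))
  # surrogate determinism under seed
  su2 <- surrogate_ripple_baseline(tr_red, y_tr, te_red, rip, n = 8, seed = 2,
                                   train_window = c(0.1, 0.6), step = 0.05)
  expect_identical(su$auc, su2$auc)
  # no qualifying ripples -> informative error
  expect_error(ripple_locked_classify(tr_red, y_tr, te_red,
                                      rip[rip$peak_s > 2.5, ]),
               "qualifying")
})
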