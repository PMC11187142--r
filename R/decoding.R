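# Multivariate decoding: PCA reduction, two-class shrinkage LDA, ROC-AUC,
# within-task cross-validated time courses, retrieval -> TMR temporal
# generalization, condition-split contrasts and ripple-locked classification
# with a non-ripple surrogate baseline.

#' Fit a spatial PCA on pooled epoch sets
#'
#' Channels are the variables and all (trial, time) pairs of all supplied
#' epoch sets are the observations, so train and test sets projected with the
#' same model share one component space (required for cross-task
#' generalization).
#'
#' @param eps list of [epochs()] objects (or a single one).
#' @param n number of components to retain (default 30; clamped to the
#'   channel count with a warning).
#' @return object of class `"pca_model"`: `rotation` (channels x n), `center`,
#'   `explained_variance` (share per retained component), `space_id`.
#' @export
pca_fit <- function(eps, n = 30) {
  if (inherits(eps, "epochs")) eps <- list(eps)
  n_ch <- dim(eps[[1L]]$data)[2L]
  X <- do.call(rbind, lapply(eps, function(ep) {
    d <- dim(ep$data)
    matrix(aperm(ep$data, c(1L, 3L, 2L)), d[1L] * d[3L], d[2L])
  }))
  if (n > n_ch) {
    warning("n reduced to the channel count (", n_ch, ")", call. = FALSE)
    n <- n_ch
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  rank_eff <- sum(pc$sdev^2 > 1e-12 * pc$sdev[1L]^2)
  if (rank_eff < n)
    warning("data rank (", rank_eff, ") below requested components",
            call. = FALSE)
  structure(list(rotation = pc$rotation[, seq_len(n), drop = FALSE],
                 center = pc$center,
                 explained_variance = ev[seq_len(n)],
                 space_id = c(n_ch, n, round(sum(pc$rotation[, seq_len(n)]^2), 6),
                              round(sum(pc$center), 6))),
            class = "pca_model")
}

#' Project an epoch set into a fitted PCA space
#'
#' @param model a [pca_fit()] result.
#' @param ep an [epochs()] object with the same channels.
#' @return object of class `"reduced_epochs"`: `scores` (trials x components
#'   x time), `times`, `fs`, `labels`, `explained_variance`, `space_id`.
#' @export
pca_apply <- function(model, ep) {
  stopifnot(inherits(model, "pca_model"), inherits(ep, "epochs"))
  d <- dim(ep$data)
  if (d[2L] != nrow(model$rotation))
    stop("channel count does not match the PCA model", call. = FALSE)
  X <- matrix(aperm(ep$data, c(1L, 3L, 2L)), d[1L] * d[3L], d[2L])
  S <- sweep(X, 2L, model$center) %*% model$rotation
  scores <- aperm(array(S, c(d[1L], d[3L], ncol(S))), c(1L, 3L, 2L))
  structure(list(scores = scores, times = ep$times, fs = ep$fs,
                 labels = ep$labels,
                 explained_variance = model$explained_variance,
                 space_id = model$space_id),
            class = "reduced_epochs")
}

#' One-step PCA reduction of an epoch set
#'
#' Fits on `ep` alone and projects it; for shared spaces across sets fit with
#' [pca_fit()] on the pooled list and apply with [pca_apply()].
#'
#' @inheritParams pca_fit
#' @param ep an [epochs()] object.
#' @return a `"reduced_epochs"` object.
#' @export
pca_reduce <- function(ep, n = 30) pca_apply(pca_fit(ep, n), ep)

#' @export
print.reduced_epochs <- function(x, ...) {
  d <- dim(x$scores)
  cat(sprintf("<reduced_epochs> %d trial(s) x %d component(s) x %d samples; ",
              d[1L], d[2L], d[3L]))
  cat(sprintf("retained variance %.1f%%\n", 100 * sum(x$explained_variance)))
  invisible(x)
}

# Ledoit-Wolf-style shrinkage intensity toward the scaled identity, computed
# from class-centered observations Z (rows)
.lw_gamma <- function(Z) {
  n <- nrow(Z); p <- ncol(Z)
  if (n < 2L) return(1)
  S <- crossprod(Z) / n
  m <- sum(diag(S)) / p
  d2 <- (sum(S^2) - p * m^2) / p
  if (d2 <= 1e-30) return(0)
  row_norm2 <- rowSums(Z^2)
  b2bar <- (sum(row_norm2^2) - n * sum(S^2)) / (n^2 * p)
  max(0, min(1, min(b2bar, d2) / d2))
}

#' Train a two-class linear discriminant with shrinkage regularization
#'
#' Pooled within-class covariance shrunk toward its scaled identity,
#' `(1 - gamma) S + gamma * mean(diag(S)) I`, with `gamma` chosen
#' automatically (Ledoit-Wolf) or fixed. Decision scores are
#' `X w + b`, positive toward the alphabetically second class.
#'
#' @param X trials x features matrix.
#' @param y class labels (exactly two distinct values, >= 2 trials each).
#' @param gamma `"auto"` or a fixed shrinkage in `[0, 1]`.
#' @return object of class `"lda_model"` with `w`, `b`, `classes`, `gamma`.
#' @export
train_lda <- function(X, y, gamma = "auto") {
  X <- as.matrix(X)
  classes <- sort(unique(as.character(y)))
  if (length(classes) != 2L)
    stop("need exactly two classes, got ", length(classes), call. = FALSE)
  i1 <- y == classes[2L]; i0 <- y == classes[1L]
  if (sum(i1) < 2L || sum(i0) < 2L)
    stop("need >= 2 trials per class", call. = FALSE)
  mu1 <- colMeans(X[i1, , drop = FALSE])
  mu0 <- colMeans(X[i0, , drop = FALSE])
  Z <- rbind(sweep(X[i1, , drop = FALSE], 2L, mu1),
             sweep(X[i0, , drop = FALSE], 2L, mu0))
  n <- nrow(Z); p <- ncol(Z)
  S <- crossprod(Z) / max(n - 2L, 1L)
  g <- if (identical(gamma, "auto")) .lw_gamma(Z) else gamma
  m <- sum(diag(S)) / p
  Sreg <- (1 - g) * S + g * m * diag(p)
  w <- solve(Sreg, mu1 - mu0)
  structure(list(w = as.numeric(w),
                 b = -sum(w * (mu1 + mu0) / 2),
                 classes = classes, gamma = g),
            class = "lda_model")
}

#' Decision scores of a trained discriminant
#' @param model an [train_lda()] model.
#' @param X trials x features matrix.
#' @return numeric score per trial (positive favors `model$classes[2]`).
#' @export
lda_scores <- function(model, X) as.numeric(as.matrix(X) %*% model$w + model$b)

#' Area under the ROC curve
#'
#' Probability that a randomly chosen trial of the positive class outscores a
#' randomly chosen trial of the other class, with ties counting 0.5
#' (equivalently the normalized Mann-Whitney statistic, which equals the
#' concordant-pair count exactly).
#'
#' @param scores numeric decision scores.
#' @param y labels; `positive` names the class treated as positive (default:
#'   alphabetically second).
#' @param positive positive class label.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, y, positive = NULL) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2L) stop("need exactly two classes", call. = FALSE)
  if (is.null(positive)) positive <- classes[2L]
  pos <- y == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("one class absent", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over folds
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# nearest sample indices of a stepped time grid
.time_grid <- function(times, step, window = NULL) {
  if (is.null(window)) window <- range(times)
  grid <- seq(max(window[1L], min(times)), min(window[2L], max(times)),
              by = step)
  idx <- vapply(grid, function(g) which.min(abs(times - g)), integer(1L))
  list(idx = unique(idx), times = times[unique(idx)])
}

#' Cross-validated decoding time course
#'
#' Stratified k-fold cross-validation, repeated `reps` times with fresh fold
#' assignments, with a separate discriminant per time point. Fold assignment
#' is seeded and bit-reproducible. AUC is averaged over folds and
#' repetitions; per-fold values are returned for variance estimates.
#'
#' @param red a `"reduced_epochs"` object (or any trials x features x time
#'   source wrapped in one).
#' @param y two-class labels, one per trial.
#' @param k folds (reduced with a warning when a class has fewer trials).
#' @param reps repetitions.
#' @param seed integer seed for fold assignment.
#' @param step time step (s) between classified time points.
#' @param window optional time window (s) to classify.
#' @param gamma LDA shrinkage (see [train_lda()]).
#' @return object of class `"decoding_result"` with `auc` (1 x times),
#'   `test_times`, `per_fold` (reps x k x times), `n_folds`, `n_reps`,
#'   `chance = 0.5`.
#' @export
crossval_timecourse <- function(red, y, k = 5, reps = 5, seed = 1L,
                                step = 0.020, window = NULL, gamma = "auto") {
  stopifnot(inherits(red, "reduced_epochs"))
  y <- as.character(y)
  min_cl <- min(table(y))
  if (min_cl < k) {
    warning("reducing folds to the smallest class size (", min_cl, ")",
            call. = FALSE)
    k <- max(2L, min_cl)
  }
  tg <- .time_grid(red$times, step, window)
  set.seed(seed)
  per_fold <- array(NA_real_, c(reps, k, length(tg$idx)))
  for (r in seq_len(reps)) {
    fold <- .stratified_folds(y, k)
    for (ti in seq_along(tg$idx)) {
      X <- red$scores[, , tg$idx[ti], drop = FALSE]
      dim(X) <- dim(red$scores)[1:2]
      for (f in seq_len(k)) {
        tr <- fold != f
        model <- train_lda(X[tr, , drop = FALSE], y[tr], gamma)
        per_fold[r, f, ti] <- auc(lda_scores(model, X[!tr, , drop = FALSE]),
                                  y[!tr], positive = model$classes[2L])
      }
    }
  }
  structure(list(auc = matrix(apply(per_fold, 3L, mean), nrow = 1L),
                 train_times = NULL, test_times = tg$times,
                 per_fold = per_fold, n_folds = k, n_reps = reps,
                 chance = 0.5),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s; mean AUC = %.3f (chance %.2f)\n",
              if (is.null(x$train_times)) sprintf("%d test time(s)",
                                                  length(x$test_times))
              else sprintf("%d train x %d test times", length(x$train_times),
                           length(x$test_times)),
              mean(x$auc, na.rm = TRUE), x$chance))
  invisible(x)
}

# temporal generalization core: one discriminant per train time, applied at
# every test time; returns the train x test AUC matrix
.tg_auc <- function(train_scores, train_y, test_scores, test_y,
                    train_idx, test_idx, gamma) {
  d_te <- dim(test_scores)
  pos <- sort(unique(as.character(test_y)))[2L]
  out <- matrix(NA_real_, length(train_idx), length(test_idx))
  # unfold test data once: (trials*time) x comp
  Xte <- matrix(aperm(test_scores[, , test_idx, drop = FALSE], c(1L, 3L, 2L)),
                d_te[1L] * length(test_idx), d_te[2L])
  for (i in seq_along(train_idx)) {
    X <- train_scores[, , train_idx[i], drop = FALSE]
    dim(X) <- dim(train_scores)[1:2]
    model <- train_lda(X, train_y, gamma)
    sc <- matrix(Xte %*% model$w + model$b, d_te[1L], length(test_idx))
    out[i, ] <- apply(sc, 2L, auc, y = test_y, positive = pos)
  }
  out
}

#' Temporal generalization: train per retrieval time, test per TMR time
#'
#' Requires both reduced sets to live in the same component space (fit the
#' PCA on the pooled data with [pca_fit()]). No cross-validation: the sets
#' are independent.
#'
#' @param train_red,test_red `"reduced_epochs"` sharing one PCA space.
#' @param train_y,test_y two-class labels.
#' @param train_window,test_window classified windows (s), defaults
#'   `[-0.5, 1]` (train) and `[-0.5, 1.5]` (test).
#' @param step time step (s).
#' @param gamma LDA shrinkage.
#' @return `"decoding_result"` with `auc` = train x test AUC matrix.
#' @export
temporal_generalization <- function(train_red, train_y, test_red, test_y,
                                    train_window = c(-0.5, 1),
                                    test_window = c(-0.5, 1.5),
                                    step = 0.020, gamma = "auto") {
  stopifnot(inherits(train_red, "reduced_epochs"),
            inherits(test_red, "reduced_epochs"))
  if (!isTRUE(all.equal(train_red$space_id, test_red$space_id)))
    stop("train and test sets are not in the same PCA component space",
         call. = FALSE)
  tg_tr <- .time_grid(train_red$times, step, train_window)
  tg_te <- .time_grid(test_red$times, step, test_window)
  amat <- .tg_auc(train_red$scores, as.character(train_y),
                  test_red$scores, as.character(test_y),
                  tg_tr$idx, tg_te$idx, gamma)
  structure(list(auc = amat, train_times = tg_tr$times,
                 test_times = tg_te$times, per_fold = NULL,
                 n_folds = NA_integer_, n_reps = 1L, chance = 0.5),
            class = "decoding_result")
}

#' Contrast of decoding performance between two trial splits
#'
#' Element-wise difference of the temporal-generalization AUC matrices for
#' the high and the low split (e.g. high vs low SO-spindle power trials).
#' Swapping the splits flips the sign of the contrast.
#'
#' @param train_red,train_y training set as in [temporal_generalization()].
#' @param test_high,test_low `"reduced_epochs"` for the two splits (same
#'   space as `train_red`), with labels `y_high`, `y_low`.
#' @param y_high,y_low labels of the split sets.
#' @param ... passed to [temporal_generalization()].
#' @return list with `contrast` (AUC_high - AUC_low) and the two
#'   `"decoding_result"`s `high` and `low`.
#' @export
split_condition_contrast <- function(train_red, train_y, test_high, y_high,
                                     test_low, y_low, ...) {
  if (!n_trials_red(test_high) || !n_trials_red(test_low))
    stop("empty split", call. = FALSE)
  hi <- temporal_generalization(train_red, train_y, test_high, y_high, ...)
  lo <- temporal_generalization(train_red, train_y, test_low, y_low, ...)
  list(contrast = hi$auc - lo$auc, high = hi, low = lo)
}

n_trials_red <- function(red) dim(red$scores)[1L]

#' Subset trials of a reduced epoch set
#' @param red a `"reduced_epochs"` object.
#' @param idx trial index.
#' @return the subsetted object.
#' @export
subset_trials_red <- function(red, idx) {
  red$scores <- red$scores[idx, , , drop = FALSE]
  red$labels <- red$labels[idx, , drop = FALSE]
  rownames(red$labels) <- NULL
  red
}

# qualifying ripples: peak inside `qualify_window` and, when a spindle table
# and reference contact are given, inside a detected spindle's extent on that
# contact in the same trial
.qualifying_ripples <- function(ripples, qualify_window, spindles = NULL,
                                ref_channel = NULL) {
  ok <- ripples$peak_s >= qualify_window[1L] &
    ripples$peak_s <= qualify_window[2L] & !is.na(ripples$trial)
  if (!is.null(spindles) && !is.null(ref_channel)) {
    sp <- spindles[spindles$channel == ref_channel, , drop = FALSE]
    in_spindle <- vapply(seq_len(nrow(ripples)), function(i) {
      s <- sp[!is.na(sp$trial) & sp$trial == ripples$trial[i], , drop = FALSE]
      any(s$onset_s <= ripples$peak_s[i] & ripples$peak_s[i] <= s$offset_s)
    }, logical(1L))
    ok <- ok & in_spindle
  }
  which(ok)
}

# extract component-space segments centered on given (trial, time) pairs
.event_segments <- function(red, trials, centers, window) {
  lag_idx <- seq(round(window[1L] * red$fs), round(window[2L] * red$fs))
  lags <- lag_idx / red$fs
  n_t <- dim(red$scores)[3L]
  segs <- array(NA_real_, c(length(trials), dim(red$scores)[2L], length(lags)))
  keep <- logical(length(trials))
  for (i in seq_along(trials)) {
    c_idx <- which.min(abs(red$times - centers[i]))
    sel <- c_idx + lag_idx
    if (sel[1L] < 1L || sel[length(sel)] > n_t) next
    segs[i, , ] <- red$scores[trials[i], , sel]
    keep[i] <- TRUE
  }
  list(segs = segs[keep, , , drop = FALSE], keep = keep, lags = lags)
}

#' Ripple-locked classification
#'
#' Applies discriminants trained on retrieval time points to TMR segments
#' re-centered on spindle-locked MTL ripple peaks (ripples inside
#' `qualify_window` after cue onset and, when `spindles`/`ref_channel` are
#' given, inside a detected spindle's extent on the reference cortical
#' contact). Each segment inherits the class label of its trial; trials whose
#' label is not one of the training classes are excluded.
#'
#' @param train_red,train_y training set (retrieval) in the shared PCA space.
#' @param tmr_red TMR set in the same space.
#' @param ripples,spindles event tables from [detect_ripples()] /
#'   [detect_spindles()] run on the TMR epochs (epoch-time clock, `trial`
#'   column set).
#' @param ref_channel spindle-reference cortical contact label
#'   (see [select_spindle_contact()]); `NULL` skips the spindle gate.
#' @param window ripple-centered segment window (s).
#' @param qualify_window post-cue window of preferred spindle-ripple
#'   interactions (s).
#' @param train_window,step,gamma as in [temporal_generalization()].
#' @return `"decoding_result"` with `auc` = train-time x ripple-lag matrix and
#'   `n_events` the qualifying segment count.
#' @export
ripple_locked_classify <- function(train_red, train_y, tmr_red, ripples,
                                   spindles = NULL, ref_channel = NULL,
                                   window = c(-0.25, 0.25),
                                   qualify_window = c(0.7, 1.4),
                                   train_window = c(-0.5, 1),
                                   step = 0.020, gamma = "auto") {
  stopifnot(inherits(train_red, "reduced_epochs"),
            inherits(tmr_red, "reduced_epochs"))
  if (!isTRUE(all.equal(train_red$space_id, tmr_red$space_id)))
    stop("train and TMR sets are not in the same PCA component space",
         call. = FALSE)
  q <- .qualifying_ripples(ripples, qualify_window, spindles, ref_channel)
  classes <- sort(unique(as.character(train_y)))
  cls <- as.character(tmr_red$labels$class[ripples$trial[q]])
  q <- q[cls %in% classes]
  if (!length(q))
    stop("zero qualifying ripples (checked ", nrow(ripples), " events)",
         call. = FALSE)
  ex <- .event_segments(tmr_red, ripples$trial[q], ripples$peak_s[q], window)
  y_ev <- as.character(tmr_red$labels$class[ripples$trial[q]])[ex$keep]
  if (length(unique(y_ev)) < 2L)
    stop("qualifying ripples cover only one class", call. = FALSE)
  tg_tr <- .time_grid(train_red$times, step, train_window)
  lag_step <- max(1L, round(step * tmr_red$fs))
  lag_sel <- seq(1L, length(ex$lags), by = lag_step)
  amat <- .tg_auc(train_red$scores, as.character(train_y), ex$segs, y_ev,
                  tg_tr$idx, lag_sel, gamma)
  structure(list(auc = amat, train_times = tg_tr$times,
                 test_times = ex$lags[lag_sel], per_fold = NULL,
                 n_folds = NA_integer_, n_reps = 1L, chance = 0.5,
                 n_events = dim(ex$segs)[1L]),
            class = "decoding_result")
}

#' Surrogate baseline for ripple-locked classification
#'
#' Repeats the ripple-locked analysis `n` times with segments centered on
#' random time points inside `qualify_window` where no ripple occurred in
#' that trial (at least `exclusion` s away from every detected ripple peak),
#' drawing as many surrogate centers per trial as that trial has qualifying
#' ripples, and averages the resulting AUC maps. Seeded and reproducible.
#'
#' @inheritParams ripple_locked_classify
#' @param n surrogate repetitions (default 100).
#' @param seed integer seed.
#' @param exclusion minimum distance (s) from any ripple peak.
#' @return `"decoding_result"` with the averaged surrogate AUC map.
#' @export
surrogate_ripple_baseline <- function(train_red, train_y, tmr_red, ripples,
                                      spindles = NULL, ref_channel = NULL,
                                      n = 100, seed = 1L,
                                      window = c(-0.25, 0.25),
                                      qualify_window = c(0.7, 1.4),
                                      train_window = c(-0.5, 1),
                                      step = 0.020, gamma = "auto",
                                      exclusion = 0.100) {
  if (n < 1) stop("need n >= 1 repetitions", call. = FALSE)
  q <- .qualifying_ripples(ripples, qualify_window, spindles, ref_channel)
  classes <- sort(unique(as.character(train_y)))
  cls <- as.character(tmr_red$labels$class[ripples$trial[q]])
  q <- q[cls %in% classes]
  if (!length(q)) stop("zero qualifying ripples", call. = FALSE)
  trials <- ripples$trial[q]
  set.seed(seed)
  acc <- NULL
  tg_tr <- .time_grid(train_red$times, step, train_window)
  for (r in seq_len(n)) {
    centers <- vapply(trials, function(tr) {
      peaks <- ripples$peak_s[!is.na(ripples$trial) & ripples$trial == tr]
      for (try in seq_len(200L)) {
        t0 <- stats::runif(1L, qualify_window[1L], qualify_window[2L])
        if (!length(peaks) || min(abs(t0 - peaks)) >= exclusion) return(t0)
      }
      stop("window saturated by ripples; no surrogate center found",
           call. = FALSE)
    }, numeric(1L))
    ex <- .event_segments(tmr_red, trials, centers, window)
    y_ev <- as.character(tmr_red$labels$class[trials])[ex$keep]
    lag_step <- max(1L, round(step * tmr_red$fs))
    lag_sel <- seq(1L, length(ex$lags), by = lag_step)
    amat <- .tg_auc(train_red$scores, as.character(train_y), ex$segs, y_ev,
                    tg_tr$idx, lag_sel, gamma)
    acc <- if (is.null(acc)) amat else acc + amat
    lags_out <- ex$lags[lag_sel]
  }
  structure(list(auc = acc / n, train_times = tg_tr$times,
                 test_times = lags_out, per_fold = NULL,
                 n_folds = NA_integer_, n_reps = n, chance = 0.5,
                 n_events = length(trials)),
            class = "decoding_result")
}
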