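# Nonparametric inference: cluster-based permutation tests over time,
# time x time or time x frequency maps, the circular V test, and rank
# correlation.

# finite stand-in for an infinite t (zero within-unit variance, nonzero
# effect); far above any attainable finite t, far below overflow
.t_cap <- 100

# connected components: 1D runs, or 4-connectivity on a matrix via iterative
# minimum-label propagation (vectorized; iterations bounded by the largest
# cluster's diameter)
.label_components <- function(mask) {
  d <- dim(mask)
  if (is.null(d) || length(d) == 1L) {
    mask <- as.logical(mask)
    lab <- integer(length(mask))
    r <- rle(mask)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    k <- 0L
    for (i in seq_along(r$values)) if (r$values[i]) {
      k <- k + 1L
      lab[starts[i]:ends[i]] <- k
    }
    return(lab)
  }
  idx <- matrix(as.numeric(seq_along(mask)), d[1L], d[2L])
  idx[!mask] <- NA_real_
  if (!any(mask)) return(matrix(0L, d[1L], d[2L]))
  repeat {
    up <- rbind(NA_real_, idx[-d[1L], , drop = FALSE])
    dn <- rbind(idx[-1L, , drop = FALSE], NA_real_)
    lf <- cbind(NA_real_, idx[, -d[2L], drop = FALSE])
    rt <- cbind(idx[, -1L, drop = FALSE], NA_real_)
    new <- pmin(idx, up, dn, lf, rt, na.rm = TRUE)
    new[!mask] <- NA_real_
    if (identical(new, idx)) break
    idx <- new
  }
  lab <- matrix(0L, d[1L], d[2L])
  ok <- !is.na(idx)
  lab[ok] <- match(idx[ok], sort(unique(idx[ok])))
  lab
}

# max |cluster mass| over both signs for one t map (vector or matrix)
.max_cluster_mass <- function(tmap, tcrit) {
  best <- 0
  for (sgn in c(1, -1)) {
    m <- sgn * tmap > tcrit
    if (!any(m)) next
    lab <- .label_components(m)
    if (max(lab) == 0L) next
    mass <- vapply(seq_len(max(lab)), function(k) sum(tmap[lab == k]),
                   numeric(1L))
    best <- max(best, max(abs(mass)))
  }
  best
}

#' Cluster-based permutation test
#'
#' Sample-level t statistics are thresholded at `cluster_alpha` (two-sided);
#' contiguous supra-threshold samples (runs over a 1D axis, 4-connected
#' regions over a 2D map) form clusters per sign, scored by the sum of their
#' t values. The null distribution is the maximum absolute cluster mass under
#' `n_perm` random permutations, and each observed cluster gets the Monte
#' Carlo p value `(b + 1) / (n_perm + 1)`.
#'
#' Two designs are supported:
#' * `type = "paired"` (default): `data` holds one map per unit
#'   (participant / contact / fold) and is tested against `reference` -- a
#'   chance scalar (e.g. 0.5 for AUC) or a paired condition of the same
#'   shape. Permutations flip the sign of each unit's deviation
#'   (dependent-samples t test at the sample level).
#' * `type = "two.sample"`: `data` holds one map per observation and
#'   `groups` assigns each to one of two conditions; permutations shuffle the
#'   group labels (pooled-variance independent t at the sample level).
#'
#' Zero-variance samples are counted in the returned `n_degenerate`; their t
#' is 0 when the effect is also zero, and a large capped value (the t would
#' be infinite) when a real effect has no within-unit variance, e.g. AUC at
#' ceiling in every fold.
#'
#' @param data numeric array: units x time, units x d1 x d2.
#' @param reference chance scalar or paired-condition array (paired design).
#' @param n_perm number of permutations (default 1000; < 100 warns).
#' @param cluster_alpha sample-level threshold (two-sided).
#' @param seed integer seed; permutations are reproducible.
#' @param type `"paired"` or `"two.sample"`.
#' @param groups two-level factor for the two-sample design.
#' @return object of class `"cluster_result"`: `clusters` (list of `mask`,
#'   `mass`, `sign`, `p`), `t` (observed map), `tcrit`, `null_max`,
#'   `n_perm`, `alpha`, `n_degenerate`.
#' @export
cluster_permutation_test <- function(data, reference = 0, n_perm = 1000,
                                     cluster_alpha = 0.05, seed = 1L,
                                     type = c("paired", "two.sample"),
                                     groups = NULL) {
  type <- match.arg(type)
  if (n_perm < 100) warning("fewer than 100 permutations", call. = FALSE)
  dms <- dim(data)
  if (is.null(dms)) stop("`data` must be units x map", call. = FALSE)
  map_dim <- dms[-1L]
  n_u <- dms[1L]
  D <- matrix(data, n_u)                     # units x cells
  n_cells <- ncol(D)
  set.seed(seed)

  if (type == "paired") {
    if (n_u < 2L) stop("need >= 2 units", call. = FALSE)
    if (length(reference) == 1L) D <- D - reference
    else {
      if (!all(dim(reference) == dms))
        stop("paired reference must match `data`", call. = FALSE)
      D <- D - matrix(reference, n_u)
    }
    df <- n_u - 1L
    ssq_b <- colSums(D^2)
    t_of_means <- function(mn) {
      v <- (ssq_b - n_u * mn^2) / df
      tt <- mn / sqrt(pmax(v, 0) / n_u)
      # zero variance with a real effect (e.g. AUC at ceiling in every unit):
      # the t statistic is formally infinite; cap it so such cells join
      # clusters without dominating the arithmetic
      deg <- !is.finite(tt) | v < 1e-30
      tt[deg] <- sign(mn[deg]) * .t_cap * (abs(mn[deg]) > 1e-12)
      tt
    }
    t_obs <- t_of_means(colMeans(D))
    n_degenerate <- sum(apply(D, 2L, function(x) stats::var(x) < 1e-30))
    S <- matrix(sample(c(-1, 1), n_perm * n_u, replace = TRUE), n_perm, n_u)
    mean_p <- S %*% D / n_u                  # n_perm x cells
    tcrit <- stats::qt(1 - cluster_alpha / 2, df)
    null_max <- vapply(seq_len(n_perm), function(r) {
      tm <- t_of_means(mean_p[r, ])
      dim(tm) <- if (length(map_dim) > 1L) map_dim else NULL
      .max_cluster_mass(tm, tcrit)
    }, numeric(1L))
  } else {
    if (is.null(groups)) stop("two-sample design needs `groups`", call. = FALSE)
    g <- as.factor(groups)
    if (nlevels(g) != 2L) stop("`groups` must have two levels", call. = FALSE)
    n1 <- sum(g == levels(g)[1L]); n2 <- n_u - n1
    if (n1 < 2L || n2 < 2L) stop("need >= 2 observations per group", call. = FALSE)
    df <- n_u - 2L
    D2 <- D^2
    csum <- colSums(D); csq <- colSums(D2)
    t_of_ind <- function(ind) {             # ind: 0/1 membership of group 1
      s1 <- drop(ind %*% D); q1 <- drop(ind %*% D2)
      s2 <- csum - s1; q2 <- csq - q1
      vp <- (q1 - s1^2 / n1 + q2 - s2^2 / n2) / df
      dm <- s1 / n1 - s2 / n2
      tt <- dm / sqrt(pmax(vp, 0) * (1 / n1 + 1 / n2))
      deg <- !is.finite(tt) | vp < 1e-30
      tt[deg] <- sign(dm[deg]) * .t_cap * (abs(dm[deg]) > 1e-12)
      tt
    }
    ind_obs <- as.numeric(g == levels(g)[1L])
    t_obs <- t_of_ind(ind_obs)
    n_degenerate <- sum(apply(D, 2L, function(x) stats::var(x) < 1e-30))
    tcrit <- stats::qt(1 - cluster_alpha / 2, df)
    null_max <- vapply(seq_len(n_perm), function(r) {
      tm <- t_of_ind(as.numeric(seq_len(n_u) %in% sample.int(n_u, n1)))
      dim(tm) <- if (length(map_dim) > 1L) map_dim else NULL
      .max_cluster_mass(tm, tcrit)
    }, numeric(1L))
  }

  tmap <- t_obs
  dim(tmap) <- if (length(map_dim) > 1L) map_dim else NULL
  clusters <- list()
  for (sgn in c(1, -1)) {
    m <- sgn * tmap > tcrit
    if (!any(m)) next
    lab <- .label_components(m)
    for (k in seq_len(max(lab))) {
      mask <- lab == k
      mass <- sum(tmap[mask])
      p <- (sum(null_max >= abs(mass)) + 1) / (n_perm + 1)
      clusters[[length(clusters) + 1L]] <-
        list(mask = mask, mass = mass, sign = sgn, p = p)
    }
  }
  ord <- order(vapply(clusters, function(cl) cl$p, numeric(1L)))
  structure(list(clusters = clusters[ord], t = tmap, tcrit = tcrit,
                 null_max = null_max, n_perm = n_perm, alpha = cluster_alpha,
                 n_degenerate = n_degenerate),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %d permutation(s)\n",
              length(x$clusters), x$n_perm))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  %d: sign %+d, mass %.2f, %d cell(s), p = %.4g\n",
                i, cl$sign, cl$mass, sum(cl$mask), cl$p))
  }
  invisible(x)
}

#' Union mask of significant clusters
#'
#' @param res a [cluster_permutation_test()] result.
#' @param alpha cluster-level significance threshold.
#' @param sign optionally restrict to positive (`1`) or negative (`-1`)
#'   clusters.
#' @return logical mask with the map's dimensions (`NULL`-dim vector for 1D);
#'   all-`FALSE` when nothing is significant.
#' @export
cluster_mask <- function(res, alpha = 0.05, sign = NULL) {
  stopifnot(inherits(res, "cluster_result"))
  out <- res$t * 0 > 1                        # all-FALSE, right shape
  for (cl in res$clusters)
    if (cl$p <= alpha && (is.null(sign) || cl$sign == sign))
      out <- out | cl$mask
  out
}

#' V test for circular non-uniformity with a specified mean direction
#'
#' `V = n R cos(theta_bar - mu)`; the test statistic `u = V sqrt(2 / n)` is
#' compared against the upper tail of the standard normal distribution.
#'
#' @param angles angles (rad), n >= 2.
#' @param mu hypothesized mean direction (rad), e.g. `pi` for the spindle
#'   trough.
#' @return list with `V`, `u`, `p`, `mean_direction`, `R`, `n`.
#' @export
v_test <- function(angles, mu) {
  n <- length(angles)
  if (n < 2L) stop("need >= 2 angles", call. = FALSE)
  cm <- circular_mean(angles)
  V <- if (is.na(cm$direction)) 0 else n * cm$R * cos(cm$direction - mu)
  u <- V * sqrt(2 / n)
  list(V = V, u = u, p = stats::pnorm(u, lower.tail = FALSE),
       mean_direction = cm$direction, R = cm$R, n = n)
}

#' Rank (or product-moment) correlation
#'
#' Spearman rank correlation by default, with the Pearson alternative
#' available; wraps [stats::cor.test()].
#'
#' @param x,y numeric vectors, equal length >= 4.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `estimate` and `p`.
#' @export
rank_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  if (length(x) < 4L) stop("need n >= 4", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(estimate = unname(ct$estimate), p = ct$p.value)
}
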