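# Cluster-based permutation inference, circular V test, rank correlation.

test_that("no clusters emerge from null data against the reference", {
  set.seed(1)
  dat <- matrix(0, 10, 50)
  res <- cluster_permutation_test(dat, reference = 0, n_perm = 200)
  expect_identical(length(res$clusters), 0L)
  expect_identical(res$n_degenerate, 50L)
})

test_that("a strong contiguous effect is recovered with a minimal p value", {
  set.seed(2)
  n_u <- 15; n_t <- 100
  dat <- matrix(rnorm(n_u * n_t), n_u, n_t)
  true_win <- 40:60
  dat[, true_win] <- dat[, true_win] + 2         # d = 2
  res <- cluster_permutation_test(dat, reference = 0, n_perm = 500, seed = 3)
  expect_gte(length(res$clusters), 1L)
  top <- res$clusters[[1L]]
  expect_equal(top$p, 1 / 501, tolerance = 1e-12)
  expect_gte(sum(top$mask[true_win]), 0.8 * length(true_win))
  msk <- cluster_mask(res)
  expect_true(any(msk))
})

test_that("cluster statistics are invariant to unit order; p within MC error", {
  set.seed(4)
  dat <- matrix(rnorm(12 * 40), 12, 40)
  dat[, 10:20] <- dat[, 10:20] + 1
  r1 <- cluster_permutation_test(dat, n_perm = 500, seed = 7)
  r2 <- cluster_permutation_test(dat[sample(12), ], n_perm = 500, seed = 7)
  # the observed t map and cluster masses are exactly order-invariant
  expect_equal(r1$t, r2$t, tolerance = 1e-12)
  expect_equal(sort(vapply(r1$clusters, `[[`, 0, "mass")),
               sort(vapply(r2$clusters, `[[`, 0, "mass")), tolerance = 1e-12)
  # Monte Carlo p values agree within sampling error of the null draws
  expect_equal(sort(vapply(r1$clusters, `[[`, 0, "p")),
               sort(vapply(r2$clusters, `[[`, 0, "p")), tolerance = 0.1)
  r3 <- cluster_permutation_test(dat, n_perm = 500, seed = 7)
  expect_identical(r1$null_max, r3$null_max)
})

test_that("2D cluster detection respects 4-connectivity", {
  set.seed(5)
  dat <- array(rnorm(14 * 20 * 30, sd = 0.5), c(14, 20, 30))
  dat[, 5:8, 10:15] <- dat[, 5:8, 10:15] + 2
  dat[, 15:17, 25:28] <- dat[, 15:17, 25:28] - 2
  res <- cluster_permutation_test(dat, n_perm = 300, seed = 8)
  signs <- vapply(res$clusters, `[[`, 0, "sign")
  sig <- vapply(res$clusters, `[[`, 0, "p") <= 0.05
  expect_true(any(sig & signs > 0))
  expect_true(any(sig & signs < 0))
  pos_mask <- cluster_mask(res, sign = 1)
  expect_gte(sum(pos_mask[5:8, 10:15]), 0.8 * 4 * 6)
  expect_identical(sum(pos_mask[15:17, 25:28]), 0L)
})

test_that("two-sample cluster test separates group differences", {
  set.seed(6)
  dat <- matrix(rnorm(20 * 60), 20, 60)
  grp <- rep(c("x", "y"), each = 10)
  dat[grp == "x", 20:35] <- dat[grp == "x", 20:35] + 2
  res <- cluster_permutation_test(dat, n_perm = 300, seed = 9,
                                  type = "two.sample", groups = grp)
  expect_gte(length(res$clusters), 1L)
  expect_lt(res$clusters[[1L]]$p, 0.05)
  expect_gte(sum(res$clusters[[1L]]$mask[20:35]), 0.8 * 16)
  expect_error(cluster_permutation_test(dat, type = "two.sample"), "groups")
})

test_that("paired test on differences equals one-sample test on the contrast", {
  set.seed(7)
  a <- matrix(rnorm(10 * 30), 10, 30)
  b <- a + matrix(rnorm(10 * 30, 0.8), 10, 30)
  r_pair <- cluster_permutation_test(b, reference = a, n_perm = 200, seed = 11)
  r_diff <- cluster_permutation_test(b - a, reference = 0, n_perm = 200,
                                     seed = 11)
  expect_equal(r_pair$t, r_diff$t, tolerance = 1e-12)
  expect_identical(r_pair$null_max, r_diff$null_max)
})

test_that("V test matches its closed form", {
  vt <- v_test(rep(pi, 10), mu = pi)
  expect_equal(vt$V, 10, tolerance = 1e-12)
  expect_equal(vt$u, 10 * sqrt(2 / 10), tolerance = 1e-12)
  expect_equal(vt$p, pnorm(10 * sqrt(0.2), lower.tail = FALSE),
               tolerance = 1e-15)
  expect_lt(vt$p, 1e-5)
  # uniform grid -> V ~ 0, p ~ 0.5
  grid <- seq(-pi + pi / 8, pi, by = pi / 4)
  vt0 <- v_test(grid, mu = 1.3)
  expect_lt(abs(vt0$V), 1e-10)
  expect_equal(vt0$p, 0.5, tolerance = 1e-10)
  # anti-aligned angles -> V = -n, p ~ 1
  vt_neg <- v_test(rep(0, 8), mu = pi)
  expect_equal(vt_neg$V, -8, tolerance = 1e-12)
  expect_gt(vt_neg$p, 0.99)
  expect_error(v_test(1, mu = 0), ">= 2")
})

test_that("V-test p decreases with concentration at fixed n", {
  set.seed(8)
  ps <- vapply(c(0.5, 2, 8), function(k)
    v_test(rvonmises(30, pi, k), mu = pi)$p, numeric(1L))
  expect_true(all(diff(ps) < 0))
})

test_that("rank correlation matches hand-computed cases", {
  expect_equal(rank_correlation(1:8, 1:8)$estimate, 1)
  expect_equal(rank_correlation(1:8, 8:1)$estimate, -1)
  expect_equal(rank_correlation(1:5, c(1, 3, 2, 5, 4))$estimate, 0.8,
               tolerance = 1e-12)
  pear <- rank_correlation(c(1, 2, 3, 10), c(1, 2, 3, 40),
                           method = "pearson")
  expect_gt(pear$estimate, 0.9)
  expect_error(rank_correlation(rep(1, 5), 1:5), "constant")
  expect_error(rank_correlation(1:3, 1:3), "n >= 4")
})

test_that("coupling direction recovery meets the stated accuracy", {
  hits <- 0L
  for (s in 1:50) {
    set.seed(s)
    ang <- rvonmises(30, pi, 2)
    d <- circular_mean(ang)$direction
    err <- abs(wrap_angle(d - pi))
    if (err <= 20 * pi / 180) hits <- hits + 1L
  }
  expect_gte(hits, 0.8 * 50)
})
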