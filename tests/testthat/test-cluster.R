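test_that("pointwise t matches the textbook statistics", {
  set.seed(7)
  x <- matrix(rnorm(15 * 4, 0.4), 15, 4)
  res <- pointwise_t(x, mode = "one_sample")
  for (j in 1:4) {
    expect_equal(res$t[j], unname(t.test(x[, j])$statistic),
                 tolerance = 1e-12)
  }
  expect_equal(res$df, 14)
  y <- matrix(rnorm(15 * 4), 15, 4)
  resp <- pointwise_t(x, y, mode = "paired")
  for (j in 1:4) {
    expect_equal(resp$t[j], unname(t.test(x[, j], y[, j],
                                          paired = TRUE)$statistic),
                 tolerance = 1e-12)
  }
  g <- rep(c("a", "b"), c(8, 7))
  resi <- pointwise_t(x, groups = g, mode = "independent")
  for (j in 1:4) {
    expect_equal(resi$t[j],
                 unname(t.test(x[g == "a", j], x[g == "b", j],
                               var.equal = TRUE)$statistic),
                 tolerance = 1e-12)
  }
  expect_equal(resi$df, 13)
})

test_that("degenerate inputs give conservative zero t values", {
  x <- matrix(1, 10, 3)
  expect_warning(res <- pointwise_t(x, mode = "one_sample"), "zero variance")
  expect_equal(res$t, rep(0, 3))
  y <- matrix(rnorm(20), 10, 2)
  expect_equal(
    suppressWarnings(pointwise_t(rbind(y, y),
                                 groups = rep(c("a", "b"), each = 10),
                                 mode = "independent"))$t,
    rep(0, 2))
})

test_that("find_clusters enumerates maximal same-sign runs", {
  cl <- find_clusters(c(0, 3, 3, 0, -3, 0), threshold = 2)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$start, c(2L, 5L))
  expect_equal(cl$end, c(3L, 5L))
  expect_equal(cl$stat, c(3, -3))
  expect_equal(nrow(find_clusters(c(0.5, -1, 1.2), threshold = 2)), 0)
  # sum statistic alternative
  cl2 <- find_clusters(c(0, 3, 3, 0, -3, 0), threshold = 2, stat = "sum")
  expect_equal(cl2$stat, c(6, -3))
  # sign changes split clusters when same_sign is on
  cl3 <- find_clusters(c(3, -3, 3), threshold = 2)
  expect_equal(nrow(cl3), 3)
  cl4 <- find_clusters(c(3, -3, 3), threshold = 2, same_sign = FALSE)
  expect_equal(nrow(cl4), 1)
  # threshold from df + alpha
  cl5 <- find_clusters(c(0, 5, 0), df = 19, alpha = 0.05)
  expect_equal(cl5$start, 2L)
})

test_that("an injected offset yields one significant cluster spanning it", {
  set.seed(21)
  x <- matrix(rnorm(20 * 100, 0, 0.1), 20, 100)
  x[, 40:60] <- x[, 40:60] + 1
  res <- cluster_permutation_test(x, mode = "one_sample", n_perm = 500,
                                  seed = 9)
  sig <- res$clusters[res$clusters$significant, ]
  expect_equal(nrow(sig), 1)
  expect_lte(sig$start, 40)
  expect_gte(sig$end, 60)
  expect_gt(sig$stat, 0)
})

test_that("Monte-Carlo p values stay inside (0, 1] and are seeded", {
  set.seed(3)
  x <- matrix(rnorm(12 * 50), 12, 50)
  a <- cluster_permutation_test(x, mode = "one_sample", n_perm = 200,
                                seed = 5)
  b <- cluster_permutation_test(x, mode = "one_sample", n_perm = 200,
                                seed = 5)
  expect_identical(a$clusters, b$clusters)
  if (nrow(a$clusters)) {
    expect_true(all(a$clusters$p > 0 & a$clusters$p <= 1))
  }
  expect_true(all(a$null_max >= 0))
})

test_that("negating the data flips t values but preserves cluster inference", {
  set.seed(13)
  x <- matrix(rnorm(15 * 60, 0.2), 15, 60)
  a <- cluster_permutation_test(x, mode = "one_sample", n_perm = 300,
                                seed = 2)
  b <- cluster_permutation_test(-x, mode = "one_sample", n_perm = 300,
                                seed = 2)
  expect_equal(b$t, -a$t, tolerance = 1e-12)
  expect_equal(abs(b$clusters$stat), abs(a$clusters$stat),
               tolerance = 1e-12)
  expect_equal(b$clusters$p, a$clusters$p)
})

test_that("identical groups produce no clusters in independent mode", {
  set.seed(31)
  y <- matrix(rnorm(10 * 40, 1), 10, 40)
  x <- rbind(y, y)
  res <- suppressWarnings(
    cluster_permutation_test(x, groups = rep(c("a", "b"), each = 10),
                             mode = "independent", n_perm = 200, seed = 1))
  expect_equal(nrow(res$clusters), 0)
})

test_that("paired mode equals one-sample mode on the differences", {
  set.seed(17)
  x <- matrix(rnorm(10 * 30, 0.5), 10, 30)
  y <- matrix(rnorm(10 * 30), 10, 30)
  a <- cluster_permutation_test(x, y, mode = "paired", n_perm = 200,
                                seed = 4)
  b <- cluster_permutation_test(x - y, mode = "one_sample", n_perm = 200,
                                seed = 4)
  expect_equal(a$clusters, b$clusters)
})

test_that("multi-ROI joint null is at least as conservative as per-ROI nulls", {
  set.seed(23)
  xs <- list(a = matrix(rnorm(14 * 40, 0.35), 14, 40),
             b = matrix(rnorm(14 * 40), 14, 40))
  joint <- cluster_permutation_test_rois(xs, mode = "one_sample",
                                         n_perm = 300, seed = 6,
                                         joint_null = TRUE)
  sep <- cluster_permutation_test_rois(xs, mode = "one_sample",
                                       n_perm = 300, seed = 6,
                                       joint_null = FALSE)
  expect_named(joint, c("a", "b"))
  for (r in c("a", "b")) {
    if (nrow(joint[[r]]$clusters)) {
      expect_true(all(joint[[r]]$clusters$p >= sep[[r]]$clusters$p - 1e-12))
    }
  }
})

test_that("small permutation counts trigger a warning", {
  x <- matrix(rnorm(10 * 20), 10, 20)
  expect_warning(cluster_permutation_test(x, mode = "one_sample",
                                          n_perm = 50, seed = 1),
                 "n_perm")
})

test_that("one-sided cluster tests honor the tail and mirror under negation", {
  cl <- find_clusters(c(0, 3, 0, -3, 0), df = 19, alpha = 0.05,
                      tail = "pos")
  expect_equal(nrow(cl), 1)
  expect_equal(cl$stat, 3)
  cl2 <- find_clusters(c(0, 3, 0, -3, 0), df = 19, alpha = 0.05,
                       tail = "neg")
  expect_equal(cl2$stat, -3)
  # one-tailed threshold is lower than the two-tailed one
  expect_gt(nrow(find_clusters(rep(1.8, 5), df = 19, tail = "pos")), 0)
  expect_equal(nrow(find_clusters(rep(1.8, 5), df = 19)), 0)
  set.seed(9)
  x <- matrix(rnorm(16 * 40, 0.3), 16, 40)
  a <- cluster_permutation_test(x, mode = "one_sample", n_perm = 300,
                                seed = 3, tail = "pos")
  b <- cluster_permutation_test(-x, mode = "one_sample", n_perm = 300,
                                seed = 3, tail = "neg")
  expect_equal(a$clusters$p, b$clusters$p)
  expect_equal(a$clusters$stat, -b$clusters$stat)
  # a negative effect is invisible to the positive tail
  y <- matrix(rnorm(16 * 40, -1), 16, 40)
  res <- cluster_permutation_test(y, mode = "one_sample", n_perm = 300,
                                  seed = 3, tail = "pos")
  expect_equal(nrow(res$clusters), 0)
})
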