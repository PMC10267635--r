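random_spd_cov <- function(n_ch, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n_ch * n_ch), n_ch)
  C <- tcrossprod(A) / n_ch + diag(n_ch)
  structure(list(cov = C, cov_raw = C, lambda = 0, n_samples = n_ch,
                 inv = solve(C), condition_scope = "combined"),
            class = "covariance_model")
}

test_that("the combined covariance is symmetric, regularized and bilinear", {
  ep <- random_epochs(10, 10, n_ch = 6, n_t = 30, seed = 2)
  cv <- compute_covariance(ep, lambda = 0.05)
  expect_equal(cv$cov, t(cv$cov))
  expect_equal(cv$cov, cv$cov_raw + 0.05 * mean(diag(cv$cov_raw)) * diag(6))
  expect_equal(cv$inv %*% cv$cov, diag(6), tolerance = 1e-8)
  # lambda = 0 on full-rank data returns the raw covariance
  cv0 <- compute_covariance(ep, lambda = 0)
  expect_equal(cv0$cov, cv0$cov_raw)
  # doubling the data scale quadruples the covariance
  ep2 <- ep
  ep2$data <- ep$data * 2
  expect_equal(compute_covariance(ep2, 0)$cov_raw, 4 * cv0$cov_raw,
               tolerance = 1e-12)
  # rank-deficient data demand regularization
  ep3 <- random_epochs(2, 2, n_ch = 40, n_t = 10, seed = 3)
  expect_error(compute_covariance(ep3, lambda = 0), "lambda")
  ep4 <- ep
  ep4$labels <- rep("standard", 20)
  expect_error(compute_covariance(ep4), "both")
})

test_that("white-noise covariance approaches a scaled identity", {
  ep <- random_epochs(60, 60, n_ch = 5, n_t = 100, sd = 2, seed = 4)
  C <- compute_covariance(ep, lambda = 0)$cov_raw
  expect_equal(diag(C), rep(4, 5), tolerance = 0.15)
  offdiag <- C[upper.tri(C)]
  expect_lt(max(abs(offdiag)), 0.1 * mean(diag(C)))
})

test_that("LCMV filters satisfy unit gain across random geometries", {
  arr <- tiny_array()
  set.seed(12)
  for (k in 1:100) {
    pos <- runif(3, -0.04, 0.04)
    if (sqrt(sum(pos^2)) < 0.01) pos <- pos + 0.02
    L <- dipole_leadfield(pos, arr)
    cv <- random_spd_cov(32, seed = k)
    f <- lcmv_vertex_filter(L, cv)
    expect_equal(sum(f$weights * (L %*% f$orientation)), 1,
                 tolerance = 1e-10)
    expect_equal(sqrt(sum(f$orientation^2)), 1, tolerance = 1e-12)
  }
})

test_that("a noiseless dipole is recovered with near-perfect fidelity", {
  arr <- make_sensor_array(64)
  grid <- default_grid()
  v <- roi_centroid(grid, "rSTG")
  L <- dipole_leadfield(grid$positions[v, ], arr)
  moment <- unit(c(1, 0.4))
  tcourse <- sin(seq(0, 6 * pi, length.out = 300)) *
    exp(-((1:300) - 150)^2 / 5000) * 2e-8
  X <- (L %*% moment) %*% t(tcourse)
  C <- tcrossprod(X) / (ncol(X) - 1)
  C <- C + 1e-6 * mean(diag(C)) * diag(nrow(C))
  cov <- structure(list(cov = C, cov_raw = C, lambda = 1e-6,
                        n_samples = ncol(X), inv = solve(C),
                        condition_scope = "combined"),
                   class = "covariance_model")
  f <- lcmv_vertex_filter(L, cov)
  rec <- as.numeric(f$weights %*% X)
  expect_gt(abs(cor(rec, tcourse)), 0.99)
  # unit gain means the amplitude comes back on scale
  expect_equal(max(abs(rec)), max(abs(tcourse)), tolerance = 0.05)
})

test_that("the scalar output is invariant to the tangential basis choice", {
  arr <- tiny_array()
  L <- dipole_leadfield(c(0.03, 0.015, 0.02), arr)
  cv <- random_spd_cov(32, seed = 5)
  f1 <- lcmv_vertex_filter(L, cv)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  L2 <- L %*% R
  attr(L2, "basis") <- attr(L, "basis") %*% R
  f2 <- lcmv_vertex_filter(L2, cv)
  set.seed(6)
  probe <- matrix(rnorm(32 * 10), 32, 10)
  y1 <- as.numeric(f1$weights %*% probe)
  y2 <- as.numeric(f2$weights %*% probe)
  expect_equal(abs(y1), abs(y2), tolerance = 1e-8)
})

test_that("pseudo-power localizes a noiseless dipole to its vertex", {
  arr <- make_sensor_array(64)
  grid <- default_grid()
  v <- roi_centroid(grid, "rIFG")
  Lv <- dipole_leadfield(grid$positions[v, ], arr)
  X <- (Lv %*% c(1, 0)) %*% t(rnorm(500)) * 1e-8
  C <- tcrossprod(X) / 499 + 1e-8 * diag(64) * mean(colSums(X^2)) / 500
  cov <- structure(list(cov = C, cov_raw = C, lambda = 0, n_samples = 500,
                        inv = solve(C), condition_scope = "combined"),
                   class = "covariance_model")
  cand <- which(vnorm_test(grid$positions, grid$positions[v, ]) < 0.035)
  pow <- vapply(cand, function(i) {
    lcmv_vertex_filter(dipole_leadfield(grid$positions[i, ], arr),
                       cov)$power
  }, 1)
  best <- cand[which.max(pow)]
  expect_lte(vnorm_test(grid$positions[best, , drop = FALSE],
                        grid$positions[v, ]), grid$spacing + 1e-9)
})

test_that("ROI filters weight by centroid proximity and collapse as sigma -> 0", {
  arr <- tiny_array()
  grid <- default_grid()
  ep <- random_epochs(12, 12, n_ch = 32, n_t = 40, seed = 7)
  cv <- compute_covariance(ep)
  f <- roi_spatial_filter(grid, "rA1", arr, cv)
  expect_equal(sum(f$prox_weights), 1)
  expect_true(all(f$prox_weights >= 0))
  expect_equal(grid$roi_labels[f$centroid], "rA1")
  # the centroid voxel carries the largest weight
  expect_equal(which.max(f$prox_weights), which(f$voxels == f$centroid))
  f0 <- roi_spatial_filter(grid, "rA1", arr, cv, sigma_prox = 1e-9)
  cen <- lcmv_vertex_filter(dipole_leadfield(grid$positions[f$centroid, ],
                                             arr), cv)
  ref <- tangential_basis_test(grid$positions[f$centroid, ])[, 1]
  s <- if (sum(cen$ori3d * ref) < 0) -1 else 1
  expect_equal(f0$weights, s * cen$weights, tolerance = 1e-6)
  expect_error(roi_spatial_filter(grid, "nope", arr, cv), "empty")
})

test_that("ROI projection is linear and channel-checked", {
  arr <- tiny_array()
  grid <- default_grid()
  ep <- random_epochs(10, 10, n_ch = 32, n_t = 30, seed = 8)
  cv <- compute_covariance(ep)
  filters <- lapply(c("lA1", "rA1"), function(r) {
    roi_spatial_filter(grid, r, arr, cv)
  })
  ev <- average_erfs(ep)
  src <- project_rois(filters, ev)
  expect_named(src$rois, c("lA1", "rA1"))
  expect_equal(src$rois$rA1$mmf, src$rois$rA1$deviant - src$rois$rA1$standard)
  # zero field projects to zero
  ev0 <- ev
  ev0$standard[] <- 0
  ev0$deviant[] <- 0
  ev0$mmf[] <- 0
  src0 <- project_rois(filters, ev0)
  expect_true(all(src0$rois$lA1$standard == 0))
  # linearity
  ev2 <- ev
  ev2$standard <- ev$standard * 2
  ev2$deviant <- ev$deviant * 2
  src2 <- project_rois(filters, ev2)
  expect_equal(src2$rois$rA1$standard, 2 * src$rois$rA1$standard)
  bad <- ev
  bad$standard <- bad$standard[1:5, ]
  bad$deviant <- bad$deviant[1:5, ]
  expect_error(project_rois(filters, bad), "match")
})
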