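#' Pointwise t statistics along a time axis
#'
#' One-sample t on `x` (rows = participants), paired t on `x - y`, or
#' pooled-variance independent-samples t on the rows of `x` split by
#' `groups`. Timepoints with zero variance yield `t = 0` with a warning
#' (conservative).
#'
#' @param x numeric matrix, observations x timepoints.
#' @param y optional matrix for `mode = "paired"` (same shape as `x`).
#' @param groups factor-like vector over rows of `x` for
#'   `mode = "independent"` (exactly two levels).
#' @param mode `"one_sample"`, `"paired"` or `"independent"`.
#' @param warn warn on zero-variance timepoints (default TRUE).
#' @return List with `t` (per timepoint) and `df`.
#' @export
pointwise_t <- function(x, y = NULL, groups = NULL,
                        mode = c("one_sample", "paired", "independent"),
                        warn = TRUE) {
  mode <- match.arg(mode)
  if (mode == "paired") {
    stopifnot(!is.null(y), all(dim(x) == dim(y)))
    x <- x - y
    mode <- "one_sample"
  }
  if (mode == "one_sample") {
    n <- nrow(x)
    if (n < 2L) stop("need at least 2 observations")
    m <- colMeans(x)
    v <- colSums(sweep(x, 2, m)^2) / (n - 1)
    bad <- v <= 0
    if (any(bad) && warn) warning("zero variance at some timepoints; t set to 0")
    tv <- ifelse(bad, 0, m / sqrt(v / n))
    return(list(t = tv, df = n - 1))
  }
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop("`groups` must have exactly two levels")
  n1 <- sum(g == levels(g)[1L])
  n2 <- sum(g == levels(g)[2L])
  if (n1 < 2L || n2 < 2L) stop("need at least 2 observations per group")
  x1 <- x[g == levels(g)[1L], , drop = FALSE]
  x2 <- x[g == levels(g)[2L], , drop = FALSE]
  m1 <- colMeans(x1)
  m2 <- colMeans(x2)
  sp2 <- (colSums(sweep(x1, 2, m1)^2) + colSums(sweep(x2, 2, m2)^2)) /
    (n1 + n2 - 2)
  bad <- sp2 <= 0
  if (any(bad) && warn) warning("zero variance at some timepoints; t set to 0")
  tv <- ifelse(bad, 0, (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2)))
  list(t = tv, df = n1 + n2 - 2)
}

#' Find temporal clusters of suprathreshold t values
#'
#' Maximal contiguous runs of samples with `|t| > threshold`, required by
#' default to share a sign. The cluster statistic is the mean of the
#' member t values (the sum is available as an alternative).
#'
#' @param tvals pointwise t values.
#' @param threshold critical t value; supply either this or `df` + `alpha`.
#' @param df degrees of freedom used to derive the threshold from `alpha`.
#' @param alpha alpha for the cluster-forming threshold (default 0.05;
#'   halved per side for the two-tailed test).
#' @param stat `"mean"` (default) or `"sum"` cluster statistic.
#' @param same_sign require constant sign within a cluster (default TRUE).
#' @param tail `"two"` (default) for clusters of either sign, `"pos"` /
#'   `"neg"` for one-sided cluster forming at the one-tailed threshold.
#' @return Data frame with `start`, `end` (sample indices, inclusive) and
#'   `stat`; zero rows when nothing exceeds the threshold.
#' @export
find_clusters <- function(tvals, threshold = NULL, df = NULL, alpha = 0.05,
                          stat = c("mean", "sum"), same_sign = TRUE,
                          tail = c("two", "pos", "neg")) {
  stat <- match.arg(stat)
  tail <- match.arg(tail)
  if (is.null(threshold)) {
    if (is.null(df)) stop("supply `threshold` or `df`")
    threshold <- stats::qt(1 - alpha / (if (tail == "two") 2 else 1), df)
  }
  code <- if (tail == "pos") {
    as.integer(tvals > threshold)
  } else if (tail == "neg") {
    -as.integer(tvals < -threshold)
  } else if (same_sign) {
    (tvals > threshold) - (tvals < -threshold)
  } else {
    as.integer(abs(tvals) > threshold)
  }
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  if (!any(keep)) {
    return(data.frame(start = integer(0), end = integer(0),
                      stat = numeric(0)))
  }
  starts <- starts[keep]
  ends <- ends[keep]
  cs <- mapply(function(s, e) {
    if (stat == "mean") mean(tvals[s:e]) else sum(tvals[s:e])
  }, starts, ends)
  data.frame(start = starts, end = ends, stat = cs)
}

max_cluster_stat <- function(tvals, threshold, stat, same_sign, tail = "two") {
  cl <- find_clusters(tvals, threshold, stat = stat, same_sign = same_sign,
                      tail = tail)
  if (nrow(cl) == 0L) 0 else if (tail == "pos") {
    max(cl$stat)
  } else if (tail == "neg") {
    max(-cl$stat)
  } else {
    max(abs(cl$stat))
  }
}

# t matrix for sign-flip permutations: S is n_perm x n of +/-1,
# X is n x T. Returns n_perm x T.
perm_t_onesample <- function(X, S) {
  n <- nrow(X)
  q <- colMeans(X^2)
  M <- (S %*% X) / n
  V <- sweep(-M^2, 2, q, "+") * (n / (n - 1))
  V[V < 1e-300] <- Inf # zero-variance permutations give t = 0
  M / sqrt(V / n)
}

# t matrix for group-label permutations: P is n_perm x n of 0/1 selecting
# group 1 (each row sums to n1). X is n x T.
perm_t_independent <- function(X, P, n1, n2) {
  S <- colSums(X)
  SS <- colSums(X^2)
  S1 <- P %*% X
  M1 <- S1 / n1
  M2 <- sweep(-S1, 2, S, "+") / n2
  # within-group sum of squares: SS_total - n1*M1^2 - n2*M2^2
  ss_w <- sweep(-(n1 * M1^2 + n2 * M2^2), 2, SS, "+")
  sp2 <- ss_w / (n1 + n2 - 2)
  sp2[sp2 < 1e-300] <- Inf
  (M1 - M2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Nonparametric cluster-based permutation test on time courses
#'
#' Forms clusters of temporally contiguous samples whose t values exceed
#' the two-tailed critical value at `alpha`, summarizes each cluster by
#' the mean of its t values, and assesses significance against the
#' permutation distribution of the maximum absolute cluster statistic
#' (family-wise error control). Resampling is by independent
#' per-participant sign flips of the (difference) data for the one-sample
#' and paired modes, and by group-label reassignment preserving group
#' sizes for the independent mode. Monte-Carlo p values use the +1
#' correction, so they are never zero.
#'
#' @param x observations x timepoints matrix (differences for
#'   `one_sample`; condition A for `paired`; all participants for
#'   `independent`).
#' @param y condition B matrix for `paired`.
#' @param groups two-level grouping over rows of `x` for `independent`.
#' @param mode test mode.
#' @param n_perm number of permutations (default 1000; fewer than 100
#'   triggers a warning).
#' @param alpha cluster-forming and cluster-level alpha (default 0.05).
#' @param seed permutation seed.
#' @param cluster_stat `"mean"` (default) or `"sum"`.
#' @param same_sign require constant sign within clusters (default TRUE).
#' @param times optional time axis used to report cluster start/end in
#'   seconds.
#' @param tail `"two"` (default), or `"pos"` / `"neg"` for a one-sided
#'   test at the one-tailed cluster-forming threshold, with the null
#'   taken from the matching tail of the permutation distribution.
#' @return A `cluster_test`: `clusters` data frame (`start`, `end`,
#'   sample indices; `start_time`, `end_time` when `times` given; `stat`,
#'   `p`, `significant`), `t` pointwise values, `threshold`, `df`,
#'   `null_max` distribution, plus the settings and seed.
#' @export
cluster_permutation_test <- function(x, y = NULL, groups = NULL,
                                     mode = c("one_sample", "paired",
                                              "independent"),
                                     n_perm = 1000L, alpha = 0.05,
                                     seed = 1L, cluster_stat = c("mean", "sum"),
                                     same_sign = TRUE, times = NULL,
                                     tail = c("two", "pos", "neg")) {
  mode <- match.arg(mode)
  cluster_stat <- match.arg(cluster_stat)
  tail <- match.arg(tail)
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse Monte-Carlo p")
  res <- cluster_test_engine(list(x), list(y), groups, mode, n_perm, alpha,
                             seed, cluster_stat, same_sign, tail)
  out <- res$tests[[1L]]
  out$null_max <- res$null_max
  out$times <- times
  if (!is.null(times) && nrow(out$clusters)) {
    out$clusters$start_time <- times[out$clusters$start]
    out$clusters$end_time <- times[out$clusters$end]
  }
  structure(out, class = "cluster_test")
}

#' Cluster permutation tests over several ROIs with a joint null
#'
#' Runs the same cluster test on each element of `x_list` (one matrix per
#' ROI) using shared permutations, with the null distribution taken as
#' the maximum absolute cluster statistic across all ROIs in each
#' permutation. This controls the family-wise error rate jointly over
#' ROIs and time. Set `joint_null = FALSE` for per-ROI nulls.
#'
#' @inheritParams cluster_permutation_test
#' @param x_list named list of observations x timepoints matrices.
#' @param y_list optional matching list for `paired` mode.
#' @param joint_null pool the max statistic across ROIs (default TRUE).
#' @return Named list of `cluster_test` objects.
#' @export
cluster_permutation_test_rois <- function(x_list, y_list = NULL,
                                          groups = NULL,
                                          mode = c("one_sample", "paired",
                                                   "independent"),
                                          n_perm = 1000L, alpha = 0.05,
                                          seed = 1L,
                                          cluster_stat = c("mean", "sum"),
                                          same_sign = TRUE, times = NULL,
                                          joint_null = TRUE,
                                          tail = c("two", "pos", "neg")) {
  mode <- match.arg(mode)
  cluster_stat <- match.arg(cluster_stat)
  tail <- match.arg(tail)
  if (!joint_null) {
    out <- lapply(seq_along(x_list), function(i) {
      cluster_permutation_test(x_list[[i]], y_list[[i]] %||% NULL,
                               groups = groups, mode = mode,
                               n_perm = n_perm, alpha = alpha, seed = seed,
                               cluster_stat = cluster_stat,
                               same_sign = same_sign, times = times,
                               tail = tail)
    })
    names(out) <- names(x_list)
    return(out)
  }
  res <- cluster_test_engine(x_list, y_list, groups, mode, n_perm, alpha,
                             seed, cluster_stat, same_sign, tail)
  out <- lapply(res$tests, function(tst) {
    tst$null_max <- res$null_max
    tst$times <- times
    if (!is.null(times) && nrow(tst$clusters)) {
      tst$clusters$start_time <- times[tst$clusters$start]
      tst$clusters$end_time <- times[tst$clusters$end]
    }
    structure(tst, class = "cluster_test")
  })
  names(out) <- names(x_list)
  out
}

cluster_test_engine <- function(x_list, y_list, groups, mode, n_perm,
                                alpha, seed, cluster_stat, same_sign,
                                tail = "two") {
  R <- length(x_list)
  if (mode == "paired") {
    for (i in seq_len(R)) {
      stopifnot(all(dim(x_list[[i]]) == dim(y_list[[i]])))
      x_list[[i]] <- x_list[[i]] - y_list[[i]]
    }
    eff_mode <- "one_sample"
  } else {
    eff_mode <- mode
  }
  n <- nrow(x_list[[1L]])
  Ts <- vapply(x_list, ncol, 1L)

  if (eff_mode == "one_sample") {
    df <- n - 1L
  } else {
    g <- as.factor(groups)
    lv <- levels(g)
    n1 <- sum(g == lv[1L])
    n2 <- sum(g == lv[2L])
    df <- n1 + n2 - 2L
  }
  threshold <- stats::qt(1 - alpha / (if (tail == "two") 2 else 1), df)

  obs <- lapply(x_list, function(X) {
    if (eff_mode == "one_sample") {
      pointwise_t(X, mode = "one_sample", warn = FALSE)
    } else {
      pointwise_t(X, groups = groups, mode = "independent", warn = FALSE)
    }
  })

  # shared resampling matrix
  perm_mats <- with_seed(seed, {
    if (eff_mode == "one_sample") {
      matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    } else {
      P <- matrix(0, n_perm, n)
      for (p in seq_len(n_perm)) P[p, sample.int(n, n1)] <- 1
      P
    }
  })

  Tm_list <- lapply(x_list, function(X) {
    if (eff_mode == "one_sample") {
      perm_t_onesample(X, perm_mats)
    } else {
      perm_t_independent(X, perm_mats, n1, n2)
    }
  })
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    mx <- 0
    for (i in seq_len(R)) {
      mx <- max(mx, max_cluster_stat(Tm_list[[i]][p, ], threshold,
                                     cluster_stat, same_sign, tail))
    }
    null_max[p] <- mx
  }

  tests <- lapply(seq_len(R), function(i) {
    cl <- find_clusters(obs[[i]]$t, threshold, stat = cluster_stat,
                        same_sign = same_sign, tail = tail)
    if (nrow(cl)) {
      cl$p <- vapply(cl$stat, function(s) {
        o <- switch(tail, pos = s, neg = -s, abs(s))
        (1 + sum(null_max >= o)) / (1 + n_perm)
      }, 1)
      cl$significant <- cl$p < alpha
    } else {
      cl$p <- numeric(0)
      cl$significant <- logical(0)
    }
    list(clusters = cl, t = obs[[i]]$t, df = df, threshold = threshold,
         alpha = alpha, n_perm = n_perm, seed = seed, mode = mode,
         cluster_stat = cluster_stat, tail = tail)
  })
  list(tests = tests, null_max = null_max)
}

#' @export
print.cluster_test <- function(x, digits = 4, ...) {
  cat("<cluster_test>", x$mode, "mode,", x$n_perm, "permutations,",
      "cluster statistic:", x$cluster_stat, "of t, threshold |t| >",
      round(x$threshold, 3), "(df", paste0(x$df, ")"), "\n")
  cl <- x$clusters
  if (!nrow(cl)) {
    cat("  no suprathreshold clusters\n")
  } else {
    if (!is.null(cl$start_time)) {
      cat(sprintf("  cluster %s: %.3f-%.3f s, stat %.3f, p = %.4f%s\n",
                  seq_len(nrow(cl)), cl$start_time, cl$end_time, cl$stat,
                  cl$p, ifelse(cl$significant, " *", "")), sep = "")
    } else {
      cat(sprintf("  cluster %s: samples %d-%d, stat %.3f, p = %.4f%s\n",
                  seq_len(nrow(cl)), cl$start, cl$end, cl$stat, cl$p,
                  ifelse(cl$significant, " *", "")), sep = "")
    }
  }
  invisible(x)
}
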