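#' Two-sided permutation test for an independent-samples comparison
#'
#' The test statistic is the difference of group means (a pooled-variance
#' t statistic is available behind `statistic = "t"`). Group labels are
#' reshuffled preserving group sizes; the two-sided Monte-Carlo p value
#' uses the +1 correction.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @param n_reshuffles label reshuffles (default 5000).
#' @param seed integer seed.
#' @param statistic `"mean_diff"` (default) or `"t"`.
#' @return List with `p`, `statistic`, `observed`, `n_reshuffles`, `seed`.
#' @export
permutation_ttest_ind <- function(x, y, n_reshuffles = 5000L, seed = 1L,
                                  statistic = c("mean_diff", "t")) {
  statistic <- match.arg(statistic)
  if (length(x) < 2L || length(y) < 2L) {
    stop("both groups need at least 2 observations")
  }
  z <- c(x, y)
  n1 <- length(x)
  n <- length(z)
  stat_fun <- if (statistic == "mean_diff") {
    function(a, b) mean(a) - mean(b)
  } else {
    function(a, b) {
      sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
        (length(a) + length(b) - 2)
      if (sp2 <= 0) return(0)
      (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    }
  }
  obs <- stat_fun(x, y)
  perm <- with_seed(seed, {
    vapply(seq_len(n_reshuffles), function(i) {
      idx <- sample.int(n, n1)
      stat_fun(z[idx], z[-idx])
    }, 1)
  })
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (1 + n_reshuffles)
  list(p = p, statistic = statistic, observed = obs,
       n_reshuffles = n_reshuffles, seed = seed)
}

#' Cohen's d for two independent groups
#'
#' `(mean(x) - mean(y)) / s_pooled` with the `(n - 1)`-weighted pooled
#' standard deviation.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @return Scalar d.
#' @export
cohens_d <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("both groups need at least 2 observations")
  }
  cohens_d_summary(length(x), mean(x), stats::sd(x),
                   length(y), mean(y), stats::sd(y))
}

#' Cohen's d from group summary statistics
#'
#' @param n1,m1,sd1 size, mean and SD of the first group.
#' @param n2,m2,sd2 size, mean and SD of the second group.
#' @return Scalar d = (m1 - m2) / pooled SD.
#' @export
#' @examples
#' cohens_d_summary(19, 0.71, 0.45, 18, 0.40, 0.34)  # ~0.77
cohens_d_summary <- function(n1, m1, sd1, n2, m2, sd2) {
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp <= 0) stop("zero pooled standard deviation")
  (m1 - m2) / sp
}

#' Bootstrap confidence interval for Cohen's d
#'
#' Seeded within-group resampling; bias-corrected and accelerated (BCa)
#' endpoints by default, with the acceleration estimated by a jackknife
#' over all observations. Falls back to percentile endpoints when the
#' BCa correction is degenerate (all bootstrap replicates on one side of
#' the estimate, or zero jackknife spread); the method actually used is
#' attached as attribute `"method"`.
#'
#' @param x,y numeric vectors.
#' @param n_boot bootstrap replicates (default 5000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @param method `"bca"` (default) or `"percentile"`.
#' @return Length-2 vector `c(lower, upper)` with attributes `method`,
#'   `d` and `boot` (the replicate vector).
#' @export
bootstrap_ci_d <- function(x, y, n_boot = 5000L, level = 0.95, seed = 1L,
                           method = c("bca", "percentile")) {
  method <- match.arg(method)
  d_obs <- cohens_d(x, y)
  n1 <- length(x)
  n2 <- length(y)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      xb <- x[sample.int(n1, n1, replace = TRUE)]
      yb <- y[sample.int(n2, n2, replace = TRUE)]
      sdx <- stats::sd(xb)
      sdy <- stats::sd(yb)
      sp <- sqrt(((n1 - 1) * sdx^2 + (n2 - 1) * sdy^2) / (n1 + n2 - 2))
      if (sp <= 0) NA_real_ else (mean(xb) - mean(yb)) / sp
    }, 1)
  })
  boots <- boots[is.finite(boots)]
  a_lo <- (1 - level) / 2
  used <- method
  if (method == "bca") {
    prop <- (sum(boots < d_obs) + 0.5 * sum(boots == d_obs)) / length(boots)
    jack <- c(
      vapply(seq_len(n1), function(i) cohens_d(x[-i], y), 1),
      vapply(seq_len(n2), function(i) cohens_d(x, y[-i]), 1))
    jm <- mean(jack)
    denom <- sum((jm - jack)^2)
    if (prop <= 0 || prop >= 1 || denom <= 0) {
      used <- "percentile"
    } else {
      z0 <- stats::qnorm(prop)
      acc <- sum((jm - jack)^3) / (6 * denom^1.5)
      adj <- function(a) {
        za <- z0 + stats::qnorm(a)
        stats::pnorm(z0 + za / (1 - acc * za))
      }
      qs <- stats::quantile(boots, c(adj(a_lo), adj(1 - a_lo)),
                            names = FALSE, type = 6)
    }
  }
  if (used == "percentile") {
    qs <- stats::quantile(boots, c(a_lo, 1 - a_lo), names = FALSE, type = 6)
  }
  structure(qs, method = used, d = d_obs, boot = boots, level = level)
}

#' Pearson correlation with the t-transform p value
#'
#' Standard product-moment correlation; the two-sided p value comes from
#' the t transform with n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param values,covariate numeric vectors of equal length >= 3 with
#'   nonzero variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_corr <- function(values, covariate) {
  if (length(values) != length(covariate) || length(values) < 3L) {
    stop("need two equal-length vectors with n >= 3")
  }
  if (stats::sd(values) == 0 || stats::sd(covariate) == 0) {
    stop("constant input: correlation undefined")
  }
  ct <- stats::cor.test(values, covariate, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(values))
}

#' Group-difference estimation statistics on TOI amplitudes
#'
#' Bundles the permutation independent-samples test, Cohen's d with its
#' bootstrap confidence interval, and (when ages are supplied) the
#' Pearson correlation between amplitude and age.
#'
#' @param x amplitudes of the first group (conventionally the older
#'   children, so positive d means larger amplitudes with age).
#' @param y amplitudes of the second group.
#' @param ages optional ages ordered as `c(ages_of_x, ages_of_y)`.
#' @param n_reshuffles,n_boot resampling sizes (defaults 5000).
#' @param level confidence level for the d interval.
#' @param seed integer seed.
#' @param ci_method `"bca"` or `"percentile"`.
#' @return An `mmf_estimation` with group summaries, `p_perm`, `d`,
#'   `d_ci`, and `correlation` (or `NULL`).
#' @export
estimate_group_effect <- function(x, y, ages = NULL, n_reshuffles = 5000L,
                                  n_boot = 5000L, level = 0.95, seed = 1L,
                                  ci_method = "bca") {
  seeds <- derive_seeds(seed, 2L)
  perm <- permutation_ttest_ind(x, y, n_reshuffles, seed = seeds[1L])
  d <- cohens_d(x, y)
  ci <- bootstrap_ci_d(x, y, n_boot, level, seed = seeds[2L],
                       method = ci_method)
  corr <- if (!is.null(ages)) pearson_corr(c(x, y), ages) else NULL
  structure(list(
    groups = data.frame(group = c("x", "y"), n = c(length(x), length(y)),
                        mean = c(mean(x), mean(y)),
                        sd = c(stats::sd(x), stats::sd(y))),
    mean_diff = mean(x) - mean(y),
    p_perm = perm$p, n_reshuffles = n_reshuffles,
    d = d, d_ci = as.numeric(ci), d_boot = attr(ci, "boot"),
    ci_method = attr(ci, "method"),
    ci_level = level, n_boot = n_boot,
    correlation = corr, seed = seed),
    class = "mmf_estimation")
}

#' @export
print.mmf_estimation <- function(x, digits = 3, ...) {
  g <- x$groups
  cat("<mmf_estimation>\n")
  cat(sprintf("  group %s: n = %d, M = %.*f, SD = %.*f\n", g$group, g$n,
              digits, g$mean, digits, g$sd), sep = "")
  cat(sprintf("  mean difference %.3g, permutation P = %.4f (%d reshuffles)\n",
              x$mean_diff, x$p_perm, x$n_reshuffles))
  cat(sprintf("  Cohen's d = %.2f (%d%% %s CI: %.2f to %.2f)\n", x$d,
              round(100 * x$ci_level), x$ci_method, x$d_ci[1], x$d_ci[2]))
  if (!is.null(x$correlation)) {
    cat(sprintf("  Pearson r (amplitude vs age) = %.2f, P = %.4f\n",
                x$correlation$r, x$correlation$p))
  }
  invisible(x)
}

#' Gardner-Altman style estimation plot
#'
#' Group scatter with means on the left axes and the bootstrap
#' distribution of Cohen's d with its confidence interval on the right
#' axis.
#'
#' @param x an `mmf_estimation`.
#' @param labels group axis labels.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.mmf_estimation <- function(x, labels = c("older", "younger"), ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  g <- x$groups
  graphics::plot(NA, xlim = c(0.5, 2.5),
                 ylim = range(g$mean + 3 * c(-max(g$sd), max(g$sd))),
                 xaxt = "n", xlab = "", ylab = "TOI mean amplitude (a.u.)",
                 main = "groups", ...)
  graphics::axis(1, at = 1:2, labels = labels)
  graphics::points(1:2, g$mean, pch = 19, cex = 1.4)
  graphics::arrows(1:2, g$mean - g$sd, 1:2, g$mean + g$sd, angle = 90,
                   code = 3, length = 0.05)
  graphics::plot(stats::density(x$d_boot %||% x$d),
                 main = sprintf("d = %.2f [%.2f, %.2f]", x$d, x$d_ci[1],
                                x$d_ci[2]),
                 xlab = "Cohen's d (bootstrap)")
  graphics::abline(v = c(x$d, x$d_ci), lty = c(1, 2, 2))
  invisible(x)
}
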