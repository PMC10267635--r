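#' Plot EMS time courses
#'
#' Standard and deviant traces with the mismatch difference.
#'
#' @param x an `ems_timecourse`.
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.ems_timecourse <- function(x, ...) {
  graphics::matplot(x$times, cbind(x$standard, x$deviant, x$mmf),
                    type = "l", lty = c(1, 1, 2), col = c(4, 2, 1),
                    xlab = "time (s)", ylab = "EMS amplitude (a.u.)", ...)
  graphics::abline(v = 0, col = "grey")
  graphics::legend("topleft", c("standard", "deviant", "MMF"),
                   lty = c(1, 1, 2), col = c(4, 2, 1), bty = "n")
  invisible(x)
}

#' Plot a cluster permutation test
#'
#' Pointwise t values, the cluster-forming threshold, and shading over
#' significant clusters.
#'
#' @param x a `cluster_test`.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.cluster_test <- function(x, ...) {
  tx <- x$times %||% seq_along(x$t)
  graphics::plot(tx, x$t, type = "l", xlab = if (is.null(x$times))
    "sample" else "time (s)", ylab = "t value", ...)
  graphics::abline(h = c(-x$threshold, x$threshold), lty = 3)
  cl <- x$clusters
  if (nrow(cl)) {
    for (i in which(cl$significant)) {
      graphics::rect(tx[cl$start[i]], graphics::par("usr")[3],
                     tx[cl$end[i]], graphics::par("usr")[4],
                     col = grDevices::adjustcolor("red", 0.15), border = NA)
    }
  }
  invisible(x)
}
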