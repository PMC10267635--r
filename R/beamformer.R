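#' Combined-condition sensor covariance with diagonal regularization
#'
#' Sample covariance pooled over all epochs and timepoints of both
#' conditions (channels centered over the pooled samples), then
#' regularized as `C + lambda * mean(diag(C)) * I`.
#'
#' @param epochs an `epoch_set` containing both conditions.
#' @param lambda regularization as a fraction of the mean diagonal
#'   (default 0.05). With `lambda = 0` the matrix must already be
#'   positive definite.
#' @return A `covariance_model`: `cov` (regularized), `cov_raw`,
#'   `lambda`, `n_samples`, `inv` (inverse of the regularized matrix).
#' @export
compute_covariance <- function(epochs, lambda = 0.05) {
  stopifnot(inherits(epochs, "epoch_set"), lambda >= 0)
  if (length(unique(epochs$labels)) < 2L) {
    stop("covariance is defined on the conditions combined; both are required")
  }
  d <- dim(epochs$data)
  X <- matrix(aperm(epochs$data, c(2, 1, 3)), d[2], d[1] * d[3]) # ch x (e*t)
  X <- X - rowMeans(X)
  n <- ncol(X)
  C <- tcrossprod(X) / (n - 1)
  Creg <- C + lambda * mean(diag(C)) * diag(d[2])
  inv <- tryCatch(chol2inv(chol(Creg)), error = function(e) NULL)
  if (is.null(inv)) {
    stop("covariance is rank deficient; use lambda > 0 to regularize")
  }
  structure(list(cov = Creg, cov_raw = C, lambda = lambda, n_samples = n,
                 inv = inv, condition_scope = "combined"),
            class = "covariance_model")
}

#' @export
print.covariance_model <- function(x, ...) {
  cat("<covariance_model>", nrow(x$cov), "channels,", x$n_samples,
      "samples, lambda =", x$lambda, "(combined conditions)\n")
  invisible(x)
}

#' LCMV beamformer filter for one source-grid vertex
#'
#' Linearly constrained minimum variance filter with free orientation in
#' the tangential plane. The scalar orientation maximizes the output
#' power-to-noise ratio (pseudo-Z) of the unit-gain beamformer, i.e. the
#' generalized eigenvector of `t(L) C^-1 L` against `t(L) C^-2 L` with
#' the largest eigenvalue. Unlike the raw minimum-eigenvalue rule this
#' choice is invariant to the leadfield norm, which otherwise biases the
#' orientation toward the weakly coupled tangential direction. The
#' weights satisfy unit gain `w . (L eta) = 1`.
#'
#' @param L channels x 2 leadfield of the vertex ([dipole_leadfield()]).
#' @param cov a `covariance_model`.
#' @param vertex optional label used in error messages.
#' @return List with `weights` (channels), `orientation` (2-vector in the
#'   tangential basis), `ori3d` when the leadfield carries its basis,
#'   and `power` (output variance).
#' @export
lcmv_vertex_filter <- function(L, cov, vertex = NULL) {
  stopifnot(inherits(cov, "covariance_model"), ncol(L) == 2L)
  CiL <- cov$inv %*% L
  M1 <- crossprod(L, CiL)            # t(L) C^-1 L
  M2 <- crossprod(CiL)               # t(L) C^-2 L
  if (!all(is.finite(M1)) || abs(det(M1)) < 1e-300) {
    stop("singular leadfield-covariance product at vertex ",
         vertex %||% "<unnamed>")
  }
  # relative jitter keeps the generalized problem solvable when the
  # covariance is nearly rank deficient (e.g. a single noiseless source)
  M2r <- M2 + 1e-12 * sum(diag(M2)) * diag(2)
  eg <- eigen(solve(M2r, M1), symmetric = FALSE)
  eta <- Re(eg$vectors[, which.max(Re(eg$values))])
  eta <- eta / sqrt(sum(eta^2))
  l <- as.numeric(L %*% eta)
  Cil <- as.numeric(cov$inv %*% l)
  denom <- sum(l * Cil)
  if (denom <= 0) {
    stop("degenerate LCMV solution at vertex ", vertex %||% "<unnamed>")
  }
  w <- Cil / denom
  basis <- attr(L, "basis")
  list(weights = w, orientation = eta,
       ori3d = if (!is.null(basis)) as.numeric(basis %*% eta) else NULL,
       power = 1 / denom)
}

#' Combined ROI spatial filter by centroid-proximity weighting
#'
#' Computes an LCMV filter at every voxel of the ROI, aligns the
#' (sign-ambiguous) vertex orientations to the centroid's orientation,
#' and averages the vertex filters with Gaussian proximity weights
#' `exp(-d^2 / (2 sigma^2))` normalized to sum 1, where `d` is the
#' distance to the ROI centroid voxel ([roi_centroid()]).
#'
#' @param grid a `source_grid`.
#' @param roi ROI label.
#' @param array the `sensor_array` (for leadfields).
#' @param cov a `covariance_model`.
#' @param sigma_prox Gaussian width in meters; default is the median
#'   distance of the ROI voxels to the centroid. `0` collapses onto the
#'   centroid filter.
#' @param leadfields optional precomputed list of leadfields indexed by
#'   voxel number (saves recomputation across participants).
#' @return An `roi_filter`: `weights` (channels), `roi`, `centroid`
#'   (voxel index), `prox_weights`, `orientations` (3-vectors per voxel).
#' @export
roi_spatial_filter <- function(grid, roi, array, cov, sigma_prox = NULL,
                               leadfields = NULL) {
  idx <- which(grid$roi_labels == roi)
  if (!length(idx)) stop("empty ROI: ", roi)
  cen <- roi_centroid(grid, roi)
  P <- grid$positions[idx, , drop = FALSE]
  d <- sqrt(rowSums(sweep(P, 2, grid$positions[cen, ])^2))
  sigma_prox <- sigma_prox %||% stats::median(d[d > 0])
  if (length(idx) == 1L || !is.finite(sigma_prox)) {
    pw <- rep(1, length(idx))
  } else if (sigma_prox <= 0) {
    pw <- as.numeric(d == 0)
  } else {
    pw <- exp(-d^2 / (2 * sigma_prox^2))
  }
  pw <- pw / sum(pw)

  filt <- lapply(seq_along(idx), function(i) {
    v <- idx[i]
    L <- if (!is.null(leadfields)) leadfields[[v]] else {
      dipole_leadfield(grid$positions[v, ], array)
    }
    lcmv_vertex_filter(L, cov, vertex = v)
  })
  cen_i <- which(idx == cen)
  ori_cen <- filt[[cen_i]]$ori3d
  # polarity is fixed against a geometry-only reference direction so that
  # traces are comparable across participants (the eigenvector sign is
  # arbitrary and would otherwise flip from one covariance to the next)
  ref <- tangential_basis(grid$positions[cen, ])[, 1L]
  flip <- if (sum(ori_cen * ref) < 0) -1 else 1
  ori_cen <- flip * ori_cen
  w <- 0
  oris <- matrix(0, length(idx), 3L)
  for (i in seq_along(idx)) {
    s <- if (sum(filt[[i]]$ori3d * ori_cen) < 0) -1 else 1
    oris[i, ] <- s * filt[[i]]$ori3d
    w <- w + pw[i] * s * filt[[i]]$weights
  }
  structure(list(roi = roi, weights = w, centroid = cen,
                 voxels = idx, prox_weights = pw, sigma_prox = sigma_prox,
                 orientations = oris),
            class = "roi_filter")
}

#' Project evoked fields through ROI spatial filters
#'
#' Right-multiplies the per-condition ERFs by each ROI filter, yielding
#' one source time course per ROI and condition plus the mismatch
#' (deviant minus standard) trace.
#'
#' @param filters list of `roi_filter` objects (typically six).
#' @param evoked an `evoked_field`.
#' @return An `roi_timecourse_set`: per ROI a list with `standard`,
#'   `deviant`, `mmf` traces (nominal A m); plus `times`.
#' @export
project_rois <- function(filters, evoked) {
  stopifnot(inherits(evoked, "evoked_field"))
  out <- lapply(filters, function(f) {
    if (length(f$weights) != nrow(evoked$standard)) {
      stop("filter and ERF channel axes do not match")
    }
    std <- as.numeric(f$weights %*% evoked$standard)
    dev <- as.numeric(f$weights %*% evoked$deviant)
    list(standard = std, deviant = dev, mmf = dev - std)
  })
  names(out) <- vapply(filters, function(f) f$roi, "")
  structure(list(rois = out, times = evoked$times),
            class = "roi_timecourse_set")
}

#' @export
print.roi_timecourse_set <- function(x, ...) {
  cat("<roi_timecourse_set>", length(x$rois), "ROIs x",
      length(x$times), "samples:", paste(names(x$rois), collapse = ", "),
      "\n")
  invisible(x)
}
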