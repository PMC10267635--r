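#' Stratified cross-validation folds
#'
#' Assigns epochs to `k` folds so every fold's condition proportions match
#' the global proportions to within one epoch (round-robin deal of a
#' seeded shuffle within each condition). Deterministic given the seed.
#'
#' @param labels condition label per epoch.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return Integer fold assignment (1..k) per epoch.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("need at least 2 folds to hold data out")
  tab <- table(labels)
  if (length(tab) < 2L) stop("all epochs share one condition label")
  if (any(tab < k)) {
    stop("each condition needs at least k epochs for stratified folds")
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    for (lv in names(tab)) {
      idx <- sample(which(labels == lv))
      folds[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  folds
}

# Per-channel mean and sd pooled over epochs x timepoints.
zscore_stats <- function(data) {
  d <- dim(data)
  m <- matrix(aperm(data, c(1, 3, 2)), d[1] * d[3], d[2]) # (e*t) x ch
  mu <- colMeans(m)
  sdv <- sqrt(colMeans(sweep(m, 2, mu)^2) * nrow(m) / (nrow(m) - 1))
  if (any(sdv <= .Machine$double.eps)) {
    warning("zero-variance channel(s): z-score sd floored at machine epsilon")
    sdv <- pmax(sdv, .Machine$double.eps)
  }
  list(mean = mu, sd = sdv)
}

zscore_apply <- function(data, stats) {
  d <- dim(data)
  out <- sweep(data, 2, stats$mean, "-")
  sweep(out, 2, stats$sd, "/")
}

#' Derive an effect-matched spatial (EMS) filter from training epochs
#'
#' The filter at each channel and timepoint is the deviant-minus-standard
#' difference of the z-scored training means; with `normalize = TRUE`
#' (default) each time slice is scaled to unit Euclidean norm (all-zero
#' slices stay zero).
#'
#' @param data epochs x channels x samples array (training folds).
#' @param labels condition per epoch; both conditions must be present.
#' @param stats z-score statistics from the training data
#'   (per-channel `mean`, `sd`).
#' @param normalize unit-norm time slices (default TRUE).
#' @return An `ems_filter`: `weights` (channels x samples), `normalized`.
#' @export
derive_ems_filter <- function(data, labels, stats = zscore_stats(data),
                              normalize = TRUE) {
  if (length(unique(labels)) < 2L) {
    stop("both conditions must be present in the training folds")
  }
  z <- zscore_apply(data, stats)
  w <- colMeans(z[labels == "deviant", , , drop = FALSE], dims = 1) -
    colMeans(z[labels == "standard", , , drop = FALSE], dims = 1)
  if (normalize) {
    nrm <- sqrt(colSums(w^2))
    nz <- nrm > 0
    w[, nz] <- sweep(w[, nz, drop = FALSE], 2, nrm[nz], "/")
  }
  structure(list(weights = w, normalized = normalize), class = "ems_filter")
}

#' Apply an EMS filter to held-out epochs
#'
#' Projects each z-scored epoch through the filter:
#' `y_e(t) = sum_c w(c, t) * x_e(c, t)`.
#'
#' @param filter an `ems_filter`.
#' @param data epochs x channels x samples array.
#' @param stats z-score statistics (from the training data, never from
#'   `data` itself).
#' @return epochs x samples matrix of spatially filtered traces.
#' @export
apply_ems_filter <- function(filter, data, stats) {
  w <- filter$weights
  d <- dim(data)
  if (d[2] != nrow(w) || d[3] != ncol(w)) {
    stop("epoch and filter channel/time axes do not match")
  }
  z <- zscore_apply(data, stats)
  out <- matrix(0, d[1], d[3])
  for (e in seq_len(d[1])) out[e, ] <- colSums(z[e, , ] * w)
  out
}

#' Cross-validated EMS time courses for one participant
#'
#' For each of `k` stratified folds, z-score statistics and the spatial
#' filter are estimated from the other `k - 1` folds and applied to the
#' held-out fold; held-out traces are pooled and averaged per condition.
#' With `crossval = FALSE` the filter is derived from and applied to the
#' same data (the circular variant, retained only as a contrast for bias
#' checks).
#'
#' @param epochs an `epoch_set`.
#' @param k folds (default 5).
#' @param seed fold-assignment seed.
#' @param normalize unit-norm filter slices (default TRUE).
#' @param crossval set `FALSE` for the circular same-data variant.
#' @return An `ems_timecourse`: `standard` and `deviant` mean traces,
#'   `mmf` difference trace, `times`, `k`, `folds`.
#' @export
ems_crossval <- function(epochs, k = 5L, seed = 1L, normalize = TRUE,
                         crossval = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  labels <- epochs$labels
  d <- dim(epochs$data)
  traces <- matrix(NA_real_, d[1], d[3])
  if (crossval) {
    folds <- stratified_folds(labels, k, seed)
    for (f in seq_len(k)) {
      tr <- folds != f
      st <- zscore_stats(epochs$data[tr, , , drop = FALSE])
      flt <- derive_ems_filter(epochs$data[tr, , , drop = FALSE],
                               labels[tr], st, normalize)
      traces[!tr, ] <- apply_ems_filter(flt, epochs$data[!tr, , , drop = FALSE],
                                        st)
    }
  } else {
    folds <- rep(0L, d[1])
    st <- zscore_stats(epochs$data)
    flt <- derive_ems_filter(epochs$data, labels, st, normalize)
    traces[, ] <- apply_ems_filter(flt, epochs$data, st)
  }
  std <- colMeans(traces[labels == "standard", , drop = FALSE])
  dev <- colMeans(traces[labels == "deviant", , drop = FALSE])
  structure(list(standard = std, deviant = dev, mmf = dev - std,
                 times = epochs$times, k = k, folds = folds,
                 crossval = crossval),
            class = "ems_timecourse")
}

#' @export
print.ems_timecourse <- function(x, ...) {
  cat("<ems_timecourse>", length(x$times), "samples,",
      if (x$crossval) paste0(x$k, "-fold cross-validated")
      else "same-data (circular)", "\n")
  invisible(x)
}

#' Mean mismatch amplitude inside a time window of interest
#'
#' Average of the deviant-minus-standard EMS trace over the TOI. A TOI
#' extending beyond the epoch is clipped with a warning.
#'
#' @param tc an `ems_timecourse` (or any list with `mmf` and `times`).
#' @param toi length-2 numeric `c(start, end)` in seconds.
#' @return Scalar mean amplitude (arbitrary units).
#' @export
mean_amplitude <- function(tc, toi) {
  stopifnot(length(toi) == 2L, toi[1] < toi[2])
  tr <- range(tc$times)
  if (toi[1] < tr[1] || toi[2] > tr[2]) {
    warning(sprintf("TOI [%g, %g] clipped to the epoch span [%g, %g]",
                    toi[1], toi[2], tr[1], tr[2]))
    toi <- c(max(toi[1], tr[1]), min(toi[2], tr[2]))
  }
  sel <- tc$times >= toi[1] & tc$times <= toi[2]
  if (!any(sel)) stop("empty TOI: no samples inside the window")
  mean(tc$mmf[sel])
}
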