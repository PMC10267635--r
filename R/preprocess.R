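#' Design the zero-phase FIR filter taps for a recording
#'
#' Windowed-sinc FIR with a Blackman window: a unit-DC-gain low-pass at
#' `lowpass` convolved with a spectral-inversion high-pass at `highpass`
#' (exactly zero response at DC for any order) and with a band-stop for
#' every notch frequency.
#' The composite is linear phase (odd length, symmetric), so a one-pass
#' application with group-delay compensation has zero net delay.
#'
#' @param sfreq sampling rate, Hz.
#' @param n_samples recording length in samples (caps the filter order).
#' @param highpass,lowpass band edges, Hz (`0 <= highpass < lowpass <
#'   Nyquist`); `highpass = 0` designs a pure low-pass.
#' @param notches numeric vector of band-stop center frequencies, Hz
#'   (default 50); notches at or above `lowpass` are dropped.
#' @param transition transition bandwidth, Hz; defaults to `highpass`
#'   (or `lowpass / 4` for a pure low-pass), the narrow edge that
#'   dominates the required order.
#' @param notch_halfwidth half-width of each band-stop, Hz (default 2.5).
#' @param max_order_frac cap on taps as a fraction of the recording length
#'   (default 0.1).
#' @return Numeric vector of taps (odd length) with design metadata in
#'   attributes.
#' @export
design_fir <- function(sfreq, n_samples, highpass = 0.1, lowpass = 40,
                       notches = 50, transition = NULL,
                       notch_halfwidth = 2.5, max_order_frac = 0.1) {
  nyq <- sfreq / 2
  if (!(highpass >= 0 && highpass < lowpass && lowpass < nyq)) {
    stop("need 0 <= highpass < lowpass < Nyquist")
  }
  transition <- transition %||% if (highpass > 0) highpass else lowpass / 4
  cap <- floor(max_order_frac * n_samples / 2)
  odd_taps <- function(tw) {
    nt <- min(ceiling(5.5 * sfreq / tw), cap)
    if (nt %% 2L == 0L) nt <- nt - 1L
    nt
  }
  lp_design <- function(fc, nt) {
    h <- as.numeric(signal::fir1(nt - 1L, fc / nyq, type = "low",
                                 window = signal::blackman(nt)))
    h / sum(h) # unit gain at DC, exactly
  }
  nt_lp <- odd_taps(max(lowpass / 4, 2))
  if (nt_lp < 11L) stop("recording too short for a feasible filter order")
  taps <- lp_design(lowpass, nt_lp)
  if (highpass > 0) {
    # spectral-inversion high-pass: exact zero response at DC for any
    # order, with a transition width set by the achievable tap count
    nt_hp <- odd_taps(transition)
    if (nt_hp < 11L) stop("recording too short for a feasible filter order")
    hp <- -lp_design(highpass, nt_hp)
    hp[(nt_hp + 1L) / 2L] <- hp[(nt_hp + 1L) / 2L] + 1
    taps <- stats::convolve(as.numeric(taps), rev(as.numeric(hp)),
                            type = "open")
  }
  notches <- notches[notches < lowpass + 3 * notch_halfwidth & notches > 0]
  for (f0 in notches) {
    nt <- min(ceiling(5.5 * sfreq / notch_halfwidth), cap)
    if (nt %% 2L == 0L) nt <- nt - 1L
    bs <- signal::fir1(nt - 1L, c(f0 - notch_halfwidth, f0 + notch_halfwidth) / nyq,
                       type = "stop", window = signal::blackman(nt))
    taps <- stats::convolve(taps, rev(bs), type = "open")
  }
  structure(as.numeric(taps), ntaps = length(taps), highpass = highpass,
            lowpass = lowpass, notches = notches, sfreq = sfreq)
}

#' Frequency response of FIR taps
#'
#' @param taps filter taps.
#' @param freqs frequencies at which to evaluate, Hz.
#' @param sfreq sampling rate, Hz.
#' @return Complex response at each frequency.
#' @export
fir_freq_response <- function(taps, freqs, sfreq) {
  k <- seq_along(taps) - 1
  vapply(freqs, function(f) {
    sum(taps * exp(-2i * pi * f * k / sfreq))
  }, complex(1))
}

# FFT convolution of each row of `x` with `taps`, keeping the centered
# (group-delay-compensated) portion so the net delay is zero.
fft_filter_rows <- function(x, taps) {
  n <- ncol(x)
  m <- length(taps)
  L <- stats::nextn(n + m - 1L, 2)
  H <- stats::fft(c(taps, rep(0, L - m)))
  d <- (m - 1L) %/% 2L
  out <- matrix(0, nrow(x), n)
  chunk <- max(1L, min(nrow(x), floor(2^22 / L)))
  i <- 1L
  while (i <= nrow(x)) {
    j <- min(i + chunk - 1L, nrow(x))
    X <- rbind(t(x[i:j, , drop = FALSE]), matrix(0, L - n, j - i + 1L))
    Y <- stats::mvfft(stats::mvfft(X) * H, inverse = TRUE) / L
    out[i:j, ] <- t(Re(Y[(d + 1L):(d + n), , drop = FALSE]))
    i <- j + 1L
  }
  out
}

#' Zero-phase FIR filtering of a continuous recording
#'
#' One-pass application of the [design_fir()] windowed-sinc filter with
#' group-delay compensation (linear phase, zero net delay). The band-pass
#' response is exactly zero at DC, so constant offsets are removed.
#'
#' @param recording a `continuous_recording` (channels x samples `data`,
#'   `sfreq`).
#' @param highpass,lowpass,notches,transition,max_order_frac see
#'   [design_fir()].
#' @return The recording with filtered `data` and the applied taps in
#'   `$filter`.
#' @export
fir_filter <- function(recording, highpass = 0.1, lowpass = 40,
                       notches = 50, transition = NULL,
                       max_order_frac = 0.1) {
  taps <- design_fir(recording$sfreq, ncol(recording$data), highpass,
                     lowpass, notches, transition,
                     max_order_frac = max_order_frac)
  recording$data <- fft_filter_rows(recording$data, taps)
  recording$filter <- list(taps = taps, highpass = highpass,
                           lowpass = lowpass, notches = notches)
  recording
}

#' Epoch a continuous recording around stimulus onsets
#'
#' Cuts half-open windows `[onset + tmin, onset + tmax)` around every
#' event and excludes the first `drop_first` events of each block.
#' Events whose window falls outside the recording are dropped with a
#' logged reason.
#'
#' @param recording a `continuous_recording` with an embedded `events`
#'   table (or pass `events`).
#' @param events optional events data frame (`onset` seconds relative to
#'   recording start, `category`, `subtype`, `block`, `index`).
#' @param tmin,tmax epoch window relative to onset, seconds (defaults
#'   -0.1 and 0.4).
#' @param drop_first leading events per block to exclude (default 15).
#' @return An `epoch_set`: `data` (epochs x channels x samples), `labels`
#'   (`standard` / `deviant`), `subtype`, `times`, `sfreq`, `array`, and a
#'   bookkeeping `log`.
#' @export
epoch_events <- function(recording, events = NULL, tmin = -0.1, tmax = 0.4,
                         drop_first = 15L) {
  if (tmin >= tmax) stop("empty epoch window: need tmin < tmax")
  ev <- events %||% recording$events
  fs <- recording$sfreq
  n_len <- round((tmax - tmin) * fs)
  onset_samp <- round(ev$onset * fs) + 1L
  start <- onset_samp + round(tmin * fs)
  keep_first <- ev$index > drop_first
  in_bounds <- start >= 1L & (start + n_len - 1L) <= ncol(recording$data)
  keep <- keep_first & in_bounds
  n_oob <- sum(keep_first & !in_bounds)
  if (n_oob > 0) {
    warning(n_oob, " epoch(s) dropped: window outside the recording")
  }
  idx <- which(keep)
  if (!length(idx)) stop("no epochs left after exclusions")
  data <- array(0, dim = c(length(idx), nrow(recording$data), n_len))
  for (k in seq_along(idx)) {
    sl <- start[idx[k]]:(start[idx[k]] + n_len - 1L)
    data[k, , ] <- recording$data[, sl]
  }
  structure(list(
    data = data,
    labels = ev$category[idx],
    subtype = ev$subtype[idx],
    times = tmin + (seq_len(n_len) - 1) / fs,
    sfreq = fs,
    array = recording$array,
    participant = recording$seed %||% NA,
    log = list(n_input = nrow(ev), n_dropped_first = sum(!keep_first),
               n_dropped_oob = n_oob, n_kept = length(idx),
               n_dropped_artifact = 0L, interpolated = character(0))
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set>", d[1], "epochs x", d[2], "channels x", d[3],
      "samples;", sum(x$labels == "standard"), "standard /",
      sum(x$labels == "deviant"), "deviant\n")
  invisible(x)
}

epoch_ptp <- function(data) {
  # peak-to-peak per epoch x channel, column-wise to avoid apply() overhead
  d <- dim(data)
  m <- matrix(data, d[1] * d[2], d[3])
  mx <- m[, 1]
  mn <- m[, 1]
  for (j in seq_len(d[3])[-1]) {
    mx <- pmax(mx, m[, j])
    mn <- pmin(mn, m[, j])
  }
  matrix(mx - mn, d[1], d[2])
}

#' Reject artifact epochs and interpolate bad channels
#'
#' Automated stand-in for visual artifact screening: epochs whose
#' peak-to-peak amplitude on any good channel exceeds `ptp_threshold` are
#' dropped, and bad channels (listed, or auto-detected from a robust
#' z-score of their median log peak-to-peak amplitude) are replaced by
#' inverse-distance-weighted averages of their `k` nearest good
#' neighbors.
#'
#' @param epochs an `epoch_set`.
#' @param ptp_threshold peak-to-peak rejection threshold in sensor units
#'   (> 0; `Inf` disables rejection).
#' @param bad_channels character vector of channel names, `"auto"`, or
#'   `NULL` for none.
#' @param k neighbors used for interpolation (default 4).
#' @param auto_z robust z threshold for auto detection (default 5).
#' @return The `epoch_set` with artifact epochs removed, bad channels
#'   interpolated, and the `log` updated.
#' @export
reject_and_interpolate <- function(epochs, ptp_threshold, bad_channels = "auto",
                                   k = 4L, auto_z = 5) {
  stopifnot(inherits(epochs, "epoch_set"), ptp_threshold > 0)
  ch_names <- epochs$array$channel_names
  ptp <- epoch_ptp(epochs$data)
  bad <- character(0)
  if (identical(bad_channels, "auto")) {
    med <- apply(ptp, 2, stats::median)
    lg <- log(pmax(med, .Machine$double.xmin))
    z <- (lg - stats::median(lg)) / max(stats::mad(lg), 1e-12)
    bad <- ch_names[abs(z) > auto_z]
  } else if (!is.null(bad_channels)) {
    bad <- intersect(bad_channels, ch_names)
  }
  if (length(bad) > length(ch_names) / 2) {
    stop("more than half the channels are bad: unrecoverable recording")
  }
  good_idx <- which(!ch_names %in% bad)
  drop <- apply(ptp[, good_idx, drop = FALSE], 1, max) > ptp_threshold
  if (all(drop)) stop("all epochs exceed the rejection threshold")
  epochs$data <- epochs$data[!drop, , , drop = FALSE]
  epochs$labels <- epochs$labels[!drop]
  epochs$subtype <- epochs$subtype[!drop]
  if (length(bad)) {
    pos <- epochs$array$positions
    for (b in which(ch_names %in% bad)) {
      d <- sqrt(rowSums(sweep(pos[good_idx, , drop = FALSE], 2, pos[b, ])^2))
      nb <- good_idx[order(d)[seq_len(min(k, length(good_idx)))]]
      w <- 1 / pmax(sort(d)[seq_along(nb)], 1e-9)
      w <- w / sum(w)
      interp <- 0
      for (j in seq_along(nb)) {
        interp <- interp + w[j] * epochs$data[, nb[j], , drop = FALSE]
      }
      epochs$data[, b, ] <- interp
    }
  }
  epochs$log$n_dropped_artifact <- sum(drop)
  epochs$log$n_kept <- dim(epochs$data)[1]
  epochs$log$interpolated <- bad
  epochs
}

#' Average epochs into per-condition evoked fields and the mismatch field
#'
#' Arithmetic mean over epochs per condition, pooling all four deviant
#' subtypes; the mismatch field (MMF) is the deviant minus standard
#' difference.
#'
#' @param epochs an `epoch_set` with at least one epoch per condition.
#' @return An `evoked_field`: `standard`, `deviant`, `mmf` (channels x
#'   samples), `n_epochs`, `times`.
#' @export
average_erfs <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_std <- sum(epochs$labels == "standard")
  n_dev <- sum(epochs$labels == "deviant")
  if (n_std < 1 || n_dev < 1) {
    stop("both conditions need at least one epoch to form ERFs")
  }
  avg <- function(sel) {
    x <- epochs$data[sel, , , drop = FALSE]
    colMeans(x, dims = 1)
  }
  std <- avg(epochs$labels == "standard")
  dev <- avg(epochs$labels == "deviant")
  structure(list(standard = std, deviant = dev, mmf = dev - std,
                 n_epochs = c(standard = n_std, deviant = n_dev),
                 times = epochs$times, array = epochs$array),
            class = "evoked_field")
}

#' @export
print.evoked_field <- function(x, ...) {
  cat("<evoked_field>", nrow(x$standard), "channels x", ncol(x$standard),
      "samples; n =", x$n_epochs["standard"], "standard /",
      x$n_epochs["deviant"], "deviant\n")
  invisible(x)
}
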