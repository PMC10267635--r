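#' Configuration for the synthetic oddball cohort simulator
#'
#' Defines a cohort of simulated participants in two age groups performing
#' the multi-feature oddball session. Every stimulus evokes a transient
#' response in bilateral A1; deviants additionally receive a mismatch
#' component in `mismatch_rois`, whose right-IFG amplitude is multiplied by
#' `group_gain_ifg` in the older group. Source activity is projected to the
#' axial-gradiometer array through the single-sphere forward model, with
#' additive white (optionally AR(1)) sensor noise and a per-participant
#' lognormal amplitude scale.
#'
#' @param n_younger,n_older group sizes (defaults 18 and 19).
#' @param group_gain_ifg older/younger ratio of the right-IFG mismatch
#'   amplitude (default 2).
#' @param mismatch_center,mismatch_width center and Gaussian SD of the
#'   mismatch window, seconds post-onset (defaults 0.29 and 0.03; the
#'   resulting support covers the 0.23-0.36 s span where the source-level
#'   effect is expected).
#' @param mismatch_latency_spread per-ROI latency progression, seconds:
#'   the mismatch peak moves from `mismatch_center - spread` in the first
#'   of `mismatch_rois` to `mismatch_center + spread` in the last
#'   (default 0.04), mimicking the feed-forward progression of prediction
#'   errors along the auditory hierarchy and decorrelating the sources.
#' @param mismatch_rois ROIs receiving the mismatch component, ordered
#'   low to high in the hierarchy (default right A1, STG, IFG).
#' @param evoked_latency peak latency of the obligatory auditory evoked
#'   component in bilateral A1, seconds (default 0.1).
#' @param evoked_width Gaussian SD of the evoked component, seconds.
#' @param evoked_freq carrier frequency of the evoked component, Hz.
#' @param evoked_amplitude evoked dipole moment, A m (default 40 nAm).
#' @param mismatch_amplitude mismatch dipole moment, A m (default 25 nAm).
#' @param noise_sd white sensor-noise SD per sample, tesla
#'   (default 3e-13, i.e. 300 fT broadband).
#' @param ar_coef AR(1) coefficient for temporally correlated noise
#'   (default 0 = white).
#' @param trial_jitter_sd sigma of the lognormal trial-to-trial amplitude
#'   fluctuation, drawn independently per stimulus and per source
#'   (default 1.0; mean-one, so evoked averages are unbiased). This is
#'   part of the noise model: it decorrelates the sources, as
#'   trial-varying generators do in real recordings; set it to 0 together
#'   with `noise_sd` for the noiseless limit.
#' @param background_dipoles number of randomly placed background brain
#'   dipoles generating spatially and temporally correlated ongoing
#'   activity (default 30; 0 disables). Positions are redrawn per
#'   participant.
#' @param background_amplitude rms moment of each background dipole, A m
#'   (default 15e-9).
#' @param background_tau AR(1) time constant of the background dynamics,
#'   seconds (default 0.05, concentrating power below ~20 Hz).
#' @param participant_scale_sd sigma of the lognormal per-participant
#'   amplitude scale (default 0.2).
#' @param seed master seed for the cohort.
#' @param sampling_rate MEG sampling rate, Hz (default 1000).
#' @param n_blocks,n_stimuli,soa paradigm shape (defaults 3 blocks of 495
#'   stimuli at 0.5 s SOA).
#' @param n_channels sensors in the array (default 125).
#' @param epoch_dropout per-participant probability that an epoch is lost
#'   to (simulated) artifacts downstream (default 0).
#' @param younger_age,older_age length-2 vectors `c(mean, sd)` of the group
#'   age distributions in years (defaults 4.1/0.9 and 6.2/0.4, truncated
#'   to 3.1-5.3 and 5.6-6.9).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_younger = 18L, n_older = 19L, group_gain_ifg = 2,
                       mismatch_center = 0.29, mismatch_width = 0.03,
                       mismatch_latency_spread = 0.04,
                       mismatch_rois = c("rA1", "rSTG", "rIFG"),
                       evoked_latency = 0.1, evoked_width = 0.03,
                       evoked_freq = 8, evoked_amplitude = 40e-9,
                       mismatch_amplitude = 25e-9,
                       noise_sd = 3e-13, ar_coef = 0,
                       trial_jitter_sd = 1.0,
                       background_dipoles = 30L,
                       background_amplitude = 15e-9,
                       background_tau = 0.05,
                       participant_scale_sd = 0.2, seed = 1L,
                       sampling_rate = 1000, n_blocks = 3L,
                       n_stimuli = 495L, soa = 0.5, n_channels = 125L,
                       epoch_dropout = 0,
                       younger_age = c(4.1, 0.9), older_age = c(6.2, 0.4)) {
  stopifnot(n_younger >= 1, n_older >= 1, noise_sd >= 0,
            mismatch_width > 0, sampling_rate > 0, epoch_dropout >= 0,
            epoch_dropout < 1, group_gain_ifg >= 0)
  if (mismatch_center < 0 || mismatch_center > soa) {
    stop("mismatch_window lies outside the epoch span")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_younger, "younger +", x$n_older, "older;",
      x$n_blocks, "x", x$n_stimuli, "stimuli @", x$sampling_rate, "Hz;",
      x$n_channels, "channels\n")
  cat("  mismatch:", paste(x$mismatch_rois, collapse = "/"),
      sprintf("center %.2f s (sd %.2f), rIFG group gain %.2f",
              x$mismatch_center, x$mismatch_width, x$group_gain_ifg), "\n")
  invisible(x)
}

#' Build the shared simulation geometry for a configuration
#'
#' Sensor array, labeled source grid, and the leadfields of one dipole per
#' ROI placed at the ROI centroid voxel with a fixed tangential
#' orientation (the first tangential basis vector).
#'
#' @param cfg a [sim_config()].
#' @return List with `array`, `grid`, `dipoles` (per-ROI list of
#'   `position`, `leadfield` (channels-long), `orientation`).
#' @export
make_default_geometry <- function(cfg = sim_config()) {
  array <- make_sensor_array(cfg$n_channels)
  grid <- make_source_grid()
  rois <- setdiff(unique(grid$roi_labels), "none")
  dipoles <- lapply(rois, function(roi) {
    v <- roi_centroid(grid, roi)
    pos <- grid$positions[v, ]
    L <- dipole_leadfield(pos, array)
    list(roi = roi, vertex = v, position = pos,
         leadfield = L[, 1L], orientation = attr(L, "basis")[, 1L])
  })
  names(dipoles) <- rois
  list(array = array, grid = grid, dipoles = dipoles)
}

# Per-ROI mismatch peak latencies: a linear progression across the
# configured ROI hierarchy around the window center.
mismatch_centers <- function(cfg) {
  k <- length(cfg$mismatch_rois)
  off <- if (k > 1) seq(-1, 1, length.out = k) else 0
  stats::setNames(cfg$mismatch_center + off * cfg$mismatch_latency_spread,
                  cfg$mismatch_rois)
}

# Per-stimulus source kernels on the epoch-local grid [0, soa), truncated
# at 0.4 s so no component leaks into the next epoch's pre-stimulus span.
sim_kernels <- function(cfg) {
  fs <- cfg$sampling_rate
  t <- (seq_len(round(cfg$soa * fs)) - 1) / fs
  support <- t <= 0.4
  evoked <- cfg$evoked_amplitude *
    exp(-(t - cfg$evoked_latency)^2 / (2 * cfg$evoked_width^2)) *
    cos(2 * pi * cfg$evoked_freq * (t - cfg$evoked_latency))
  evoked[abs(t - cfg$evoked_latency) > 3 * cfg$evoked_width] <- 0
  evoked[!support] <- 0
  centers <- mismatch_centers(cfg)
  mismatch <- lapply(centers, function(cen) {
    m <- cfg$mismatch_amplitude *
      exp(-(t - cen)^2 / (2 * cfg$mismatch_width^2))
    m[abs(t - cen) > 3 * cfg$mismatch_width] <- 0
    m[!support] <- 0
    m
  })
  list(t = t, evoked = evoked, mismatch = mismatch)
}

add_kernel_at <- function(trace, kernel, start_samples, gains = NULL) {
  L <- length(kernel)
  if (is.null(gains)) gains <- rep(1, length(start_samples))
  for (k in seq_along(start_samples)) {
    s <- start_samples[k]
    trace[s:(s + L - 1L)] <- trace[s:(s + L - 1L)] + gains[k] * kernel
  }
  trace
}

# mean-one lognormal trial gains
trial_gains <- function(n, sd) {
  if (sd <= 0) rep(1, n) else exp(stats::rnorm(n, 0, sd) - sd^2 / 2)
}

#' Simulate one participant's continuous recording
#'
#' Generates a full session with [make_session()], builds per-ROI source
#' moment time courses (evoked component in bilateral A1 for every
#' stimulus; mismatch component on deviant trials in the configured ROIs,
#' right-IFG scaled by the group gain for older participants), projects to
#' the sensors and adds noise. Fully deterministic given `seed`.
#'
#' @param cfg a [sim_config()].
#' @param group `"younger"` or `"older"`.
#' @param seed participant seed.
#' @param block_order permutation of 1:3 (default in-order).
#' @param geometry optional [make_default_geometry()] result (rebuilt when
#'   omitted; pass it when simulating many participants).
#' @return List with `recording` (fields `data` channels x samples in
#'   tesla, `sfreq`, `events`, `array`, `group`) and `truth` (per-ROI
#'   standard/deviant source kernels in A m, participant scale, mismatch
#'   window, group).
#' @export
simulate_participant <- function(cfg, group = c("younger", "older"),
                                 seed = 1L, block_order = 1:3,
                                 geometry = NULL) {
  group <- match.arg(group)
  if (is.null(geometry)) geometry <- make_default_geometry(cfg)
  fs <- cfg$sampling_rate
  seeds <- derive_seeds(seed, 4L)
  session <- make_session(seeds[1L], order = block_order,
                          n_stimuli = cfg$n_stimuli, soa = cfg$soa)
  session <- session$events[seq_len(min(nrow(session$events),
                                        cfg$n_blocks * cfg$n_stimuli)), ]
  start_pad <- 1.0
  session$onset <- session$onset + start_pad
  n_samp <- round((max(session$onset) + 1.0) * fs)
  ker <- sim_kernels(cfg)
  L <- length(ker$evoked)
  onset_samp <- round(session$onset * fs) + 1L
  dev_samp <- onset_samp[session$category == "deviant"]

  gain <- if (group == "older") cfg$group_gain_ifg else 1
  rois_active <- union(c("lA1", "rA1"), cfg$mismatch_rois)

  scale <- NULL
  source_traces <- list()
  truth_kernels <- list()
  with_seed(seeds[2L], {
    scale <- exp(stats::rnorm(1, 0, cfg$participant_scale_sd))
    for (roi in rois_active) {
      evo_k <- if (roi %in% c("lA1", "rA1")) ker$evoked else numeric(L)
      mis_k <- if (roi %in% cfg$mismatch_rois) {
        ker$mismatch[[roi]] * (if (roi == "rIFG") gain else 1)
      } else {
        numeric(L)
      }
      tr <- numeric(n_samp)
      if (any(evo_k != 0)) {
        tr <- add_kernel_at(tr, scale * evo_k, onset_samp,
                            trial_gains(length(onset_samp),
                                        cfg$trial_jitter_sd))
      }
      if (any(mis_k != 0)) {
        tr <- add_kernel_at(tr, scale * mis_k, dev_samp,
                            trial_gains(length(dev_samp),
                                        cfg$trial_jitter_sd))
      }
      source_traces[[roi]] <- tr
      truth_kernels[[roi]] <- list(standard = scale * evo_k,
                                    deviant = scale * (evo_k + mis_k))
    }
  })

  n_ch <- geometry$array$n_channels
  data <- matrix(0, n_ch, n_samp)
  for (roi in names(source_traces)) {
    lf <- geometry$dipoles[[roi]]$leadfield
    data <- data + outer(lf, source_traces[[roi]])
  }
  if (cfg$background_dipoles > 0 && cfg$background_amplitude > 0) {
    data <- data + with_seed(seeds[4L], {
      ar <- exp(-1 / (fs * cfg$background_tau))
      innov <- sqrt(1 - ar^2) * cfg$background_amplitude
      eligible <- which(vnorm(geometry$grid$positions) > 0.015)
      vox <- sample(eligible, cfg$background_dipoles)
      Lmat <- sapply(vox, function(v) {
        L <- dipole_leadfield(geometry$grid$positions[v, ], geometry$array)
        phi <- stats::runif(1, 0, 2 * pi)
        as.numeric(L %*% c(cos(phi), sin(phi)))
      })
      S <- sapply(seq_along(vox), function(i) {
        as.numeric(stats::filter(stats::rnorm(n_samp, 0, innov), ar,
                                 method = "recursive"))
      })
      Lmat %*% t(S)
    })
  }
  if (cfg$noise_sd > 0) {
    noise <- with_seed(seeds[3L],
                       matrix(stats::rnorm(n_ch * n_samp, 0, cfg$noise_sd),
                              n_ch, n_samp))
    if (cfg$ar_coef != 0) {
      innov_sd <- sqrt(1 - cfg$ar_coef^2) # keep marginal sd = noise_sd
      noise <- t(apply(noise * innov_sd, 1, function(x) {
        as.numeric(stats::filter(x, cfg$ar_coef, method = "recursive"))
      }))
    }
    data <- data + noise
  }

  recording <- list(data = data, sfreq = fs, events = session,
                    array = geometry$array, group = group, seed = seed)
  class(recording) <- "continuous_recording"
  truth <- list(kernels = truth_kernels, scale = scale, group = group,
                gain_ifg = gain,
                mismatch_rois = cfg$mismatch_rois,
                mismatch_window = c(min(mismatch_centers(cfg)) - 3 * cfg$mismatch_width,
                                    min(max(mismatch_centers(cfg)) + 3 * cfg$mismatch_width,
                                        0.4)),
                kernel_times = ker$t)
  list(recording = recording, truth = truth)
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat("<continuous_recording>", nrow(x$data), "channels x", ncol(x$data),
      "samples @", x$sfreq, "Hz;", nrow(x$events), "events\n")
  invisible(x)
}

block_order_table <- function(n) {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  perms[(seq_len(n) - 1L) %% 6L + 1L, , drop = FALSE]
}

# Cohort metadata (ids, groups, ages, seeds, block orders) without the
# heavy recordings; used by simulate_cohort and the streaming pipeline.
cohort_plan <- function(cfg) {
  n <- cfg$n_younger + cfg$n_older
  seeds <- derive_seeds(cfg$seed, n + 1L)
  group <- c(rep("younger", cfg$n_younger), rep("older", cfg$n_older))
  ages <- with_seed(seeds[n + 1L], {
    y <- stats::rnorm(cfg$n_younger, cfg$younger_age[1], cfg$younger_age[2])
    o <- stats::rnorm(cfg$n_older, cfg$older_age[1], cfg$older_age[2])
    c(pmin(pmax(y, 3.1), 5.3), pmin(pmax(o, 5.6), 6.9))
  })
  data.frame(id = sprintf("sub-%02d", seq_len(n)), group = group,
             age = ages, seed = seeds[seq_len(n)],
             order1 = block_order_table(n)[, 1],
             order2 = block_order_table(n)[, 2],
             order3 = block_order_table(n)[, 3],
             stringsAsFactors = FALSE)
}

#' Simulate a full cohort
#'
#' One recording per participant (`n_younger + n_older`), with
#' per-participant seeds derived from `cfg$seed` and block order
#' counterbalanced across participants (cycling the six permutations).
#' Recordings are materialized in memory; for large configurations prefer
#' the streaming [run_pipeline()], which simulates and reduces one
#' participant at a time.
#'
#' @param cfg a [sim_config()].
#' @param geometry optional shared geometry.
#' @return List with `participants` (each: `recording`, `truth`, `id`,
#'   `group`, `age`), `plan` (cohort metadata), `cfg`, `geometry`.
#' @export
simulate_cohort <- function(cfg = sim_config(), geometry = NULL) {
  if (is.null(geometry)) geometry <- make_default_geometry(cfg)
  plan <- cohort_plan(cfg)
  participants <- lapply(seq_len(nrow(plan)), function(i) {
    ps <- simulate_participant(cfg, group = plan$group[i],
                               seed = plan$seed[i],
                               block_order = as.integer(plan[i, c("order1", "order2", "order3")]),
                               geometry = geometry)
    c(ps, list(id = plan$id[i], group = plan$group[i], age = plan$age[i]))
  })
  list(participants = participants, plan = plan, cfg = cfg,
       geometry = geometry)
}
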