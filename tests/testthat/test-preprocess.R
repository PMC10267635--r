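test_that("the FIR design attenuates 50 Hz by over 40 dB and blocks DC", {
  taps <- design_fir(1000, 60000, highpass = 0.1, lowpass = 40,
                     notches = 50)
  H <- function(f) abs(fir_freq_response(taps, f, 1000))
  expect_lt(20 * log10(H(50)), -40)
  expect_lt(H(0), 1e-3)
  expect_equal(H(10), 1, tolerance = 0.01) # passband
  expect_lt(H(80), 0.01)                   # stopband above lowpass
  expect_error(design_fir(1000, 50, 0.1, 40), "too short")
})

test_that("one-pass zero-phase filtering has no net delay", {
  n <- 4000
  x <- matrix(0, 1, n)
  x[1, 2000] <- 1
  rec <- list(data = x, sfreq = 250)
  out <- fir_filter(rec, highpass = 1, lowpass = 40, notches = NULL)
  y <- out$data[1, ]
  expect_equal(which.max(y), 2000)
  # linear phase: response symmetric about the impulse
  k <- 300
  expect_equal(y[2000 + seq_len(k)], y[2000 - seq_len(k)],
               tolerance = 1e-10)
})

test_that("filtering removes a DC offset and a 50 Hz tone from data", {
  n <- 60000
  t <- (seq_len(n) - 1) / 1000
  x <- rbind(5 + sin(2 * pi * 50 * t), sin(2 * pi * 10 * t))
  rec <- list(data = x, sfreq = 1000)
  out <- fir_filter(rec)$data
  mid <- 10000:50000
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(out[1, mid]) / rms(x[1, mid] - 5), 0.01)
  expect_equal(rms(out[2, mid]), rms(x[2, mid]), tolerance = 0.02)
})

test_that("epoch windows are half-open with exact sample arithmetic", {
  data <- matrix(seq_len(3000), 1, 3000, byrow = TRUE)
  ev <- data.frame(onset = 0.999, category = "deviant",
                   subtype = "gap", block = 1L, index = 16L)
  rec <- list(data = data, sfreq = 1000, events = ev,
              array = list(channel_names = "MEG001"))
  ep <- epoch_events(rec, tmin = -0.1, tmax = 0.4)
  # onset at sample 1000 -> samples 900..1399 inclusive
  expect_equal(dim(ep$data)[3], 500)
  expect_equal(as.numeric(ep$data[1, 1, ]), 900:1399)
  expect_equal(ep$times[1], -0.1)
  expect_error(epoch_events(rec, tmin = 0.1, tmax = 0.1), "empty")
})

test_that("a default block yields 480 epochs after the first-15 exclusion", {
  blk <- make_block_sequence(1, seed = 2, n_stimuli = 495)
  ev <- blk$events
  ev$onset <- ev$onset + 1
  rec <- list(data = matrix(0, 1, 260000), sfreq = 1000, events = ev,
              array = list(channel_names = "MEG001"))
  ep <- epoch_events(rec)
  expect_equal(dim(ep$data)[1], 480)
  expect_equal(sum(ep$labels == "standard"), 240)
  expect_equal(sum(ep$labels == "deviant"), 240)
  expect_equal(ep$log$n_input,
               ep$log$n_kept + ep$log$n_dropped_first + ep$log$n_dropped_oob)
})

test_that("out-of-bounds epochs are dropped with a warning", {
  ev <- data.frame(onset = c(0.05, 1), category = c("standard", "deviant"),
                   subtype = c("none", "gap"), block = 1L, index = 16:17)
  rec <- list(data = matrix(0, 1, 2000), sfreq = 1000, events = ev,
              array = list(channel_names = "MEG001"))
  expect_warning(ep <- epoch_events(rec), "outside")
  expect_equal(dim(ep$data)[1], 1)
  expect_equal(ep$log$n_dropped_oob, 1)
})

test_that("artifact rejection drops exactly the spiked epoch", {
  ep <- random_epochs(10, 10, n_ch = 6, n_t = 40, sd = 1)
  base <- max(epochs_from_array(ep$data, ep$labels)$data)
  ep$data[7, 3, 20] <- ep$data[7, 3, 20] + 10 * max(abs(ep$data))
  thr <- 5 * max(abs(ep$data[-7, , ]))
  out <- reject_and_interpolate(ep, ptp_threshold = thr,
                                bad_channels = NULL)
  expect_equal(out$log$n_dropped_artifact, 1)
  expect_equal(dim(out$data)[1], 19)
  # clean data with any finite threshold loses nothing
  clean <- random_epochs(5, 5, n_ch = 4, n_t = 20)
  out2 <- reject_and_interpolate(clean, ptp_threshold = 1e6,
                                 bad_channels = NULL)
  expect_equal(out2$log$n_dropped_artifact, 0)
})

test_that("bad-channel interpolation reproduces identical neighbors", {
  n_ch <- 8
  arr <- make_sensor_array(n_ch)
  data <- array(0, dim = c(4, n_ch, 10))
  for (e in 1:4) for (c in seq_len(n_ch)) data[e, c, ] <- sin(1:10) * 2
  data[, 3, ] <- 100 # bad channel amid identical-valued neighbors
  ep <- epochs_from_array(data, c("standard", "standard", "deviant",
                                  "deviant"), array = arr)
  out <- reject_and_interpolate(ep, ptp_threshold = 1e6,
                                bad_channels = arr$channel_names[3])
  expect_equal(out$data[1, 3, ], sin(1:10) * 2, tolerance = 1e-12)
  expect_equal(out$log$interpolated, arr$channel_names[3])
  # refusing to continue when most channels are bad
  expect_error(reject_and_interpolate(ep, 1e6,
                                      bad_channels = arr$channel_names[1:5]),
               "half")
})

test_that("ERF averaging pools subtypes and subtracts exactly", {
  data <- array(0, dim = c(6, 3, 12))
  tmpl_s <- matrix(rnorm(36), 3, 12)
  tmpl_d <- tmpl_s + 2
  for (e in 1:3) data[e, , ] <- tmpl_s
  for (e in 4:6) data[e, , ] <- tmpl_d
  ep <- epochs_from_array(data, rep(c("standard", "deviant"), each = 3),
                          array = make_sensor_array(3))
  ev <- average_erfs(ep)
  expect_equal(ev$standard, tmpl_s)
  expect_equal(ev$deviant, tmpl_d)
  expect_equal(ev$mmf, tmpl_d - tmpl_s)
  expect_equal(unname(ev$n_epochs), c(3L, 3L))
  # permutation invariance of the mean
  perm <- c(4, 1, 6, 3, 2, 5)
  ep2 <- epochs_from_array(data[perm, , ], ep$labels[perm],
                           array = make_sensor_array(3))
  expect_equal(average_erfs(ep2)$mmf, ev$mmf)
  ep3 <- epochs_from_array(data[1:3, , , drop = FALSE],
                           rep("standard", 3),
                           array = make_sensor_array(3))
  expect_error(average_erfs(ep3), "condition")
})

test_that("a noiseless participant's sensor MMF is confined to the mismatch window", {
  cfg <- fast_sim_config(noise_sd = 0, trial_jitter_sd = 0,
                         background_dipoles = 0L,
                         participant_scale_sd = 0)
  geo <- make_default_geometry(cfg)
  ps <- simulate_participant(cfg, "younger", seed = 5, geometry = geo)
  ep <- epoch_events(ps$recording)
  ev <- average_erfs(ep)
  energy <- colSums(ev$mmf^2)
  win <- ps$truth$mismatch_window
  inside <- ep$times >= win[1] - 1e-9 & ep$times <= win[2] + 1e-9
  expect_gt(sum(energy[inside]) / sum(energy), 0.99)
})
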