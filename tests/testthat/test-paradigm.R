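test_that("a default block has the alternating structure and exact counts", {
  b <- make_block_sequence(1, seed = 7, n_stimuli = 495)
  ev <- b$events
  expect_equal(nrow(ev), 495)
  expect_true(all(ev$category[1:15] == "standard"))
  # strict alternation after the leading standards, deviant first
  post <- ev$category[16:495]
  expect_equal(post, rep(c("deviant", "standard"), 240))
  expect_equal(sum(ev$category == "standard"), 255)
  expect_equal(sum(ev$category == "deviant"), 240)
  sub <- ev$subtype[ev$category == "deviant"]
  expect_equal(unname(table(sub)["frequency_up"]), 30)
  expect_equal(unname(table(sub)["frequency_down"]), 30)
  expect_equal(unname(table(sub)["intensity_up"]), 30)
  expect_equal(unname(table(sub)["intensity_down"]), 30)
  expect_equal(unname(table(sub)["duration"]), 60)
  expect_equal(unname(table(sub)["gap"]), 60)
  # onsets follow the SOA exactly
  expect_equal(ev$onset, (ev$index - 1) * 0.5)
  # standards carry no subtype
  expect_true(all((ev$category == "standard") == (ev$subtype == "none")))
})

test_that("deviant subtype relative frequency is exactly 0.125 per dimension", {
  b <- make_block_sequence(2, seed = 3, n_stimuli = 495)
  post <- b$events[16:495, ]
  dims <- sub("_(up|down)$", "", post$subtype[post$category == "deviant"])
  for (d in c("frequency", "intensity", "duration", "gap")) {
    expect_equal(sum(dims == d) / nrow(post), 0.125)
  }
  expect_equal(mean(post$category == "standard"), 0.5)
})

test_that("no two successive deviants share a feature dimension (many seeds)", {
  for (seed in 1:1000) {
    n <- if (seed <= 50) 495 else 95
    ev <- make_block_sequence(1, seed = seed, n_stimuli = n)$events
    dims <- sub("_(up|down)$", "", ev$subtype[ev$category == "deviant"])
    expect_equal(sum(dims[-1] == dims[-length(dims)]), 0)
  }
})

test_that("the smallest legal block is 15 standards, a deviant, a standard", {
  ev <- make_block_sequence(1, seed = 99, n_stimuli = 17)$events
  expect_equal(ev$category, c(rep("standard", 15), "deviant", "standard"))
})

test_that("infeasible block sizes are rejected", {
  expect_error(make_block_sequence(1, seed = 1, n_stimuli = 16))
  expect_error(make_block_sequence(1, seed = 1, n_stimuli = 18), "even")
})

test_that("blocks are deterministic given the seed", {
  expect_identical(make_block_sequence(1, seed = 5, n_stimuli = 495)$events,
                   make_block_sequence(1, seed = 5, n_stimuli = 495)$events)
  a <- make_block_sequence(1, seed = 5, n_stimuli = 495)$events
  b <- make_block_sequence(1, seed = 6, n_stimuli = 495)$events
  expect_false(identical(a$subtype, b$subtype))
  # category pattern is deterministic, only the subtype draw is random
  expect_identical(a$category, b$category)
})

test_that("a session concatenates three blocks with continuous onsets", {
  s <- make_session(seed = 1, order = c(1, 2, 3))
  expect_equal(nrow(s$events), 1485)
  expect_equal(s$events$onset, (seq_len(1485) - 1) * 0.5)
  # per-block counts are invariant under reordering
  s2 <- make_session(seed = 1, order = c(3, 1, 2))
  t1 <- table(s$events$block, s$events$subtype)
  t2 <- table(s2$events$block, s2$events$subtype)
  expect_equal(t1[order(rownames(t1)), ], t2[order(rownames(t2)), ])
  expect_error(make_session(seed = 1, order = c(1, 1, 2)), "permutation")
})

test_that("standard tone spans 75 ms with 5 ms ramps", {
  spec <- tone_spec()
  w <- synthesize_stimulus(spec)
  expect_equal(length(w) / spec$audio_rate * 1000, 75, tolerance = 0.02)
  env_span <- diff(range(which(abs(w) > 0))) + 1
  expect_equal(env_span / spec$audio_rate * 1000, 75, tolerance = 0.1)
})

test_that("frequency deviants move every partial by 10%", {
  spec <- tone_spec()
  peak_freqs <- function(w, k = 3) {
    n <- 2^19
    pw <- (Mod(fft(c(w, rep(0, n - length(w)))))^2)[1:(n / 2)]
    fr <- (seq_len(n / 2) - 1) * spec$audio_rate / n
    i <- 2:(length(pw) - 1)
    loc <- i[pw[i] > pw[i - 1] & pw[i] >= pw[i + 1]]
    top <- loc[order(pw[loc], decreasing = TRUE)][1:k]
    sort(fr[top])
  }
  up <- peak_freqs(synthesize_stimulus(spec, "frequency_up"))
  down <- peak_freqs(synthesize_stimulus(spec, "frequency_down"))
  expect_equal(up, c(605, 1100, 1650), tolerance = 2e-3)
  expect_equal(down, c(495, 900, 1350), tolerance = 2e-3)
})

test_that("intensity deviants scale RMS by 1.1 / 0.9 and energy by the square", {
  spec <- tone_spec()
  w <- synthesize_stimulus(spec)
  up <- synthesize_stimulus(spec, "intensity_up")
  down <- synthesize_stimulus(spec, "intensity_down")
  rms <- function(x) sqrt(mean(x^2))
  expect_equal(rms(up) / rms(w), 1.1, tolerance = 1e-6)
  expect_equal(rms(down) / rms(w), 0.9, tolerance = 1e-6)
  expect_equal(sum(up^2) / sum(w^2), 1.1^2, tolerance = 1e-9)
  expect_equal(sum(down^2) / sum(w^2), 0.9^2, tolerance = 1e-9)
})

test_that("duration deviant has 25 ms tone-on padded to the standard length", {
  spec <- tone_spec()
  w <- synthesize_stimulus(spec, "duration")
  expect_equal(length(w), length(synthesize_stimulus(spec)))
  nz <- which(abs(w) > 0)
  expect_equal((max(nz) - min(nz) + 1) / spec$audio_rate * 1000, 25,
               tolerance = 0.1)
  expect_error(synthesize_stimulus(spec, "duration", duration_on_ms = 80),
               "longer")
})

test_that("gap deviant has a 7 ms central silent span", {
  spec <- tone_spec()
  w <- synthesize_stimulus(spec, "gap")
  r <- rle(abs(w) > 0)
  silent_ms <- max(r$lengths[!r$values]) / spec$audio_rate * 1000
  expect_equal(silent_ms, 7, tolerance = 0.05)
  # the gap is centered
  ends <- cumsum(r$lengths)
  i <- which(!r$values & r$lengths == max(r$lengths[!r$values]))[1]
  center <- (ends[i] - r$lengths[i] / 2) / length(w)
  expect_equal(center, 0.5, tolerance = 0.01)
  expect_error(synthesize_stimulus(spec, "gap", gap_ms = 80), "longer")
})

test_that("tone_spec validates its invariants", {
  expect_error(tone_spec(partials = c(1000, 550)), "increasing")
  expect_error(tone_spec(partials = c(-5, 100)), "positive")
  expect_error(tone_spec(rise_fall_ms = 40), "rise")
  expect_error(synthesize_stimulus(tone_spec(), "warble"), "unrecognized")
})

test_that("events round-trip through the TSV dialect", {
  s <- make_session(seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_events_tsv(s, path)
  back <- read_events_tsv(path)
  expect_equal(back$events$onset, s$events$onset)
  expect_equal(back$events$category, s$events$category)
  expect_equal(back$events$subtype, s$events$subtype)
  unlink(path)
})
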