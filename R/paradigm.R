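#' Tone specification for the oddball stimuli
#'
#' Describes the standard tone of the multi-feature oddball paradigm: a
#' harmonic complex of equal-amplitude sinusoidal partials with linear
#' rise/fall ramps. All four deviant transforms are derived from this
#' specification by [synthesize_stimulus()].
#'
#' @param partials numeric vector of partial frequencies in Hz, strictly
#'   positive and increasing. Default `c(550, 1000, 1500)`, the harmonic
#'   complex whose 10% raised version has partials 605/1100/1650 Hz.
#' @param duration_ms total tone duration in milliseconds (default 75).
#' @param rise_fall_ms linear rise and fall ramp duration in milliseconds
#'   (default 5; both ramps must fit inside the tone).
#' @param base_amplitude linear amplitude scale; 1.0 stands for the nominal
#'   80 dB SPL presentation level.
#' @param audio_rate audio synthesis rate in Hz (default 44100; independent
#'   of the MEG sampling rate).
#' @return An object of class `tone_spec`.
#' @seealso [synthesize_stimulus()]
#' @export
#' @examples
#' spec <- tone_spec()
#' length(synthesize_stimulus(spec)) / spec$audio_rate  # 75 ms
tone_spec <- function(partials = c(550, 1000, 1500), duration_ms = 75,
                      rise_fall_ms = 5, base_amplitude = 1,
                      audio_rate = 44100) {
  stopifnot(is.numeric(partials), length(partials) >= 1)
  if (any(partials <= 0) || is.unsorted(partials, strictly = TRUE)) {
    stop("`partials` must be strictly positive and strictly increasing")
  }
  if (!(rise_fall_ms > 0 && 2 * rise_fall_ms <= duration_ms)) {
    stop("rise/fall ramps must satisfy 0 < 2 * rise_fall_ms <= duration_ms")
  }
  if (max(partials) >= audio_rate / 2) {
    stop("highest partial must lie below the audio Nyquist frequency")
  }
  structure(list(partials = partials, duration_ms = duration_ms,
                 rise_fall_ms = rise_fall_ms,
                 base_amplitude = base_amplitude, audio_rate = audio_rate),
            class = "tone_spec")
}

DEVIANT_SUBTYPES <- c("frequency_up", "frequency_down", "intensity_up",
                      "intensity_down", "duration", "gap")
FEATURE_DIMENSIONS <- c("frequency", "intensity", "duration", "gap")

subtype_dimension <- function(subtype) {
  sub("_(up|down)$", "", subtype)
}

# Split `n` items over the four feature dimensions (and up/down halves of
# frequency and intensity) as evenly as possible; exact when n %% 8 == 0.
# Remainders are assigned by seeded draw so the result is deterministic.
balanced_subtype_multiset <- function(n_dev) {
  base <- n_dev %/% 4L
  extra <- n_dev %% 4L
  dims <- FEATURE_DIMENSIONS
  counts <- stats::setNames(rep(base, 4L), dims)
  if (extra > 0L) {
    pick <- sample(dims, extra)
    counts[pick] <- counts[pick] + 1L
  }
  split_half <- function(total, up, down) {
    n_up <- total %/% 2L
    if (total %% 2L == 1L && sample(c(TRUE, FALSE), 1L)) n_up <- n_up + 1L
    c(rep(up, n_up), rep(down, total - n_up))
  }
  c(split_half(counts[["frequency"]], "frequency_up", "frequency_down"),
    split_half(counts[["intensity"]], "intensity_up", "intensity_down"),
    rep("duration", counts[["duration"]]),
    rep("gap", counts[["gap"]]))
}

# Arrange a subtype multiset so no two successive deviants share a feature
# dimension. Sequential weighted draw (probability proportional to the
# remaining count of each admissible dimension) with restart on dead ends.
arrange_no_repeat <- function(subtypes, max_attempts = 200L) {
  dims <- subtype_dimension(subtypes)
  tab <- table(factor(dims, levels = FEATURE_DIMENSIONS))
  n <- length(subtypes)
  if (max(tab) > ceiling(n / 2)) {
    stop("infeasible deviant multiset: one feature dimension exceeds half the slots")
  }
  pools <- split(subtypes, dims)
  pools <- lapply(pools, sample) # seeded shuffle of up/down order within dims
  for (attempt in seq_len(max_attempts)) {
    counts <- as.vector(tab)
    names(counts) <- FEATURE_DIMENSIONS
    out_dim <- character(n)
    prev <- ""
    ok <- TRUE
    for (i in seq_len(n)) {
      avail <- counts > 0L & names(counts) != prev
      if (!any(avail)) { ok <- FALSE; break }
      pick <- sample(names(counts)[avail], 1L,
                     prob = counts[avail] / sum(counts[avail]))
      out_dim[i] <- pick
      counts[pick] <- counts[pick] - 1L
      prev <- pick
    }
    if (ok) {
      used <- stats::setNames(rep(0L, length(pools)), names(pools))
      out <- character(n)
      for (i in seq_len(n)) {
        d <- out_dim[i]
        used[d] <- used[d] + 1L
        out[i] <- pools[[d]][used[d]]
      }
      return(out)
    }
  }
  stop("could not arrange deviant subtypes without immediate repeats")
}

#' Generate one multi-feature oddball stimulus block
#'
#' A block starts with 15 standards and then strictly alternates standard
#' and deviant tones at a fixed stimulus-onset asynchrony. Deviants are
#' drawn from four feature dimensions (frequency, intensity, duration, gap)
#' in pseudorandom order such that the same dimension never occurs on two
#' successive deviant slots; frequency deviants are split half raised /
#' half lowered and intensity deviants half louder / half softer.
#'
#' @param block block number (1-3), recorded in the event table.
#' @param seed integer seed; the sequence is deterministic given the seed.
#' @param n_stimuli number of stimuli in the block (default 495). Must be
#'   at least 17 with `n_stimuli - 15` even.
#' @param soa stimulus-onset asynchrony in seconds (default 0.5).
#' @param n_lead number of leading standards (default 15).
#' @return A `stimulus_sequence`: a list with an `events` data frame
#'   (`index`, `onset`, `category`, `subtype`, `block`), plus `block_count`,
#'   `seed` and `soa`.
#' @export
#' @examples
#' seq1 <- make_block_sequence(1, seed = 7, n_stimuli = 495)
#' table(seq1$events$category)
make_block_sequence <- function(block = 1L, seed = 1L, n_stimuli = 495L,
                                soa = 0.5, n_lead = 15L) {
  n_stimuli <- as.integer(n_stimuli)
  if (n_stimuli < n_lead + 2L) {
    stop("`n_stimuli` must allow at least one deviant after the ",
         n_lead, " leading standards")
  }
  if ((n_stimuli - n_lead) %% 2L != 0L) {
    stop("`n_stimuli - ", n_lead, "` must be even so the alternation closes ",
         "on a standard")
  }
  n_alt <- n_stimuli - n_lead
  n_dev <- n_alt %/% 2L
  subtype <- rep("none", n_stimuli)
  category <- rep("standard", n_stimuli)
  dev_pos <- n_lead + seq(1L, n_alt, by = 2L) # deviant-first alternation
  category[dev_pos] <- "deviant"
  sub_seq <- with_seed(seed + block, {
    arrange_no_repeat(balanced_subtype_multiset(n_dev))
  })
  subtype[dev_pos] <- sub_seq
  events <- data.frame(
    index = seq_len(n_stimuli),
    onset = (seq_len(n_stimuli) - 1) * soa,
    category = category,
    subtype = subtype,
    block = as.integer(block),
    stringsAsFactors = FALSE
  )
  structure(list(events = events, block_count = 1L, seed = as.integer(seed),
                 soa = soa),
            class = "stimulus_sequence")
}

#' Generate a full oddball session (three blocks)
#'
#' Concatenates three blocks in the given order with continuous onsets.
#' Block content depends on the block identity (not its position), so
#' counterbalancing the order across participants permutes whole blocks.
#'
#' @param seed integer master seed; per-block seeds are derived from it.
#' @param order permutation of `1:3` giving the block presentation order.
#' @param n_stimuli stimuli per block (default 495).
#' @param soa stimulus-onset asynchrony in seconds (default 0.5).
#' @param interblock_gap silence between blocks in seconds (default 0).
#' @return A `stimulus_sequence` whose `events` contain all blocks; the
#'   extra column `session_index` numbers events across the session.
#' @export
make_session <- function(seed = 1L, order = c(1L, 2L, 3L), n_stimuli = 495L,
                         soa = 0.5, interblock_gap = 0) {
  if (!identical(sort(as.integer(order)), 1:3)) {
    stop("`order` must be a permutation of 1:3")
  }
  block_seeds <- derive_seeds(seed, 3L)
  offset <- 0
  parts <- vector("list", 3L)
  for (k in seq_along(order)) {
    b <- as.integer(order[k])
    blk <- make_block_sequence(b, seed = block_seeds[b],
                               n_stimuli = n_stimuli, soa = soa)
    ev <- blk$events
    ev$onset <- ev$onset + offset
    parts[[k]] <- ev
    offset <- offset + n_stimuli * soa + interblock_gap
  }
  events <- do.call(rbind, parts)
  events$session_index <- seq_len(nrow(events))
  rownames(events) <- NULL
  structure(list(events = events, block_count = 3L, seed = as.integer(seed),
                 soa = soa, order = as.integer(order)),
            class = "stimulus_sequence")
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  ev <- x$events
  cat("<stimulus_sequence>", nrow(ev), "events,",
      x$block_count, "block(s), SOA", x$soa, "s\n")
  tab <- table(ev$subtype[ev$category == "deviant"])
  cat("  standards:", sum(ev$category == "standard"),
      " deviants:", sum(ev$category == "deviant"), "\n")
  if (length(tab)) {
    cat("  deviant subtypes:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

linear_ramp_envelope <- function(n, ramp_samples) {
  i <- seq_len(n)
  pmin(1, i / ramp_samples, (n - i + 1) / ramp_samples)
}

#' Synthesize a stimulus waveform
#'
#' Builds the standard tone (sum of equal-amplitude sinusoidal partials
#' with linear rise/fall ramps) or one of the four deviant transforms:
#' frequency deviants scale every partial by 1.1 or 0.9; intensity
#' deviants scale the amplitude by 1.1 or 0.9; the duration deviant
#' truncates the tone-on time to 25 ms (ramps preserved) and pads with
#' silence to the standard length; the gap deviant silences 7 ms at the
#' waveform midpoint, flanked by 1 ms fall and rise ramps.
#'
#' @param spec a [tone_spec()].
#' @param subtype `"none"` for the standard, or one of `"frequency_up"`,
#'   `"frequency_down"`, `"intensity_up"`, `"intensity_down"`,
#'   `"duration"`, `"gap"`.
#' @param peak_normalize if `TRUE`, rescale the result to unit peak.
#' @param duration_on_ms tone-on time of the duration deviant (default 25).
#' @param gap_ms silent span of the gap deviant (default 7).
#' @param gap_ramp_ms fall/rise ramp flanking the gap (default 1).
#' @return Numeric vector of mono audio samples at `spec$audio_rate`.
#' @export
#' @examples
#' w <- synthesize_stimulus(tone_spec(), "intensity_up")
synthesize_stimulus <- function(spec, subtype = "none",
                                peak_normalize = FALSE,
                                duration_on_ms = 25, gap_ms = 7,
                                gap_ramp_ms = 1) {
  stopifnot(inherits(spec, "tone_spec"))
  if (!subtype %in% c("none", DEVIANT_SUBTYPES)) {
    stop("unrecognized stimulus subtype: ", subtype)
  }
  fs <- spec$audio_rate
  n <- round(spec$duration_ms / 1000 * fs)
  ramp <- round(spec$rise_fall_ms / 1000 * fs)
  freqs <- spec$partials
  amp <- spec$base_amplitude
  if (subtype == "frequency_up") freqs <- freqs * 1.1
  if (subtype == "frequency_down") freqs <- freqs * 0.9
  if (subtype == "intensity_up") amp <- amp * 1.1
  if (subtype == "intensity_down") amp <- amp * 0.9

  tone_samples <- n
  if (subtype == "duration") {
    if (duration_on_ms > spec$duration_ms) {
      stop("duration deviant cannot be longer than the standard tone")
    }
    tone_samples <- round(duration_on_ms / 1000 * fs)
    if (2 * ramp > tone_samples) {
      stop("rise/fall ramps do not fit inside the truncated tone")
    }
  }
  t <- (seq_len(tone_samples) - 1) / fs
  carrier <- rowSums(sapply(freqs, function(f) sin(2 * pi * f * t)))
  env <- linear_ramp_envelope(tone_samples, ramp)

  if (subtype == "gap") {
    g <- round(gap_ms / 1000 * fs)
    rg <- round(gap_ramp_ms / 1000 * fs)
    if (g + 2 * rg >= tone_samples) stop("gap is longer than the tone")
    gstart <- floor((tone_samples - g) / 2) + 1L
    gidx <- gstart:(gstart + g - 1L)
    env[gidx] <- 0
    # ramps flank the silent span and stay strictly positive outside it
    fall <- gstart - rev(seq_len(rg))
    rise <- gstart + g - 1L + seq_len(rg)
    env[fall] <- env[fall] * (1 - seq_len(rg) / (rg + 1))
    env[rise] <- env[rise] * (seq_len(rg) / (rg + 1))
  }

  w <- amp / length(freqs) * env * carrier
  if (subtype == "duration") w <- c(w, rep(0, n - tone_samples))
  if (peak_normalize && max(abs(w)) > 0) w <- w / max(abs(w))
  w
}

#' Write a stimulus sequence as a tab-separated events file
#'
#' Columns `onset`, `duration`, `block`, `category`, `subtype` (a
#' BIDS-events-like dialect); onsets in seconds.
#'
#' @param x a `stimulus_sequence`.
#' @param path output file path.
#' @param stimulus_duration stimulus duration written to the `duration`
#'   column, seconds (default 0.075).
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(x, path, stimulus_duration = 0.075) {
  stopifnot(inherits(x, "stimulus_sequence"))
  ev <- x$events
  out <- data.frame(onset = ev$onset, duration = stimulus_duration,
                    block = ev$block, category = ev$category,
                    subtype = ev$subtype)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an events file written by [write_events_tsv()]
#' @param path file path.
#' @param soa stimulus-onset asynchrony of the paradigm (default 0.5 s).
#' @return A `stimulus_sequence`.
#' @export
read_events_tsv <- function(path, soa = 0.5) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  blocks <- unique(ev$block)
  events <- data.frame(
    index = unlist(lapply(blocks, function(b) seq_len(sum(ev$block == b)))),
    onset = ev$onset, category = ev$category, subtype = ev$subtype,
    block = ev$block, stringsAsFactors = FALSE)
  events$session_index <- seq_len(nrow(events))
  structure(list(events = events, block_count = length(blocks), seed = NA,
                 soa = soa),
            class = "stimulus_sequence")
}
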