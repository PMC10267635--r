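# Shared small fixtures, built once per test run.

vnorm_test <- function(x, ref) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  sqrt(rowSums(sweep(x, 2, ref)^2))
}

tangential_basis_test <- function(pos) mmfpipe:::tangential_basis(pos)

unit <- function(x) x / sqrt(sum(x^2))

tiny_array <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_sensor_array(32)
    val
  }
})

default_grid <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_source_grid()
    val
  }
})

# A fast simulation configuration: one short block, 250 Hz, 32 channels.
fast_sim_config <- function(...) {
  sim_config(n_blocks = 1L, n_stimuli = 47L, sampling_rate = 250,
             n_channels = 32L, ...)
}

# Epoch set built directly from a deterministic array (no simulation),
# for unit tests of EMS / rejection / averaging.
epochs_from_array <- function(data, labels, sfreq = 250,
                              tmin = -0.1, array = tiny_array()) {
  stopifnot(length(dim(data)) == 3L, dim(data)[1] == length(labels))
  structure(list(
    data = data, labels = labels,
    subtype = ifelse(labels == "deviant", "frequency_up", "none"),
    times = tmin + (seq_len(dim(data)[3]) - 1) / sfreq,
    sfreq = sfreq, array = array, participant = NA,
    log = list(n_input = length(labels), n_dropped_first = 0L,
               n_dropped_oob = 0L, n_kept = length(labels),
               n_dropped_artifact = 0L, interpolated = character(0))
  ), class = "epoch_set")
}

# Random epochs with a condition effect injected on given samples.
random_epochs <- function(n_std = 20, n_dev = 20, n_ch = 8, n_t = 50,
                          effect = 0, effect_idx = integer(0), sd = 1,
                          seed = 1) {
  set.seed(seed)
  n <- n_std + n_dev
  data <- array(rnorm(n * n_ch * n_t, 0, sd), dim = c(n, n_ch, n_t))
  labels <- c(rep("standard", n_std), rep("deviant", n_dev))
  if (effect != 0 && length(effect_idx)) {
    pattern <- rnorm(n_ch)
    pattern <- pattern / sqrt(sum(pattern^2))
    for (e in which(labels == "deviant")) {
      data[e, , effect_idx] <- data[e, , effect_idx] + effect * pattern
    }
  }
  epochs_from_array(data, labels, array = make_sensor_array(n_ch))
}
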