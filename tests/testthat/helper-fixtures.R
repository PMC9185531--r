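# Shared fixtures. Everything is generated in code; expensive objects are
# memoized so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# Small drift-enabled simulated dataset: 5 classes x 12 records, 3 cycles.
small_sim <- function() {
  memo("small_sim", simulate_beat_signals(radar_config(
    records_per_class = 12L, antennas = 1L, n_power_cycles = 3L, seed = 101L
  )))
}

# Clean (noiseless, drift-free) reference record at a given concentration.
clean_record <- function(conc = 0.91) {
  cfg <- radar_config(records_per_class = 1L, antennas = 1L, drift = FALSE,
                      snr_db = Inf, concentrations = conc)
  simulate_beat_signals(cfg)$signal[[1]]
}

# Noisy record sharing the clean record's deterministic tone.
noisy_record <- function(conc = 0.91, seed = 1L, snr_db = 20) {
  cfg <- radar_config(records_per_class = 1L, antennas = 1L, drift = FALSE,
                      snr_db = snr_db, concentrations = conc, seed = seed)
  simulate_beat_signals(cfg)$signal[[1]]
}

# Tiny linearly separable 2-class tensor problem: class means differ along a
# fixed random direction, noise well below the separation.
toy_tensors <- function(n_per_class = 12L, dims = c(6L, 12L, 4L),
                        seed = 7L) {
  withr::with_seed(seed, {
    base <- array(rnorm(prod(dims)), dim = dims)
    delta <- array(rnorm(prod(dims), sd = 0.5), dim = dims)
    tensors <- list()
    labels <- character(0)
    for (cls in 1:2) {
      for (i in seq_len(n_per_class)) {
        noise <- array(rnorm(prod(dims), sd = 0.05), dim = dims)
        tensors[[length(tensors) + 1L]] <-
          base + (if (cls == 2) delta else -delta) + noise
        labels <- c(labels, as.character(cls))
      }
    }
    list(tensors = tensors, labels = labels)
  })
}

rmse <- function(a, b) sqrt(mean(Mod(a - b)^2))
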