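# Synthetic FMCW beat-signal generator. After dechirping, a static target at
# fixed range contributes a single low-frequency complex tone; its amplitude
# carries the dielectric signature of the solution through echo_amplitude().
# The generator adds the two nuisances the analysis chain has to survive:
# high-band thermal noise and a per-power-cycle gain/offset drift.

#' Simulation run configuration
#'
#' Bundles every knob of the synthetic acquisition in one list, mirroring the
#' config file consumed by the command-line wrapper. Defaults are the
#' package's reference bench: N = 64 samples per record, 77 GHz carrier,
#' 1.3 mm solution cell, beat tone at bin 3 (lowest eighth of the band),
#' 20 dB SNR thermal noise confined to the upper half of the Nyquist band,
#' and a lognormal per-power-cycle gain drift (sdlog 0.01) plus a complex DC
#' offset (sd 0.08 per part, the receiver's session-dependent LO-leakage
#' level).
#'
#' @param n_samples Record length N.
#' @param carrier_hz Carrier frequency (Hz).
#' @param thickness_m One-way solution path (m).
#' @param dielectric Named list `a0, a1, b0, b1` for [dielectric_law()].
#' @param beat_bin Beat-tone DFT bin (cycles per record).
#' @param snr_db Signal-to-noise ratio of the thermal noise in dB
#'   (`Inf` disables noise).
#' @param drift Logical, enable power-cycle drift.
#' @param drift_sigma Lognormal sdlog of the multiplicative gain drift.
#' @param drift_offset_sd Standard deviation of the additive complex DC
#'   offset (per real/imaginary part).
#' @param concentrations Concentration grid (mg/mL); defaults to the five
#'   calibration solutions.
#' @param records_per_class Records generated per concentration.
#' @param n_power_cycles Number of simulated power-on sessions.
#' @param antennas Transmit-antenna ids to emit per acquisition.
#' @param antenna_gains Fixed relative gains of the three Tx chains.
#' @param seed Base RNG seed for the run.
#' @return A named list of class `radar_config`.
#' @export
radar_config <- function(n_samples = 64L,
                         carrier_hz = 77e9,
                         thickness_m = 1.3e-3,
                         dielectric = list(a0 = 6, a1 = 2, b0 = 0.35, b1 = 0.16),
                         beat_bin = 3L,
                         snr_db = 20,
                         drift = TRUE,
                         drift_sigma = 0.01,
                         drift_offset_sd = 0.08,
                         concentrations = c(0.69, 0.81, 0.91, 1.03, 1.08),
                         records_per_class = 200L,
                         n_power_cycles = 10L,
                         antennas = 1:3,
                         antenna_gains = c(1, 0.97, 1.03),
                         seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), carrier_hz = carrier_hz,
    thickness_m = thickness_m, dielectric = dielectric,
    beat_bin = as.integer(beat_bin), snr_db = snr_db, drift = drift,
    drift_sigma = drift_sigma, drift_offset_sd = drift_offset_sd,
    concentrations = concentrations,
    records_per_class = as.integer(records_per_class),
    n_power_cycles = as.integer(n_power_cycles),
    antennas = as.integer(antennas), antenna_gains = antenna_gains,
    seed = seed
  )
  if (cfg$n_samples < 8L) abort("`n_samples` must be at least 8")
  if (any(!cfg$antennas %in% 1:3)) abort("`antennas` must be a subset of 1:3")
  structure(cfg, class = "radar_config")
}

#' Read a simulation configuration from JSON or YAML
#'
#' Unknown keys are rejected; missing keys fall back to [radar_config()]
#' defaults.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file. Keys may be nested
#'   under a top-level `simulate` entry.
#' @return A `radar_config`.
#' @export
read_radar_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$simulate)) raw <- raw$simulate
  known <- names(formals(radar_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(paste0("unknown config keys: ", paste(extra, collapse = ", ")))
  }
  do.call(radar_config, raw)
}

# Gain/offset drift of one power-on session, drawn once per power_cycle_id:
# deterministic in (seed, power_cycle_id) so every record of a session sees
# the same working status.
power_cycle_drift <- function(power_cycle_id, seed, sigma_gain, offset_sd) {
  with_seed_or_not(derive_seed(seed, 1e6 + power_cycle_id), {
    list(
      gain = exp(rnorm(1, 0, sigma_gain)),
      offset = complex(
        real = rnorm(1, 0, offset_sd),
        imaginary = rnorm(1, 0, offset_sd)
      )
    )
  })
}

# Complex white Gaussian noise restricted to the upper half of the Nyquist
# band (normalized |f| >= 0.25), scaled so its expected variance is `power`.
highband_noise <- function(n, power) {
  z <- complex(real = rnorm(n), imaginary = rnorm(n)) / sqrt(2)
  f <- (seq_len(n) - 1) / n
  f <- ifelse(f > 0.5, f - 1, f)
  keep <- abs(f) >= 0.25
  zf <- fft(z)
  zf[!keep] <- 0
  z <- fft(zf, inverse = TRUE) / n
  # zeroing bins removes a known fraction of the unit variance
  z * sqrt(power / mean(keep))
}

#' Synthesize one complex beat-signal record
#'
#' Produces the length-`n_samples` dechirped tone
#' `x(n) = g A(c) exp(i 2 pi k0 (n-1) / N) + offset + noise`, where `A(c)` is
#' the concentration-dependent [echo_amplitude()], `g` collects the antenna
#' gain and the session's multiplicative drift, `offset` is the session's DC
#' drift, and the noise term is complex white Gaussian band-limited to the
#' upper half of the Nyquist band at the configured SNR (relative to the
#' deterministic tone power).
#'
#' @param conc Glucose concentration (mg/mL).
#' @param config A [radar_config()].
#' @param power_cycle_id Integer id of the simulated power-on session.
#' @param antenna_id Transmit antenna (1, 2 or 3).
#' @param seed RNG seed for the record's noise (the drift draw is keyed by
#'   `config$seed` and `power_cycle_id` only).
#' @return Complex vector of length `config$n_samples` with attributes
#'   `concentration`, `antenna_id`, `power_cycle_id`.
#' @export
synthesize_beat_signal <- function(conc, config = radar_config(),
                                   power_cycle_id = 1L, antenna_id = 1L,
                                   seed = 1L) {
  n <- config$n_samples
  snr_lin <- 10^(config$snr_db / 10)
  if (is.na(snr_lin) || snr_lin <= 0) {
    abort("SNR must be positive on the linear scale")
  }
  law <- do.call(dielectric_law, config$dielectric)
  geom <- scene_geometry(
    solution_thickness = config$thickness_m,
    carrier_hz = config$carrier_hz
  )
  amp <- echo_amplitude(conc, geom, law) * config$antenna_gains[antenna_id]
  dr <- if (isTRUE(config$drift)) {
    power_cycle_drift(power_cycle_id, config$seed, config$drift_sigma,
                      config$drift_offset_sd)
  } else {
    list(gain = 1, offset = 0 + 0i)
  }
  tone <- amp * dr$gain * exp(2i * pi * config$beat_bin * (seq_len(n) - 1) / n)
  noise <- if (is.infinite(config$snr_db)) {
    rep(0 + 0i, n)
  } else {
    with_seed_or_not(seed, highband_noise(n, mean(Mod(tone)^2) / snr_lin))
  }
  x <- tone + dr$offset + noise
  attributes(x) <- list(
    concentration = conc, antenna_id = as.integer(antenna_id),
    power_cycle_id = as.integer(power_cycle_id)
  )
  x
}

#' Simulate a labelled beat-signal dataset
#'
#' Generates `records_per_class` acquisitions for every concentration in the
#' configuration, spread round-robin over the configured power-on sessions,
#' and emits one row per (acquisition, antenna). Fully reproducible from
#' `config$seed`.
#'
#' @param config A [radar_config()].
#' @return A tibble with columns `record_id`, `antenna_id`, `power_cycle_id`,
#'   `concentration` and the list-column `signal` (complex vectors of length
#'   `config$n_samples`).
#' @examples
#' sims <- simulate_beat_signals(radar_config(records_per_class = 2L))
#' dplyr::count(sims, concentration)
#' @export
simulate_beat_signals <- function(config = radar_config()) {
  grid <- tidyr::expand_grid(
    concentration = config$concentrations,
    replicate = seq_len(config$records_per_class)
  )
  n_acq <- nrow(grid)
  grid$acquisition <- seq_len(n_acq)
  # round-robin session assignment within class, shuffled reproducibly
  grid$power_cycle_id <- with_seed_or_not(
    derive_seed(config$seed, 2),
    as.integer(sample(rep_len(seq_len(config$n_power_cycles), n_acq)))
  )
  out <- tidyr::expand_grid(grid, antenna_id = config$antennas)
  out$record_id <- seq_len(nrow(out))
  out$signal <- purrr::pmap(
    list(out$concentration, out$power_cycle_id, out$antenna_id, out$acquisition),
    function(conc, cyc, ant, acq) {
      synthesize_beat_signal(
        conc, config,
        power_cycle_id = cyc, antenna_id = ant,
        seed = derive_seed(config$seed, acq * 4L + ant)
      )
    }
  )
  tibble::as_tibble(out[, c("record_id", "antenna_id", "power_cycle_id",
                            "concentration", "signal")])
}

#' Write and read beat-signal datasets as CSV
#'
#' One row per complex sample, columns `antenna_id`, `sample_index`, `I`, `Q`,
#' `concentration`, `power_cycle_id` plus `record_id` to keep replicate
#' records distinct. The reader checks the dialect strictly and re-nests one
#' complex vector per record.
#'
#' @param signals Tibble as returned by [simulate_beat_signals()].
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); the nested tibble (reader).
#' @export
write_beat_csv <- function(signals, path) {
  long <- tidyr::unnest(
    dplyr::mutate(
      signals,
      sample_index = purrr::map(.data$signal, seq_along),
      I = purrr::map(.data$signal, Re),
      Q = purrr::map(.data$signal, Im),
      signal = NULL
    ),
    cols = c("sample_index", "I", "Q")
  )
  readr::write_csv(
    long[, c("record_id", "antenna_id", "sample_index", "I", "Q",
             "concentration", "power_cycle_id")],
    path
  )
  invisible(path)
}

#' @rdname write_beat_csv
#' @export
read_beat_csv <- function(path) {
  long <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("antenna_id", "sample_index", "I", "Q", "concentration",
                "power_cycle_id")
  missing <- setdiff(required, names(long))
  if (length(missing)) {
    abort(paste0("malformed beat CSV, missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (!"record_id" %in% names(long)) {
    long$record_id <- cumsum(long$sample_index == 1L)
  }
  nested <- long |>
    dplyr::arrange(.data$record_id, .data$sample_index) |>
    dplyr::group_by(.data$record_id, .data$antenna_id, .data$power_cycle_id,
                    .data$concentration) |>
    dplyr::summarise(
      signal = list(complex(real = .data$I, imaginary = .data$Q)),
      .groups = "drop"
    )
  nested[order(nested$record_id), ]
}
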