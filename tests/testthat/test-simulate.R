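# Beat-signal generator: record geometry, determinism, noise statistics,
# drift structure, CSV and config round trips.

test_that("records have the configured length and metadata", {
  sims <- small_sim()
  expect_true(all(lengths(sims$signal) == 64L))
  expect_true(is.complex(sims$signal[[1]]))
  expect_equal(nrow(sims), 5L * 12L)
  expect_setequal(unique(sims$concentration),
                  c(0.69, 0.81, 0.91, 1.03, 1.08))
  # every power cycle sees every class (round-robin assignment)
  tab <- table(sims$power_cycle_id, sims$concentration)
  expect_true(all(tab > 0))
})

test_that("the noiseless drift-free record is the deterministic tone", {
  x <- clean_record(0.81)
  amp <- echo_amplitude(0.81)
  tone <- amp * exp(2i * pi * 3 * (0:63) / 64)
  expect_equal(x, tone, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("generation is bitwise reproducible from the seed", {
  cfg <- radar_config(records_per_class = 3L, seed = 55L)
  expect_identical(simulate_beat_signals(cfg), simulate_beat_signals(cfg))
  a <- synthesize_beat_signal(0.91, cfg, power_cycle_id = 2L, seed = 9L)
  b <- synthesize_beat_signal(0.91, cfg, power_cycle_id = 2L, seed = 9L)
  expect_identical(a, b)
  c2 <- synthesize_beat_signal(0.91, cfg, power_cycle_id = 2L, seed = 10L)
  expect_false(identical(a, c2))
})

test_that("thermal noise hits the configured variance and band", {
  cfg <- radar_config(drift = FALSE, snr_db = 20)
  tone_power <- mean(Mod(clean_record(0.91))^2)
  target <- tone_power / 100
  noise_var <- vapply(1:100, function(s) {
    x <- synthesize_beat_signal(0.91, cfg, seed = s)
    n <- x - clean_record(0.91)
    mean(Mod(n)^2)
  }, numeric(1))
  expect_lt(abs(mean(noise_var) - target) / target, 0.2)
  # band check: noise energy concentrated at |f| >= 0.25
  x <- synthesize_beat_signal(0.91, cfg, seed = 1)
  n <- x - clean_record(0.91)
  spec <- Mod(fft(as.vector(n)))^2
  f <- (0:63) / 64
  f <- ifelse(f > 0.5, f - 1, f)
  expect_gt(sum(spec[abs(f) >= 0.25]) / sum(spec), 0.999)
  expect_error(
    synthesize_beat_signal(0.91, radar_config(snr_db = NA)),
    "SNR"
  )
})

test_that("noiseless, drift-disabled samples sit exactly on the tone", {
  cfg <- radar_config(drift = FALSE, snr_db = Inf)
  x <- synthesize_beat_signal(0.69, cfg, seed = 3)
  tone <- echo_amplitude(0.69) * exp(2i * pi * 3 * (0:63) / 64)
  expect_equal(as.vector(x), tone, tolerance = 1e-12)
})

test_that("power-cycle drift shifts the energy line but keeps the order", {
  cfg <- radar_config(records_per_class = 10L, antennas = 1L,
                      n_power_cycles = 2L, snr_db = Inf, seed = 77L)
  fe <- spectral_features(simulate_beat_signals(cfg))
  by_cycle <- split(fe, fe$power_cycle_id)
  fits <- lapply(by_cycle, energy_calibration)
  # different sessions, different lines
  expect_false(isTRUE(all.equal(fits[[1]]$slope, fits[[2]]$slope,
                                tolerance = 1e-6)))
  # but identical class ordering inside each session
  for (df in by_cycle) {
    m <- tapply(df$total_energy, df$concentration, mean)
    expect_true(all(diff(m) > 0))
  }
})

test_that("mean spectral energy increases strictly with concentration", {
  cfg <- radar_config(records_per_class = 20L, antennas = 1L,
                      n_power_cycles = 1L, seed = 42L)
  fe <- spectral_features(simulate_beat_signals(cfg))
  m <- tapply(fe$total_energy, fe$concentration, mean)
  expect_true(all(diff(m) > 0))
})

test_that("beat CSV and config files round-trip", {
  sims <- small_sim()[1:6, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_beat_csv(sims, path)
  back <- read_beat_csv(path)
  expect_equal(nrow(back), 6L)
  for (i in 1:6) {
    expect_equal(back$signal[[i]], as.vector(sims$signal[[i]]),
                 tolerance = 1e-12)
  }
  expect_equal(back$concentration, sims$concentration)
  # strict dialect: missing column rejected
  broken <- readr::read_csv(path, show_col_types = FALSE)
  broken$I <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(broken, path2)
  expect_error(read_beat_csv(path2), "missing columns: I")

  cfg <- radar_config(records_per_class = 7L, snr_db = 14)
  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(simulate = list(records_per_class = 7, snr_db = 14)),
    jpath, auto_unbox = TRUE
  )
  cfg2 <- read_radar_config(jpath)
  expect_equal(cfg2$records_per_class, 7L)
  expect_equal(cfg2$snr_db, 14)
  ypath <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("simulate:", "  n_samples: 32", "  beat_bin: 2"), ypath)
  expect_equal(read_radar_config(ypath)$n_samples, 32L)
  writeLines(c("simulate:", "  bogus_key: 1"), ypath)
  expect_error(read_radar_config(ypath), "unknown config keys")
})
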