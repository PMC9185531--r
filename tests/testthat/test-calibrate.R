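# Least-squares calibration, concentration extrapolation and the
# power-cycle drift diagnostic.

test_that("linear_fit recovers exact lines and matches lm()", {
  fit <- linear_fit(c(0, 1, 2, 3), 2 * c(0, 1, 2, 3) + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$intercept, fit$y_mean - fit$slope * fit$x_mean,
               tolerance = 1e-9)

  withr::with_seed(4, {
    xs <- runif(5, 0.5, 1.5)
    ys <- 300 * xs + 40 + rnorm(5, sd = 5)
    fit <- linear_fit(xs, ys)
    # independent oracle: stats::lm via the normal equations
    ref <- coef(lm(ys ~ xs))
    expect_equal(fit$intercept, unname(ref[1]), tolerance = 1e-9)
    expect_equal(fit$slope, unname(ref[2]), tolerance = 1e-9)
    # brute-force grid refinement around the optimum cannot do better
    rss <- function(k, b) sum((ys - k * xs - b)^2)
    ks <- fit$slope + seq(-1, 1, length.out = 41)
    bs <- fit$intercept + seq(-1, 1, length.out = 41)
    grid_best <- min(outer(ks, bs, Vectorize(rss)))
    expect_gte(grid_best, rss(fit$slope, fit$intercept) - 1e-9)
    # affine equivariance
    fit2 <- linear_fit(xs, ys + 11)
    expect_equal(fit2$slope, fit$slope, tolerance = 1e-12)
    expect_equal(fit2$intercept, fit$intercept + 11, tolerance = 1e-9)
  })
  expect_error(linear_fit(c(1, 1, 1), c(1, 2, 3)), "degenerate")
})

test_that("tidy and glance expose the fit", {
  fit <- linear_fit(c(1, 2, 3), c(3, 5, 7))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "slope"], 2)
  expect_equal(glance(fit)$r.squared, 1)
})

test_that("predict_concentration inverts the calibration line", {
  fit <- linear_fit(c(0.69, 0.81, 0.91, 1.03, 1.08),
                    500 * c(0.69, 0.81, 0.91, 1.03, 1.08) + 120)
  expect_equal(predict_concentration(500 * 0.91 + 120, fit), 0.91,
               tolerance = 1e-12)
  expect_equal(predict_concentration(fit$intercept, fit), 0)
  withr::with_seed(5, {
    cs <- runif(100, 0.5, 1.5)
    back <- predict_concentration(fit$slope * cs + fit$intercept, fit)
    expect_lt(max(abs(back - cs)), 1e-9)
  })
  degenerate <- linear_fit(c(1, 2), c(3, 3))
  expect_error(predict_concentration(5, degenerate), "zero slope")
})

test_that("noiseless single-cycle calibration predicts held-out classes", {
  cfg <- radar_config(records_per_class = 1L, antennas = 1L, drift = FALSE,
                      snr_db = Inf)
  fe <- spectral_features(simulate_beat_signals(cfg))
  held_out <- fe$concentration == 0.91
  fit <- energy_calibration(fe[!held_out, ])
  pred <- predict_concentration(fe$total_energy[held_out], fit)
  expect_lt(abs(pred - 0.91), 0.02)
})

test_that("drift report flags cross-session transfer, not the control", {
  # drift disabled: the two sessions are statistically identical
  cfg0 <- radar_config(records_per_class = 20L, antennas = 1L,
                       n_power_cycles = 2L, drift = FALSE, seed = 31L)
  fe0 <- spectral_features(simulate_beat_signals(cfg0))
  rep0 <- drift_report(fe0, 1L, 2L)
  expect_lt(abs(rep0$delta_slope) / rep0$slope_a, 0.02)
  # identical inputs in both sessions: exactly zero deltas
  fe_same <- fe0
  fe_same$power_cycle_id <- rep(1:2, length.out = nrow(fe_same))
  half <- fe_same[fe_same$power_cycle_id == 1L, ]
  both <- rbind(half, transform(half, power_cycle_id = 2L))
  rep_same <- drift_report(both, 1L, 2L)
  expect_equal(rep_same$delta_slope, 0)
  expect_equal(rep_same$delta_intercept, 0)
  # drift enabled: applying session A's line to session B inflates the error
  cfg1 <- radar_config(records_per_class = 30L, antennas = 1L,
                       n_power_cycles = 20L, seed = 32L)
  fe1 <- spectral_features(simulate_beat_signals(cfg1))
  reps <- lapply(1:10, function(s) drift_report(fe1, 2L * s - 1L, 2L * s))
  reps <- dplyr::bind_rows(reps)
  expect_gt(mean(reps$mae_cross_ab), mean(reps$mae_within_b))
})
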