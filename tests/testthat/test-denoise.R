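# EMD sifting and the zero-crossing rejection rule; db10 wavelet shrinkage;
# complex-signal plumbing.

test_that("zero crossings count sign changes with explicit zero handling", {
  expect_equal(zero_crossing_count(rep(2, 10)), 0L)
  expect_equal(zero_crossing_count(rep(0, 10)), 0L)
  # a zero between opposite signs contributes exactly one crossing
  expect_equal(zero_crossing_count(c(1, 0, -1)), 1L)
  expect_equal(zero_crossing_count(c(1, 0, 1)), 0L)
  # sine over m full periods, densely sampled past the last zero: 2m
  # crossings
  for (m in c(2, 5)) {
    t <- seq(1 / 1024, m + 0.2, by = 1 / 512)
    expect_equal(zero_crossing_count(sin(2 * pi * t)), 2L * m)
  }
  x <- rnorm(100)
  expect_equal(zero_crossing_count(x), zero_crossing_count(-x))
})

test_that("EMD reconstructs exactly and separates well-spaced tones", {
  n <- 0:127
  # strictly monotone input: nothing to sift
  dec0 <- emd_decompose(seq(0, 1, length.out = 64))
  expect_length(dec0$imfs, 0L)
  expect_equal(dec0$residual, seq(0, 1, length.out = 64))

  fast <- 0.4 * sin(2 * pi * 30 * n / 128 + 0.6)
  slow <- sin(2 * pi * 3 * n / 128)
  dec <- emd_decompose(slow + fast)
  expect_gt(length(dec$imfs), 0L)
  expect_gt(cor(dec$imfs[[1]], fast), 0.9)
  recon <- Reduce(`+`, dec$imfs, dec$residual)
  expect_equal(recon, slow + fast, tolerance = 1e-8)
  # IMF criterion: extrema and zero-crossing counts differ by at most 1
  imf1 <- dec$imfs[[1]]
  ext <- glucoradar:::local_extrema(imf1)
  n_ext <- length(ext$max) + length(ext$min)
  expect_lte(abs(n_ext - zero_crossing_count(imf1)), 1L)
})

test_that("the rejection rule removes exactly the components with fi >= 3 f0", {
  f0 <- 5L
  # alternating-block components with exact zero-crossing counts:
  # b blocks of constant sign give b - 1 crossings
  block_wave <- function(blocks, len = 64L) {
    signs <- rep(c(1, -1), length.out = blocks)
    sizes <- diff(round(seq(0, len, length.out = blocks + 1)))
    rep(signs, times = sizes)
  }
  imfs <- list(block_wave(21), block_wave(16), block_wave(15))
  fi <- vapply(imfs, zero_crossing_count, integer(1))
  expect_equal(fi, c(20L, 15L, 14L))  # above, exactly 3 f0, below
  dec <- structure(
    list(imfs = imfs, residual = rep(0, 64), source_length = 64L),
    class = "emd_decomposition"
  )
  out <- classify_and_filter(dec, f0)
  # the 20- and 15-crossing components go; the 14-crossing one stays
  expect_equal(out, imfs[[3]], tolerance = 1e-12)
  labels <- imf_frequency_labels(dec, f0)
  expect_equal(labels$label, c("high", "high", "low"))
  # nothing removed when every fi < 3 f0
  expect_equal(classify_and_filter(dec, 7L),
               imfs[[1]] + imfs[[2]] + imfs[[3]])
})

test_that("wavelet bank reconstructs perfectly at several lengths", {
  withr::with_seed(11, {
    for (spec in list(c(64, 3), c(96, 3), c(50, 2))) {
      x <- rnorm(spec[1])
      dec <- wavelet_decompose(x, "db10", spec[2])
      expect_equal(wavelet_reconstruct(dec), x, tolerance = 1e-10)
      expect_equal(dwt_denoise(x, threshold = 0), x, tolerance = 1e-8)
      dec4 <- wavelet_decompose(x, "db4", spec[2])
      expect_equal(wavelet_reconstruct(dec4), x, tolerance = 1e-10)
    }
  })
  expect_equal(dwt_denoise(rep(0, 64)), rep(0, 64))
  expect_error(wavelet_decompose(rnorm(4)), "too short")
  expect_error(wavelet_filters("sym8"), "unknown wavelet")
})

test_that("db10 shrinkage beats the raw signal on a white-noise tone", {
  n <- 0:63
  clean <- cos(2 * pi * 3 * n / 64)
  errs <- withr::with_seed(21, {
    vapply(1:20, function(i) {
      noisy <- clean + rnorm(64, sd = 0.3)
      c(raw = sqrt(mean((noisy - clean)^2)),
        dwt = sqrt(mean((dwt_denoise(noisy) - clean)^2)))
    }, numeric(2))
  })
  expect_lt(mean(errs["dwt", ]), mean(errs["raw", ]))
})

test_that("complex denoising is part-wise and symmetric", {
  x <- noisy_record(seed = 5)
  for (method in c("dwt", "emd")) {
    y <- denoise_complex(x, method)
    expect_length(y, length(x))
    # matches applying the real path twice explicitly
    expect_equal(y, complex(
      real = if (method == "dwt") dwt_denoise(Re(x)) else emd_denoise(Re(x)),
      imaginary = if (method == "dwt") dwt_denoise(Im(x)) else
        emd_denoise(Im(x))
    ))
    # conjugation symmetry
    expect_equal(denoise_complex(Conj(x), method), Conj(y), tolerance = 1e-12)
  }
  # purely real input keeps a zero imaginary part
  yr <- denoise_complex(Re(x) + 0i, "dwt")
  expect_true(all(Im(yr) == 0))
  expect_identical(denoise_complex(x, "none"), x)
  expect_error(denoise_complex(x, "fir"), "method")
})

test_that("DWT denoising never inflates the record's total energy", {
  for (seed in 1:10) {
    x <- noisy_record(seed = seed)
    e0 <- compute_spectrum(x)$total_energy
    e1 <- compute_spectrum(denoise_complex(x, "dwt"))$total_energy
    expect_lte(e1, e0 + 1e-9 * e0)
  }
})

test_that("DWT preserves the low band better than EMD on simulator output", {
  clean <- clean_record()
  nb <- 1024L / 8L
  lowband_err <- function(y) {
    py <- compute_spectrum(y)$psd[1:nb]
    pr <- compute_spectrum(clean)$psd[1:nb]
    sqrt(sum((py - pr)^2) / sum(pr^2))
  }
  errs <- vapply(1:12, function(seed) {
    x <- noisy_record(seed = seed)
    c(dwt = lowband_err(denoise_complex(x, "dwt")),
      emd = lowband_err(denoise_complex(x, "emd")))
  }, numeric(2))
  expect_lt(mean(errs["dwt", ]), 0.1)
  expect_true(all(errs["emd", ] >= errs["dwt", ]))
})
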