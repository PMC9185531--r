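# Spectral energy analysis of beat signals: IDFT reconstruction, 16x
# zero-padding against the picket-fence effect, FFT, power spectral density
# and the energy/peak summaries used for calibration.
#
# Package-wide DFT convention: the forward transform is unnormalized
# (stats::fft) and the inverse carries the 1/N factor.

#' Forward and inverse discrete Fourier transforms
#'
#' `beat_dft()` is the unnormalized forward DFT; `beat_idft()` is its exact
#' inverse, `x(n) = (1/N) sum_k X(k) exp(+i 2 pi n k / N)`. The radar chip
#' streams out 1D-FFT bins, so the time-domain record is recovered with
#' `beat_idft()` before any further processing.
#'
#' @param x Complex (or numeric) vector.
#' @return Complex vector of the same length.
#' @export
beat_idft <- function(x) {
  if (length(x) < 1L) abort("empty input to beat_idft()")
  fft(as_complex(x), inverse = TRUE) / length(x)
}

#' @rdname beat_idft
#' @export
beat_dft <- function(x) {
  if (length(x) < 1L) abort("empty input to beat_dft()")
  fft(as_complex(x))
}

#' Zero-pad a record to a multiple of its length
#'
#' Keeps the first `N` samples and appends `(factor - 1) N` exact zeros, so a
#' 64-sample record becomes 1024 samples of which 960 are zero. Padding
#' refines the DFT bin spacing (mitigating the picket-fence effect) without
#' adding energy.
#'
#' @param x Complex vector of length N.
#' @param factor Integer padding factor >= 1 (default 16).
#' @return Complex vector of length `factor * length(x)`.
#' @export
zero_pad <- function(x, factor = 16L) {
  if (length(factor) != 1L || is.na(factor) || factor < 1 ||
      abs(factor - round(factor)) > 1e-9) {
    abort("`factor` must be a positive integer")
  }
  factor <- as.integer(round(factor))
  c(as_complex(x), rep(0 + 0i, (factor - 1L) * length(x)))
}

#' Power spectral density of a (padded) record
#'
#' `P(k) = |S(k)|^2 / N` where `S` is the unnormalized DFT of the padded
#' signal and `N` is the *original* (unpadded) record length.
#'
#' @param s Complex vector (typically zero-padded).
#' @param n_original Original record length N.
#' @return Nonnegative numeric vector, one value per DFT bin.
#' @export
psd_estimate <- function(s, n_original) {
  if (length(s) < 1L) abort("empty input to psd_estimate()")
  stopifnot_scalar_number(n_original, "n_original", lower = 1)
  if (length(s) < n_original) abort("`s` shorter than `n_original`")
  Mod(fft(as_complex(s)))^2 / n_original
}

#' Total spectral energy
#'
#' Sum of the PSD over all bins (DC included unless `drop_dc`). With the
#' package DFT convention this equals `(M/N) * sum(|x(n)|^2)` for a length-N
#' record padded to length M (Parseval).
#'
#' @param psd Nonnegative PSD vector.
#' @param drop_dc Exclude bin 1 (DC) from the sum.
#' @return Scalar energy (a.u.^2).
#' @export
total_energy <- function(psd, drop_dc = FALSE) {
  if (any(psd < 0)) abort("PSD must be nonnegative")
  if (isTRUE(drop_dc)) psd <- psd[-1L]
  sum(psd)
}

#' Peak of the power spectral density
#'
#' Index (1-based DFT bin) and value of the maximum PSD entry; ties go to the
#' lowest bin.
#'
#' @param psd Nonnegative PSD vector.
#' @return List with `bin` and `value`.
#' @export
peak_power <- function(psd) {
  if (length(psd) < 1L) abort("empty PSD")
  k <- which.max(psd)
  list(bin = k, value = psd[[k]])
}

#' Full spectral summary of one record
#'
#' Chains [zero_pad()], the forward DFT, [psd_estimate()], [total_energy()]
#' and [peak_power()] into a single `spectrum_result`.
#'
#' @param x Complex record of length N.
#' @param pad_factor Zero-padding factor (default 16).
#' @param drop_dc Exclude the DC bin from the total energy.
#' @return An object of class `spectrum_result`: a list with `padded_signal`,
#'   `spectrum`, `psd`, `total_energy`, `peak_bin`, `peak_power`,
#'   `n_original`, `pad_factor`.
#' @export
compute_spectrum <- function(x, pad_factor = 16L, drop_dc = FALSE) {
  n <- length(x)
  s <- zero_pad(x, pad_factor)
  spec <- beat_dft(s)
  p <- Mod(spec)^2 / n
  pk <- peak_power(p)
  structure(
    list(
      padded_signal = s, spectrum = spec, psd = p,
      total_energy = total_energy(p, drop_dc = drop_dc),
      peak_bin = pk$bin, peak_power = pk$value,
      n_original = n, pad_factor = as.integer(pad_factor)
    ),
    class = "spectrum_result"
  )
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf(
    "<spectrum_result> N = %d, padded to %d; E = %.6g, peak P(%d) = %.6g\n",
    x$n_original, length(x$psd), x$total_energy, x$peak_bin, x$peak_power
  ))
  invisible(x)
}

#' Per-record spectral features of a beat-signal dataset
#'
#' Maps [compute_spectrum()] over the `signal` list-column and returns one
#' row per record with its total energy and PSD peak.
#'
#' @param signals Tibble with a complex `signal` list-column (see
#'   [simulate_beat_signals()]).
#' @param pad_factor Zero-padding factor.
#' @param drop_dc Exclude the DC bin from the total energy.
#' @return The input tibble without `signal`, plus `total_energy`,
#'   `peak_bin`, `peak_power`.
#' @examples
#' radar_config(records_per_class = 2L, antennas = 1L) |>
#'   simulate_beat_signals() |>
#'   spectral_features()
#' @export
spectral_features <- function(signals, pad_factor = 16L, drop_dc = FALSE) {
  if (!"signal" %in% names(signals)) {
    abort("`signals` must contain a `signal` list-column")
  }
  specs <- purrr::map(signals$signal, compute_spectrum,
                      pad_factor = pad_factor, drop_dc = drop_dc)
  out <- dplyr::mutate(
    signals,
    signal = NULL,
    total_energy = purrr::map_dbl(specs, "total_energy"),
    peak_bin = purrr::map_int(specs, ~ as.integer(.x$peak_bin)),
    peak_power = purrr::map_dbl(specs, "peak_power")
  )
  tibble::as_tibble(out)
}

#' Plot a power spectral density
#'
#' @param object A `spectrum_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spectrum_result
#' @export
autoplot.spectrum_result <- function(object, ...) {
  m <- length(object$psd)
  df <- tibble::tibble(
    frequency = (seq_len(m) - 1) / m,
    psd = object$psd
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency, .data$psd)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(
      x = "normalized frequency (cycles/sample)",
      y = "P(k) (a.u.²)",
      title = sprintf("PSD, E = %.4g", object$total_energy)
    ) +
    ggplot2::theme_minimal()
}
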