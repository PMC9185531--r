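# Complex continuous-wavelet scalogram tensors: the network input. A complex
# beat signal is split into its counterclockwise (positive-frequency) and
# clockwise (negative-frequency) rotating components by an analytic Morlet
# CWT of the signal and of its conjugate, and the four real planes
# Re/Im(positive), Re/Im(negative) are stacked into a zero-mean 3-D tensor.

# Analytic Morlet CWT of a complex signal: responds only to positive
# (counterclockwise) frequencies. FFT implementation; rows = scales.
cwt_analytic <- function(x, scales, omega0 = 6) {
  n <- length(x)
  xf <- fft(as_complex(x))
  omega <- 2 * pi * (seq_len(n) - 1) / n
  omega[omega > pi] <- omega[omega > pi] - 2 * pi
  out <- matrix(0 + 0i, nrow = length(scales), ncol = n)
  pos <- omega > 0
  for (i in seq_along(scales)) {
    s <- scales[i]
    psi_hat <- numeric(n)
    psi_hat[pos] <- pi^(-0.25) * exp(-(s * omega[pos] - omega0)^2 / 2)
    out[i, ] <- fft(xf * sqrt(s) * psi_hat, inverse = TRUE) / n
  }
  out
}

# Log-spaced scale grid covering normalized frequencies [f_min, f_max].
morlet_scales <- function(n_scales, f_min = 0.01, f_max = 0.45, omega0 = 6) {
  freqs <- exp(seq(log(f_max), log(f_min), length.out = n_scales))
  list(scales = omega0 / (2 * pi * freqs), freqs = freqs)
}

#' Complex CWT: counterclockwise and clockwise components
#'
#' Computes the analytic Morlet continuous wavelet transform of a complex
#' signal on the positive scales (responding to counterclockwise,
#' positive-frequency rotation) and on the negative scales (clockwise
#' rotation), the latter realized as the positive-scale transform of the
#' conjugated signal. Scales are logarithmically spaced over the band
#' containing the beat tone.
#'
#' @param x Complex vector, length >= 8.
#' @param n_scales Number of scales (>= 4, default 32).
#' @param f_range Normalized frequency band `(f_min, f_max)` covered by the
#'   scale grid (cycles/sample).
#' @param omega0 Morlet center frequency (default 6).
#' @return List with complex matrices `pos` and `neg` of shape
#'   `(n_scales, length(x))`, plus `scales` and `freqs`.
#' @export
cwt_complex <- function(x, n_scales = 32L, f_range = c(0.01, 0.45),
                        omega0 = 6) {
  if (length(x) < 8L) abort("signal too short for the CWT (need >= 8)")
  if (n_scales < 4L) abort("`n_scales` must be at least 4")
  sc <- morlet_scales(n_scales, f_range[1], f_range[2], omega0)
  list(
    pos = cwt_analytic(x, sc$scales, omega0),
    neg = cwt_analytic(Conj(as_complex(x)), sc$scales, omega0),
    scales = sc$scales,
    freqs = sc$freqs
  )
}

#' Stack CWT components into the 4-page network input tensor
#'
#' Pages, in order: real part of the positive-scale CWT, imaginary part of
#' the positive-scale CWT, real part of the negative-scale CWT, imaginary
#' part of the negative-scale CWT. The tensor is then zero-mean normalized
#' (one global mean over all entries); variance scaling is available but off
#' by default.
#'
#' @param pos,neg Complex matrices of identical shape `(scales, time)`.
#' @param normalize `"zero_mean"` (default) or `"raw"`.
#' @param unit_variance Also divide by the global standard deviation.
#' @return A 3-D array `(scales, time, 4)` of class `scalogram_tensor` with
#'   attribute `normalization_state`.
#' @export
build_input_tensor <- function(pos, neg, normalize = c("zero_mean", "raw"),
                               unit_variance = FALSE) {
  normalize <- match.arg(normalize)
  if (!all(dim(pos) == dim(neg))) abort("`pos` and `neg` shapes differ")
  x <- array(0, dim = c(nrow(pos), ncol(pos), 4L))
  x[, , 1L] <- Re(pos)
  x[, , 2L] <- Im(pos)
  x[, , 3L] <- Re(neg)
  x[, , 4L] <- Im(neg)
  if (normalize == "zero_mean") {
    x <- x - mean(x)
    if (isTRUE(unit_variance)) {
      s <- sd(as.vector(x))
      if (s > 0) x <- x / s
    }
  }
  structure(x, class = c("scalogram_tensor", "array"),
            normalization_state = normalize)
}

#' Scalogram tensors for every record of a dataset
#'
#' Chains [cwt_complex()] and [build_input_tensor()] over the `signal`
#' list-column.
#'
#' @param signals Tibble with a complex `signal` list-column.
#' @inheritParams cwt_complex
#' @inheritParams build_input_tensor
#' @return The input tibble with `signal` replaced by the list-column
#'   `tensor` of `(n_scales, N, 4)` arrays.
#' @examples
#' radar_config(records_per_class = 1L, antennas = 1L) |>
#'   simulate_beat_signals() |>
#'   featurize_signals(n_scales = 8L)
#' @export
featurize_signals <- function(signals, n_scales = 32L,
                              f_range = c(0.01, 0.45), omega0 = 6,
                              normalize = "zero_mean",
                              unit_variance = FALSE) {
  dplyr::mutate(
    signals,
    tensor = purrr::map(.data$signal, function(x) {
      cw <- cwt_complex(x, n_scales = n_scales, f_range = f_range,
                        omega0 = omega0)
      build_input_tensor(cw$pos, cw$neg, normalize = normalize,
                         unit_variance = unit_variance)
    }),
    signal = NULL
  )
}

#' Serialize a batch of scalogram tensors
#'
#' Writes the flattened tensor values to a plain CSV (one row per record)
#' and the shape, labels and metadata to a JSON sidecar `<path>.json`; the
#' reader restores the list-column tibble.
#'
#' @param tensors Tibble with a `tensor` list-column (see
#'   [featurize_signals()]).
#' @param path Output CSV path.
#' @return `path` invisibly (writer); the restored tibble (reader).
#' @export
write_tensor_batch <- function(tensors, path) {
  dims <- dim(tensors$tensor[[1L]])
  flat <- do.call(rbind, lapply(tensors$tensor, as.vector))
  readr::write_csv(tibble::as_tibble(flat, .name_repair = "minimal"), path,
                   col_names = FALSE)
  meta <- as.list(tensors[setdiff(names(tensors), "tensor")])
  jsonlite::write_json(
    list(dim = dims, n = nrow(tensors), meta = meta),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_tensor_batch
#' @export
read_tensor_batch <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(readr::read_csv(path, col_names = FALSE,
                                    show_col_types = FALSE))
  out <- tibble::as_tibble(meta$meta)
  out$tensor <- lapply(seq_len(nrow(flat)), function(i) {
    structure(array(flat[i, ], dim = meta$dim),
              class = c("scalogram_tensor", "array"),
              normalization_state = "zero_mean")
  })
  out
}

#' Plot one scalogram tensor page
#'
#' @param object A `scalogram_tensor`.
#' @param page Page 1--4 (default 1, real part of the counterclockwise
#'   component).
#' @param ... Unused.
#' @return A ggplot raster of the time-scale plane.
#' @method autoplot scalogram_tensor
#' @export
autoplot.scalogram_tensor <- function(object, page = 1L, ...) {
  d <- dim(object)
  df <- tidyr::expand_grid(time = seq_len(d[2]), scale = seq_len(d[1]))
  df$value <- as.vector(object[, , page])
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$scale,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (samples)", y = "scale index",
                  title = sprintf("scalogram page %d", page)) +
    ggplot2::theme_minimal()
}
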