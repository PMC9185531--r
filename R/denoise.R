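# Complex-signal denoising plumbing: the beat signal is complex, the EMD and
# DWT denoisers are real-signal operations, so the in-phase and quadrature
# parts are filtered independently and recombined.

#' Denoise a complex beat signal
#'
#' Applies the chosen real-signal denoiser to the real and imaginary parts
#' independently and recombines them. `method = "none"` returns the input.
#'
#' @param x Complex (or numeric) vector.
#' @param method `"dwt"` (3-level db10 shrinkage, default), `"emd"`
#'   (zero-crossing IMF rejection) or `"none"`.
#' @param ... Passed to [dwt_denoise()] or [emd_denoise()].
#' @return Complex vector of the same length.
#' @export
denoise_complex <- function(x, method = c("dwt", "emd", "none"), ...) {
  if (length(method) != 1L || !method %in% c("dwt", "emd", "none")) {
    abort("`method` must be one of \"dwt\", \"emd\", \"none\"")
  }
  x <- as_complex(x)
  if (method == "none") return(x)
  f <- switch(method, dwt = dwt_denoise, emd = emd_denoise)
  complex(real = f(Re(x), ...), imaginary = f(Im(x), ...))
}

#' Denoise every record of a beat-signal dataset
#'
#' Maps [denoise_complex()] over the `signal` list-column.
#'
#' @param signals Tibble with a complex `signal` list-column.
#' @inheritParams denoise_complex
#' @return The input tibble with `signal` replaced by its denoised version.
#' @examples
#' radar_config(records_per_class = 2L, antennas = 1L) |>
#'   simulate_beat_signals() |>
#'   denoise_signals(method = "dwt")
#' @export
denoise_signals <- function(signals, method = c("dwt", "emd", "none"), ...) {
  method <- match.arg(method)
  dplyr::mutate(
    signals,
    signal = purrr::map(.data$signal, denoise_complex, method = method, ...)
  )
}
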