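# Empirical mode decomposition with the zero-crossing rejection rule: the
# beat signal is sifted into intrinsic mode functions (IMFs) ordered fast to
# slow, and every IMF whose zero-crossing count reaches three times that of
# the raw signal is discarded as thermal noise.

# Indices of strict local maxima / minima (plateaus collapse to their first
# sample).
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(max = integer(), min = integer()))
  d <- diff(x)
  # treat exact ties as continuing the previous trend so plateaus give one
  # extremum, not one per sample
  s <- sign(d)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  turn <- diff(s)
  list(
    max = which(turn < 0) + 1L,
    min = which(turn > 0) + 1L
  )
}

# Cubic-spline envelope through the extrema, with the first/last extremum
# mirrored across the record ends to tame boundary swings.
envelope_through <- function(idx, x, n) {
  xi <- idx
  yi <- x[idx]
  if (length(idx) >= 2L) {
    xi <- c(2L - idx[2L], xi, 2L * n - idx[length(idx) - 1L])
    yi <- c(yi[1L], yi, yi[length(yi)])
  }
  stats::splinefun(xi, yi, method = "natural")(seq_len(n))
}

#' Empirical mode decomposition of a real signal
#'
#' Sifts the signal into intrinsic mode functions `C_i(n)` plus a residual
#' `r(n)` so that `x(n) = sum_i C_i(n) + r(n)` holds to machine precision by
#' construction. Each sift subtracts the mean of the upper and lower cubic
#' spline envelopes; sifting stops when the normalized change between
#' iterations drops below `sd_tol` or after `max_sift` iterations, and
#' decomposition stops when the residual has fewer than three extrema or
#' `max_imfs` IMFs were extracted.
#'
#' @param x Real numeric vector, length >= 8.
#' @param max_imfs Maximum number of IMFs P (default 8).
#' @param sd_tol Sifting stop tolerance on the normalized squared change
#'   (default 0.2).
#' @param max_sift Cap on sifting iterations per IMF (default 10).
#' @return An object of class `emd_decomposition`: list with `imfs` (list of
#'   numeric vectors, possibly empty), `residual`, `source_length`.
#' @examples
#' x <- sin(2 * pi * 3 * (0:63) / 64) + 0.2 * sin(2 * pi * 20 * (0:63) / 64)
#' dec <- emd_decompose(x)
#' length(dec$imfs)
#' @export
emd_decompose <- function(x, max_imfs = 8L, sd_tol = 0.2, max_sift = 10L) {
  if (length(x) < 8L) abort("signal too short for EMD (need >= 8 samples)")
  if (!all(is.finite(x))) abort("EMD input must be finite")
  x <- as.numeric(x)
  n <- length(x)
  imfs <- list()
  resid <- x
  for (p in seq_len(max_imfs)) {
    ext <- local_extrema(resid)
    if (length(ext$max) + length(ext$min) < 3L) break
    h <- resid
    for (it in seq_len(max_sift)) {
      e <- local_extrema(h)
      if (length(e$max) < 2L || length(e$min) < 2L) break
      upper <- envelope_through(e$max, h, n)
      lower <- envelope_through(e$min, h, n)
      m <- (upper + lower) / 2
      h_new <- h - m
      sd_it <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
      h <- h_new
      if (sd_it < sd_tol) break
    }
    imfs[[length(imfs) + 1L]] <- h
    resid <- resid - h
  }
  structure(
    list(imfs = imfs, residual = resid, source_length = n),
    class = "emd_decomposition"
  )
}

#' @export
print.emd_decomposition <- function(x, ...) {
  cat(sprintf("<emd_decomposition> %d IMF(s) + residual, N = %d\n",
              length(x$imfs), x$source_length))
  invisible(x)
}

#' Zero-crossing count of a real signal
#'
#' Counts sign changes between consecutive samples. Exact zeros are dropped
#' before counting, so a zero sample whose neighbours have opposite signs
#' contributes exactly one crossing and a zero inside a same-sign run
#' contributes none; an all-zero signal has zero crossings. This makes the
#' `f_i >= 3 f_0` rejection rule deterministic.
#'
#' @param x Real numeric vector.
#' @return Nonnegative integer count.
#' @export
zero_crossing_count <- function(x) {
  if (length(x) < 1L) abort("empty input to zero_crossing_count()")
  s <- sign(as.numeric(x))
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

#' Remove high-frequency IMFs by the zero-crossing rule
#'
#' An IMF is labelled high-frequency when its zero-crossing count `f_i`
#' reaches three times the count `f_0` of the source signal
#' (`f_i >= 3 f_0`, boundary included). The denoised signal is the residual
#' plus every low-frequency IMF.
#'
#' @param dec An [emd_decompose()] result.
#' @param f0 Zero-crossing count of the source signal, >= 0.
#' @return Denoised numeric vector of the source length.
#' @export
classify_and_filter <- function(dec, f0) {
  stopifnot_scalar_number(f0, "f0", lower = 0)
  out <- dec$residual
  for (imf in dec$imfs) {
    if (zero_crossing_count(imf) < 3 * f0) out <- out + imf
  }
  out
}

#' Frequency labels of the IMFs of a decomposition
#'
#' @param dec An [emd_decompose()] result.
#' @param f0 Zero-crossing count of the source signal.
#' @return Tibble with `imf`, `f_i`, `f0`, `label` (`"high"` or `"low"`).
#' @export
imf_frequency_labels <- function(dec, f0) {
  fi <- vapply(dec$imfs, zero_crossing_count, integer(1))
  tibble::tibble(
    imf = seq_along(fi),
    f_i = fi,
    f0 = as.integer(f0),
    label = ifelse(fi >= 3 * f0, "high", "low")
  )
}

#' EMD denoising of a real signal
#'
#' Convenience wrapper: decomposes `x`, takes `f_0` from the raw signal and
#' removes the IMFs labelled high-frequency.
#'
#' @inheritParams emd_decompose
#' @return Denoised numeric vector.
#' @export
emd_denoise <- function(x, max_imfs = 8L, sd_tol = 0.2, max_sift = 10L) {
  dec <- emd_decompose(x, max_imfs = max_imfs, sd_tol = sd_tol,
                       max_sift = max_sift)
  classify_and_filter(dec, zero_crossing_count(x))
}
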