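# Dataset partition (85/10/5) and white-noise augmentation of the training
# tensors.

#' Split record indices into train / validation / test sets
#'
#' Sizes are `round(n * ratio)` for the validation and test sets with the
#' remainder assigned to training, so 1000 records at the default ratios
#' give exactly 850/100/50. The assignment is a seeded random permutation.
#'
#' @param n Number of records (>= 20).
#' @param ratios Train/validation/test fractions summing to 1
#'   (default `c(0.85, 0.10, 0.05)`).
#' @param seed RNG seed.
#' @return A `dataset_split`: list with integer index vectors `train`,
#'   `validation`, `test`, plus `ratios` and `seed`.
#' @examples
#' lengths(split_dataset(1000, seed = 1)[1:3])
#' @export
split_dataset <- function(n, ratios = c(0.85, 0.10, 0.05), seed = 1L) {
  if (n < 20L) abort("need at least 20 records to split")
  if (length(ratios) != 3L || any(ratios < 0) ||
      abs(sum(ratios) - 1) > 1e-9) {
    abort("`ratios` must be three nonnegative fractions summing to 1")
  }
  n_val <- round(n * ratios[2])
  n_test <- round(n * ratios[3])
  n_train <- n - n_val - n_test
  perm <- with_seed_or_not(seed, sample.int(n))
  structure(
    list(
      train = sort(perm[seq_len(n_train)]),
      validation = sort(perm[n_train + seq_len(n_val)]),
      test = sort(perm[n_train + n_val + seq_len(n_test)]),
      ratios = ratios, seed = seed
    ),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d / validation %d / test %d (seed %s)\n",
              length(x$train), length(x$validation), length(x$test),
              format(x$seed)))
  invisible(x)
}

#' Expand a training set with white-noise copies
#'
#' Appends `copies` noisy replicas of every tensor (i.i.d. Gaussian noise of
#' standard deviation `sigma` added element-wise); the originals are kept
#' unmodified at the head of the output and labels travel with their
#' tensors.
#'
#' @param tensors List of scalogram tensors.
#' @param labels Labels, one per tensor.
#' @param copies Number of noisy copies per tensor (default 3).
#' @param sigma Noise standard deviation; `NULL` (default) uses 5% of the
#'   pooled standard deviation of the tensor entries.
#' @param seed RNG seed.
#' @return List with `tensors` and `labels` of length `(copies + 1) * n`.
#' @export
augment_white_noise <- function(tensors, labels, copies = 3L, sigma = NULL,
                                seed = 1L) {
  if (copies < 0L) abort("`copies` must be nonnegative")
  if (length(tensors) != length(labels)) {
    abort("`tensors` and `labels` lengths differ")
  }
  if (is.null(sigma)) {
    sigma <- 0.05 * sd(unlist(lapply(tensors[seq_len(min(50, length(tensors)))],
                                     as.vector)))
  }
  if (sigma < 0) abort("`sigma` must be nonnegative")
  if (copies == 0L) return(list(tensors = tensors, labels = labels))
  out_t <- tensors
  out_l <- labels
  with_seed_or_not(seed, {
    for (k in seq_len(copies)) {
      out_t <- c(out_t, lapply(tensors, function(x) {
        x + array(rnorm(length(x), sd = sigma), dim = dim(x))
      }))
      out_l <- c(out_l, labels)
    }
  })
  list(tensors = out_t, labels = out_l)
}
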