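# Internal helpers shared across modules.

# Derive a reproducible child seed from a parent seed and a stream index.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  ((as.numeric(seed) %% 2147483647) * 48271 + as.numeric(stream) * 7919) %% 2147483647
}

# Run `code` under a temporary RNG state seeded with `seed` (NULL = use the
# current stream without touching it).
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed %% 2147483647), code)
  }
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%g, %g], got %g.", name, lower, upper, x))
  }
  invisible(x)
}

is_complex_vector <- function(x) is.complex(x) || is.numeric(x)

as_complex <- function(x) {
  if (is.complex(x)) x else complex(real = as.numeric(x), imaginary = 0)
}
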