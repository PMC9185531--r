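# Sparrow Search Algorithm: a population metaheuristic with producer,
# scrounger and alarmed-sparrow update rules. Generic over any bounded
# continuous search space; for hyperparameter tuning, positions are decoded
# to the integer grid by decode_position() and evaluations are cached by
# decoded configuration.

#' Decode a continuous position to a hyperparameter vector
#'
#' Clips each coordinate to its bounds, rounds the integer dimensions,
#' forces the kernel-size dimension to the nearest odd value (4.4 decodes
#' to 5) and the recurrent width to the nearest multiple of 4 (so the
#' search works on a grid coarse enough for evaluation caching to pay off).
#'
#' @param position Numeric vector `(conv_kernel_size, conv_stride,
#'   lstm_hidden_size)`.
#' @param bounds Named bounds list (see [hyperparameter_bounds()]).
#' @return A [hyperparameter_vector()].
#' @export
decode_position <- function(position, bounds = hyperparameter_bounds()) {
  if (any(!is.finite(position))) abort("position must be finite")
  k <- min(max(position[1], bounds$conv_kernel_size[1]),
           bounds$conv_kernel_size[2])
  k <- 2L * as.integer(round((k - 1) / 2)) + 1L  # nearest odd
  k <- min(max(k, bounds$conv_kernel_size[1]), bounds$conv_kernel_size[2])
  s <- as.integer(round(min(max(position[2], bounds$conv_stride[1]),
                            bounds$conv_stride[2])))
  h <- 4L * as.integer(round(min(max(position[3], bounds$lstm_hidden_size[1]),
                                 bounds$lstm_hidden_size[2]) / 4))
  h <- min(max(h, bounds$lstm_hidden_size[1]), bounds$lstm_hidden_size[2])
  hyperparameter_vector(k, s, h, bounds = bounds)
}

clip_bounds <- function(pos, lo, hi) pmin(pmax(pos, lo), hi)

#' Sparrow search maximization over a bounded space
#'
#' Maximizes `objective(decode(position))` with the sparrow search update
#' rules. Per iteration, the fittest `producer_frac` of the population
#' explore (contracting toward the origin of their position under low alarm,
#' taking Gaussian steps under high alarm `R2 >= safety_threshold`); the
#' remaining scroungers either hop toward the best producer or flee the
#' worst position; and an `alarm_frac` subset takes anti-predator moves
#' around the incumbent. Every position is clipped to the bounds after each
#' update. The incumbent best never regresses, so `history$best_fitness` is
#' monotone non-decreasing, and the whole run is reproducible from `seed`.
#' A failed objective evaluation scores `-Inf` (with a warning) and the run
#' continues.
#'
#' @param objective Function from a decoded position to a scalar fitness
#'   (higher is better).
#' @param bounds Named list of `c(min, max)` per dimension (default: the
#'   classifier hyperparameter bounds).
#' @param pop_size Population size (>= 4, default 6).
#' @param n_iter Iterations (default 5).
#' @param seed RNG seed.
#' @param producer_frac Fraction of producers (default 0.2).
#' @param alarm_frac Fraction of alarmed sparrows (default 0.1).
#' @param safety_threshold Alarm threshold ST (default 0.8).
#' @param decode Mapping from a raw position to the objective's argument.
#'   Defaults to [decode_position()] when `bounds` names match the
#'   hyperparameter dimensions, identity otherwise.
#' @param init Optional list of numeric positions seeding the population
#'   (first slots); by default the hyperparameter search starts from the
#'   package default configuration `c(3, 1, 16)`.
#' @return List with `best` (decoded), `best_fitness`, `history` (tibble:
#'   `iteration`, `best_fitness`), `evaluations` (tibble: `key`, `fitness`
#'   for every distinct configuration evaluated).
#' @examples
#' sphere <- function(x) -sum(x^2)
#' res <- ssa_optimize(sphere, bounds = list(x = c(-5, 5), y = c(-5, 5)),
#'                     pop_size = 10, n_iter = 20, seed = 1)
#' res$best_fitness
#' @export
ssa_optimize <- function(objective, bounds = hyperparameter_bounds(),
                         pop_size = 6L, n_iter = 5L, seed = 1L,
                         producer_frac = 0.2, alarm_frac = 0.1,
                         safety_threshold = 0.8, decode = NULL,
                         init = NULL) {
  if (pop_size < 4L) abort("`pop_size` must be at least 4")
  if (n_iter < 1L) abort("`n_iter` must be at least 1")
  d <- length(bounds)
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  if (any(!is.finite(c(lo, hi)))) abort("bounds must be finite")
  is_hyper <- identical(sort(names(bounds)),
                        sort(names(hyperparameter_bounds())))
  if (is.null(decode)) {
    decode <- if (is_hyper) {
      function(p) decode_position(p, bounds)
    } else {
      function(p) p
    }
  }
  if (is.null(init) && is_hyper) init <- list(c(3, 1, 16))

  cache <- new.env(parent = emptyenv())
  eval_log <- list()
  evaluate <- function(pos) {
    arg <- decode(clip_bounds(pos, lo, hi))
    key <- paste(vapply(unclass(arg)[!vapply(arg, is.list, logical(1))],
                        function(v) paste(format(v, digits = 12),
                                          collapse = ","),
                        character(1)),
                 collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    fit <- tryCatch(objective(arg), error = function(e) {
      warn(sprintf("objective failed at %s: %s", key, conditionMessage(e)))
      -Inf
    })
    cache[[key]] <- fit
    eval_log[[length(eval_log) + 1L]] <<- tibble::tibble(key = key,
                                                         fitness = fit)
    fit
  }

  with_seed_or_not(seed, {
    pop <- matrix(runif(pop_size * d, lo, hi), nrow = pop_size, byrow = TRUE)
    if (!is.null(init)) {
      for (i in seq_along(init)) {
        if (i <= pop_size) pop[i, ] <- clip_bounds(init[[i]], lo, hi)
      }
    }
    fitness <- apply(pop, 1, evaluate)
    best_idx <- which.max(fitness)
    best_pos <- pop[best_idx, ]
    best_fit <- fitness[best_idx]
    history <- numeric(n_iter)
    n_prod <- max(1L, round(producer_frac * pop_size))
    n_alarm <- max(1L, round(alarm_frac * pop_size))

    for (iter in seq_len(n_iter)) {
      ord <- order(fitness, decreasing = TRUE)
      worst_pos <- pop[ord[pop_size], ]
      R2 <- runif(1)
      for (j in seq_len(n_prod)) {            # producers
        i <- ord[j]
        pop[i, ] <- if (R2 < safety_threshold) {
          pop[i, ] * exp(-j / (runif(1) * n_iter + 1e-12))
        } else {
          pop[i, ] + rnorm(1)
        }
        pop[i, ] <- clip_bounds(pop[i, ], lo, hi)
      }
      prod_best <- pop[ord[1L], ]
      for (j in (n_prod + 1L):pop_size) {     # scroungers
        i <- ord[j]
        pop[i, ] <- if (j > pop_size / 2) {
          rnorm(1) * exp((worst_pos - pop[i, ]) / j^2)
        } else {
          A <- sample(c(-1, 1), d, replace = TRUE)
          prod_best + sum(abs(pop[i, ] - prod_best) * A) / d
        }
        pop[i, ] <- clip_bounds(pop[i, ], lo, hi)
      }
      for (i in sample.int(pop_size, n_alarm)) {  # alarmed sparrows
        pop[i, ] <- if (fitness[i] < best_fit) {
          best_pos + rnorm(1) * abs(pop[i, ] - best_pos)
        } else {
          pop[i, ] + runif(1, -1, 1) * abs(pop[i, ] - worst_pos) /
            (best_fit - fitness[i] + 1e-12)
        }
        pop[i, ] <- clip_bounds(pop[i, ], lo, hi)
      }
      fitness <- apply(pop, 1, evaluate)
      it_best <- which.max(fitness)
      if (fitness[it_best] > best_fit) {
        best_fit <- fitness[it_best]
        best_pos <- pop[it_best, ]
      }
      history[iter] <- best_fit
    }
    list(
      best = decode(best_pos),
      best_fitness = best_fit,
      history = tibble::tibble(iteration = seq_len(n_iter),
                               best_fitness = history),
      evaluations = dplyr::bind_rows(eval_log)
    )
  })
}
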