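# End-to-end benchmark: simulate the five-class dataset with power-cycle
# drift, denoise, featurize, split 85/10/5, train the reduced classifier,
# tune it with the sparrow search, and compare against the single-session
# energy-calibration baseline.

#' Prepare the synthetic five-class benchmark dataset
#'
#' Simulates single-antenna beat signals for the five calibration
#' concentrations with power-cycle drift enabled, denoises every record,
#' computes scalogram tensors and draws the 85/10/5 split.
#'
#' @param seed Master seed for the run (drives simulation and split).
#' @param records_per_class Records per concentration (default 200, i.e.
#'   1000 records total).
#' @param n_scales CWT scales per tensor (default 16, the desk-scale
#'   resolution of the benchmark; [featurize_signals()] itself defaults to
#'   32).
#' @param denoise `"dwt"`, `"emd"` or `"none"`.
#' @param config Optional [radar_config()] override; `records_per_class`
#'   and seed fields are taken from the other arguments.
#' @return List with `tensors` (list), `labels` (concentrations), `split`
#'   (a [split_dataset()] result), and `meta` (per-record tibble).
#' @export
prepare_benchmark_data <- function(seed = 1L, records_per_class = 200L,
                                   n_scales = 16L, denoise = "dwt",
                                   config = NULL) {
  if (is.null(config)) config <- radar_config()
  config$records_per_class <- as.integer(records_per_class)
  config$antennas <- 1L
  config$seed <- derive_seed(seed, 11)
  df <- simulate_beat_signals(config) |>
    denoise_signals(method = denoise) |>
    featurize_signals(n_scales = n_scales)
  split <- split_dataset(nrow(df), seed = derive_seed(seed, 12))
  list(
    tensors = df$tensor,
    labels = df$concentration,
    split = split,
    meta = df[setdiff(names(df), "tensor")],
    n_scales = as.integer(n_scales),
    n_samples = config$n_samples
  )
}

#' Train and score a classifier on prepared benchmark data
#'
#' @param data A [prepare_benchmark_data()] result.
#' @param hyper A [hyperparameter_vector()].
#' @param epochs Training epochs.
#' @param seed Seed for initialization and shuffling.
#' @param scale Trunk scale (`"reduced"` or `"full"`).
#' @param augment_copies White-noise training copies (default 0).
#' @param lr,batch_size Optimizer settings for the benchmark runs (desk
#'   scale: 0.03 and 64; [train_classifier()] keeps its own defaults).
#' @return List with `model` (trained `gluconet`), `val_accuracy`,
#'   `test_accuracy`.
#' @export
train_benchmark_model <- function(data, hyper = hyperparameter_vector(),
                                  epochs = 5L, seed = 1L, scale = "reduced",
                                  augment_copies = 0L, lr = 0.03,
                                  batch_size = 64L) {
  sp <- data$split
  train_t <- data$tensors[sp$train]
  train_l <- data$labels[sp$train]
  if (augment_copies > 0L) {
    aug <- augment_white_noise(train_t, train_l, copies = augment_copies,
                               seed = derive_seed(seed, 21))
    train_t <- aug$tensors
    train_l <- aug$labels
  }
  model <- build_network(
    hyper,
    input_shape = c(data$n_scales, data$n_samples, 4L),
    n_classes = 5L, scale = scale, seed = derive_seed(seed, 22)
  )
  model <- train_classifier(
    model, train_t, train_l,
    epochs = epochs, lr = lr, batch_size = batch_size,
    seed = derive_seed(seed, 23),
    validation = list(tensors = data$tensors[sp$validation],
                      labels = data$labels[sp$validation])
  )
  list(
    model = model,
    val_accuracy = evaluate_classifier(model, data$tensors[sp$validation],
                                       data$labels[sp$validation]),
    test_accuracy = evaluate_classifier(model, data$tensors[sp$test],
                                        data$labels[sp$test])
  )
}

#' Run the sparrow-search classification benchmark
#'
#' The full deep-learning pipeline on the synthetic benchmark: prepare the
#' dataset, score the default hyperparameters, run the sparrow search
#' (validation accuracy as the objective), retrain at the tuned setting and
#' report accuracies.
#'
#' @inheritParams prepare_benchmark_data
#' @param pop_size,n_iter Sparrow-search budget (defaults 6 and 5).
#' @param epochs Training epochs per objective evaluation.
#' @param final_epochs Epochs for the final retrain at the tuned setting.
#' @param augment_copies White-noise copies for the final retrain.
#' @return List with `default_accuracy`, `tuned_accuracy`, `test_accuracy`,
#'   `best_hyper`, `ssa` (search result), `model` (final trained model),
#'   `n_records`.
#' @export
run_classification_benchmark <- function(seed = 1L, records_per_class = 200L,
                                         n_scales = 16L, denoise = "dwt",
                                         pop_size = 6L, n_iter = 5L,
                                         epochs = 5L, final_epochs = 10L,
                                         augment_copies = 1L) {
  data <- prepare_benchmark_data(seed, records_per_class, n_scales, denoise)
  default_fit <- train_benchmark_model(
    data, hyperparameter_vector(), epochs = epochs,
    seed = derive_seed(seed, 31)
  )
  objective <- function(hyper) {
    train_benchmark_model(data, hyper, epochs = epochs,
                          seed = derive_seed(seed, 31))$val_accuracy
  }
  ssa <- ssa_optimize(
    objective,
    pop_size = pop_size, n_iter = n_iter,
    seed = derive_seed(seed, 32)
  )
  final <- train_benchmark_model(
    data, ssa$best, epochs = final_epochs,
    seed = derive_seed(seed, 31), augment_copies = augment_copies
  )
  list(
    default_accuracy = default_fit$val_accuracy,
    tuned_accuracy = max(final$val_accuracy, ssa$best_fitness),
    test_accuracy = final$test_accuracy,
    best_hyper = ssa$best,
    ssa = ssa,
    model = final$model,
    n_records = length(data$tensors)
  )
}

#' Accuracy of the energy-calibration baseline across power cycles
#'
#' The baseline the deep pipeline is meant to beat: fit the
#' energy-versus-concentration line on one power-on session and classify
#' every record of the *other* sessions by the nearest calibration
#' concentration. Returns per-session-pair accuracies.
#'
#' @param features Per-record [spectral_features()] with `power_cycle_id`.
#' @param classes Concentration classes (defaults to the distinct
#'   concentrations present).
#' @return Tibble with `fit_session`, `eval_session`, `accuracy`.
#' @export
calibration_transfer_accuracy <- function(features, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(features$concentration))
  sessions <- sort(unique(features$power_cycle_id))
  out <- list()
  for (sa in sessions) {
    fit <- energy_calibration(
      dplyr::filter(features, .data$power_cycle_id == sa)
    )
    for (sb in sessions) {
      fb <- dplyr::filter(features, .data$power_cycle_id == sb)
      pred <- predict_concentration(fb$total_energy, fit)
      pred_class <- classes[
        vapply(pred, function(p) which.min(abs(classes - p)), integer(1))
      ]
      out[[length(out) + 1L]] <- tibble::tibble(
        fit_session = sa, eval_session = sb,
        accuracy = mean(pred_class == fb$concentration)
      )
    }
  }
  dplyr::bind_rows(out)
}
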