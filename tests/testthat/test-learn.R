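# Dataset split, augmentation, network construction, backpropagation and
# training behaviour.

test_that("split sizes follow round(n * ratio) with remainder to train", {
  sp <- split_dataset(1000, seed = 1)
  expect_length(sp$train, 850L)
  expect_length(sp$validation, 100L)
  expect_length(sp$test, 50L)
  sp20 <- split_dataset(20, seed = 1)
  expect_equal(lengths(sp20[c("train", "validation", "test")]),
               c(train = 17L, validation = 2L, test = 1L))
  # disjoint and covering
  all_idx <- c(sp$train, sp$validation, sp$test)
  expect_equal(sort(all_idx), 1:1000)
  # deterministic given the seed
  expect_identical(split_dataset(1000, seed = 7), split_dataset(1000, seed = 7))
  expect_false(identical(split_dataset(1000, seed = 7)$train,
                         split_dataset(1000, seed = 8)$train))
  expect_error(split_dataset(1000, ratios = c(0.8, 0.1, 0.05)), "summing to 1")
  expect_error(split_dataset(10), "at least 20")
})

test_that("white-noise augmentation expands without touching originals", {
  toy <- toy_tensors(n_per_class = 4L)
  aug <- augment_white_noise(toy$tensors, toy$labels, copies = 3L,
                             sigma = 0.1, seed = 2)
  expect_length(aug$tensors, 4L * length(toy$tensors))
  expect_identical(aug$tensors[seq_along(toy$tensors)], toy$tensors)
  expect_equal(aug$labels, rep(toy$labels, 4L))
  # sigma 0: copies identical to originals
  aug0 <- augment_white_noise(toy$tensors, toy$labels, copies = 1L, sigma = 0)
  expect_equal(aug0$tensors[[length(toy$tensors) + 1L]], toy$tensors[[1L]])
  # copies 0: identity
  id <- augment_white_noise(toy$tensors, toy$labels, copies = 0L)
  expect_identical(id$tensors, toy$tensors)
  expect_error(augment_white_noise(toy$tensors, toy$labels, sigma = -1),
               "nonnegative")
})

test_that("network outputs normalized probabilities for both trunk scales", {
  withr::with_seed(8, {
    # reduced trunk on a small tensor, full 18-layer-class trunk on the
    # native 32 x 64 input (it downsamples five times)
    X <- lapply(1:4, function(i) array(rnorm(16 * 32 * 4), dim = c(16, 32, 4)))
    m <- build_network(hyperparameter_vector(5, 2, 8),
                       input_shape = c(16, 32, 4), scale = "reduced", seed = 3)
    p <- predict(m, X, type = "prob")
    expect_equal(rowSums(as.matrix(p)), rep(1, 4), tolerance = 1e-6)
    expect_true(all(as.matrix(p) >= 0))
    Xf <- lapply(1:2, function(i) array(rnorm(32 * 64 * 4), dim = c(32, 64, 4)))
    mf <- build_network(hyperparameter_vector(7, 2, 8),
                        input_shape = c(32, 64, 4), scale = "full", seed = 3)
    pf <- predict(mf, Xf, type = "prob")
    expect_equal(rowSums(as.matrix(pf)), rep(1, 2), tolerance = 1e-6)
  })
  # seeded construction is reproducible
  m1 <- build_network(seed = 5)
  m2 <- build_network(seed = 5)
  expect_identical(glucoradar:::nn_params(m1), glucoradar:::nn_params(m2))
  expect_error(hyperparameter_vector(4, 1, 16), "odd")
  expect_error(hyperparameter_vector(3, 3, 16), "outside bounds")
})

test_that("forward pass is batch-equivariant", {
  withr::with_seed(9, {
    X <- lapply(1:6, function(i) array(rnorm(8 * 16 * 4), dim = c(8, 16, 4)))
    m <- build_network(hyperparameter_vector(3, 1, 8),
                       input_shape = c(8, 16, 4), seed = 4)
    p <- as.matrix(predict(m, X, type = "prob"))
    perm <- c(4, 1, 6, 2, 5, 3)
    p_perm <- as.matrix(predict(m, X[perm], type = "prob"))
    expect_equal(p_perm, p[perm, ], tolerance = 1e-12, ignore_attr = TRUE)
  })
})

test_that("backpropagation matches numerical gradients", {
  withr::with_seed(10, {
    m <- build_network(hyperparameter_vector(3, 1, 8),
                       input_shape = c(8, 12, 4), n_classes = 3, seed = 6)
    X <- array(rnorm(8 * 12 * 4 * 3), dim = c(8, 12, 3, 4))
    y <- 1:3
    lg <- glucoradar:::nn_loss_grads(m, X, y)
    flat <- glucoradar:::nn_flat_grads(m, lg$grads)
    params <- glucoradar:::nn_params(m)
    eps <- 1e-5
    for (nm in names(params)) {
      for (ix in sample(length(params[[nm]]), min(2, length(params[[nm]])))) {
        p2 <- params
        p2[[nm]][ix] <- p2[[nm]][ix] + eps
        up <- glucoradar:::nn_loss_grads(glucoradar:::nn_set_params(m, p2),
                                         X, y)$loss
        p2[[nm]][ix] <- p2[[nm]][ix] - 2 * eps
        dn <- glucoradar:::nn_loss_grads(glucoradar:::nn_set_params(m, p2),
                                         X, y)$loss
        num <- (up - dn) / (2 * eps)
        expect_equal(flat[[nm]][ix], num, tolerance = 1e-4,
                     label = sprintf("analytic gradient of %s[%d]", nm, ix))
      }
    }
  })
})

test_that("training solves a separable toy problem and is reproducible", {
  toy <- toy_tensors()
  m <- build_network(hyperparameter_vector(3, 1, 8),
                     input_shape = c(6, 12, 4), n_classes = 2, seed = 11)
  fit <- train_classifier(m, toy$tensors, toy$labels, epochs = 20L,
                          lr = 0.05, batch_size = 8L, seed = 12,
                          validation = list(tensors = toy$tensors,
                                            labels = toy$labels))
  expect_equal(max(fit$history$val_accuracy), 1)
  expect_equal(evaluate_classifier(fit, toy$tensors, toy$labels), 1)

  # identical seeds give identical training curves
  fit2 <- train_classifier(m, toy$tensors, toy$labels, epochs = 5L,
                           lr = 0.05, batch_size = 8L, seed = 12)
  fit3 <- train_classifier(m, toy$tensors, toy$labels, epochs = 5L,
                           lr = 0.05, batch_size = 8L, seed = 12)
  expect_identical(fit2$history, fit3$history)
  expect_identical(glucoradar:::nn_params(fit2), glucoradar:::nn_params(fit3))

  # zero learning rate leaves parameters untouched
  frozen <- train_classifier(m, toy$tensors, toy$labels, epochs = 2L,
                             lr = 0, seed = 13, center = FALSE)
  expect_identical(glucoradar:::nn_params(frozen), glucoradar:::nn_params(m))
})

test_that("evaluation and prediction contracts hold", {
  toy <- toy_tensors(n_per_class = 6L)
  m <- build_network(hyperparameter_vector(3, 1, 8),
                     input_shape = c(6, 12, 4), n_classes = 2, seed = 14)
  fit <- train_classifier(m, toy$tensors, toy$labels, epochs = 10L, lr = 0.05,
                          batch_size = 8L, seed = 15)
  acc <- evaluate_classifier(fit, toy$tensors, toy$labels)
  # invariant under reordering of the evaluation set
  perm <- sample(length(toy$tensors))
  expect_equal(evaluate_classifier(fit, toy$tensors[perm], toy$labels[perm]),
               acc)
  expect_error(evaluate_classifier(fit, list(), character(0)), "empty")
  expect_error(evaluate_classifier(fit, toy$tensors, rep("9", 24)),
               "unknown class label")
  # glance/tidy/history plumbing
  expect_equal(nrow(tidy(fit)), 10L)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_gt(glance(fit)$n_parameters, 1000)
})

test_that("a uniform-random predictor scores near chance on balanced data", {
  # expectation check for the accuracy metric itself
  withr::with_seed(16, {
    y <- rep(1:5, each = 200)
    pred <- sample(1:5, 1000, replace = TRUE)
    expect_lt(abs(mean(pred == y) - 0.2), 0.05)
  })
})
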