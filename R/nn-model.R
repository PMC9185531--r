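# Concentration classifier: a residual convolutional trunk over the
# (scale, time, 4-page) scalogram tensor, a mean collapse of the scale axis
# into a time sequence, two bidirectional LSTM layers, and a softmax head
# over the five concentration classes. Trained with momentum SGD
# (hand-written backpropagation; see nn-layers.R for the primitives).

#' Classifier hyperparameter vector
#'
#' The three hyperparameters searched by the sparrow search: the first
#' convolution's kernel size (odd), its stride, and the hidden width of the
#' bidirectional LSTM layers. Bounds are enforced here and used by
#' [decode_position()].
#'
#' @param conv_kernel_size Odd kernel size of the first convolution.
#' @param conv_stride Stride of the first convolution.
#' @param lstm_hidden_size Hidden units per LSTM direction.
#' @param bounds Named list of `c(min, max)` bounds per dimension.
#' @return A `hyperparameter_vector` (named list).
#' @export
hyperparameter_vector <- function(conv_kernel_size = 3L, conv_stride = 1L,
                                  lstm_hidden_size = 16L,
                                  bounds = hyperparameter_bounds()) {
  h <- list(
    conv_kernel_size = as.integer(conv_kernel_size),
    conv_stride = as.integer(conv_stride),
    lstm_hidden_size = as.integer(lstm_hidden_size),
    bounds = bounds
  )
  if (h$conv_kernel_size %% 2L == 0L) {
    abort("`conv_kernel_size` must be odd")
  }
  for (nm in names(bounds)) {
    v <- h[[nm]]
    if (v < bounds[[nm]][1] || v > bounds[[nm]][2]) {
      abort(sprintf("`%s` = %d outside bounds [%d, %d]",
                    nm, v, bounds[[nm]][1], bounds[[nm]][2]))
    }
  }
  structure(h, class = "hyperparameter_vector")
}

#' @rdname hyperparameter_vector
#' @export
hyperparameter_bounds <- function() {
  list(
    conv_kernel_size = c(3L, 7L),
    conv_stride = c(1L, 2L),
    lstm_hidden_size = c(8L, 32L)
  )
}

conv_out_dim <- function(n, k, pad, stride) (n + 2L * pad - k) %/% stride + 1L

# Architecture table for the two trunk scales. `reduced` is the desk-scale
# 4-block trunk; `full` is an 18-layer-class residual trunk (a 7x7 stem plus
# eight two-convolution residual blocks with projection shortcuts).
trunk_spec <- function(hyper, in_ch, scale) {
  k <- hyper$conv_kernel_size
  s <- hyper$conv_stride
  if (scale == "reduced") {
    list(
      list(kind = "single", k = k, stride = s, out = 8L, pool = TRUE),
      list(kind = "single", k = 3L, stride = 1L, out = 8L, pool = FALSE),
      list(kind = "single", k = 3L, stride = 1L, out = 16L, pool = TRUE),
      list(kind = "single", k = 3L, stride = 1L, out = 16L, pool = FALSE)
    )
  } else {
    c(
      list(list(kind = "single", k = max(k, 7L), stride = 2L, out = 64L,
                pool = TRUE)),
      lapply(seq_len(8L), function(i) {
        out <- c(64L, 64L, 128L, 128L, 256L, 256L, 512L, 512L)[i]
        list(kind = "double", k = 3L, stride = 1L, out = out,
             pool = out > c(64L, 64L, 64L, 128L, 128L, 256L, 256L, 512L)[i])
      })
    )
  }
}

#' Build the concentration classifier
#'
#' Assembles an untrained network for `(scales, time, 4)` scalogram tensors:
#' a convolutional trunk (`scale = "reduced"`: four convolution blocks with
#' identity skips; `scale = "full"`: an 18-layer-class residual trunk), a
#' mean collapse of the scale axis, two bidirectional LSTM layers of
#' `lstm_hidden_size` units per direction, and a softmax output over
#' `n_classes`. Parameter initialization is seeded and reproducible.
#'
#' @param hyper A [hyperparameter_vector()].
#' @param input_shape Integer triple `(scales, time, pages)`.
#' @param n_classes Number of output classes (default 5).
#' @param scale `"reduced"` (default) or `"full"`.
#' @param seed Seed for the parameter initialization.
#' @return An untrained `gluconet` object.
#' @export
build_network <- function(hyper = hyperparameter_vector(),
                          input_shape = c(32L, 64L, 4L),
                          n_classes = 5L,
                          scale = c("reduced", "full"),
                          seed = 1L) {
  scale <- match.arg(scale)
  if (!inherits(hyper, "hyperparameter_vector")) {
    hyper <- do.call(hyperparameter_vector, hyper)
  }
  spec <- trunk_spec(hyper, input_shape[3], scale)
  with_seed_or_not(seed, {
    blocks <- list()
    S <- input_shape[1]; T <- input_shape[2]; C <- input_shape[3]
    for (bs in spec) {
      blk <- list(kind = bs$kind, pool = bs$pool)
      blk$conv1 <- conv_init(bs$k, bs$k, C, bs$out, bs$stride)
      S <- conv_out_dim(S, bs$k, blk$conv1$pad, bs$stride)
      T <- conv_out_dim(T, bs$k, blk$conv1$pad, bs$stride)
      if (bs$kind == "double") {
        blk$conv2 <- conv_init(bs$k, bs$k, bs$out, bs$out, 1L)
        if (bs$out != C) blk$proj <- conv_init(1L, 1L, C, bs$out, bs$stride)
      }
      blk$identity <- bs$kind == "single" && bs$out == C && bs$stride == 1L
      if (bs$pool) { S <- S %/% 2L; T <- T %/% 2L }
      if (S < 1L || T < 2L) abort("input too small for this architecture")
      C <- bs$out
      blocks[[length(blocks) + 1L]] <- blk
    }
    H <- hyper$lstm_hidden_size
    model <- structure(
      list(
        blocks = blocks,
        lstm1 = bilstm_init(C, H),
        lstm2 = bilstm_init(2L * H, H),
        head = dense_init(2L * H, n_classes),
        hyper = hyper, input_shape = as.integer(input_shape),
        n_classes = as.integer(n_classes), scale = scale,
        seq_len = T, seq_feat = C,
        class_levels = NULL, center = NULL, input_scale = NULL,
        history = NULL
      ),
      class = "gluconet"
    )
    model
  })
}

#' @export
print.gluconet <- function(x, ...) {
  cat(sprintf(
    "<gluconet> %s trunk (%d blocks) + 2 bi-LSTM(%d) -> %d classes; input %s%s\n",
    x$scale, length(x$blocks), x$hyper$lstm_hidden_size, x$n_classes,
    paste(x$input_shape, collapse = "x"),
    if (is.null(x$history)) " (untrained)" else
      sprintf("; trained %d epochs", nrow(x$history))
  ))
  invisible(x)
}

# ---- forward / backward ---------------------------------------------------

block_forward <- function(blk, X) {
  cache <- list()
  cf <- conv_forward(blk$conv1, X)
  cache$c1 <- cf$cache
  if (blk$kind == "single") {
    A <- cf$Y
    mask <- A > 0
    Y <- A * mask
    cache$mask <- mask
    if (blk$identity) Y <- Y + X
  } else {
    mask1 <- cf$Y > 0
    Hh <- cf$Y * mask1
    cache$mask1 <- mask1
    cf2 <- conv_forward(blk$conv2, Hh)
    cache$c2 <- cf2$cache
    sc <- if (!is.null(blk$proj)) {
      pf <- conv_forward(blk$proj, X)
      cache$cp <- pf$cache
      pf$Y
    } else X
    Z <- cf2$Y + sc
    mask2 <- Z > 0
    Y <- Z * mask2
    cache$mask2 <- mask2
  }
  if (blk$pool) {
    pl <- pool_forward(Y)
    cache$pool_dim <- pl$dim_in
    Y <- pl$Y
  }
  list(Y = Y, cache = cache)
}

block_backward <- function(blk, dY, cache, need_dx = TRUE) {
  if (blk$pool) dY <- pool_backward(dY, cache$pool_dim)
  grads <- list()
  if (blk$kind == "single") {
    dA <- dY * cache$mask
    cb <- conv_backward(blk$conv1, dA, cache$c1, need_dx = need_dx)
    grads$conv1 <- cb[c("dW", "db")]
    dX <- cb$dX
    if (blk$identity && need_dx) dX <- dX + dY
  } else {
    dZ <- dY * cache$mask2
    cb2 <- conv_backward(blk$conv2, dZ, cache$c2)
    grads$conv2 <- cb2[c("dW", "db")]
    dH <- cb2$dX * cache$mask1
    cb1 <- conv_backward(blk$conv1, dH, cache$c1, need_dx = need_dx)
    grads$conv1 <- cb1[c("dW", "db")]
    dX <- cb1$dX
    if (need_dx) {
      if (!is.null(blk$proj)) {
        cbp <- conv_backward(blk$proj, dZ, cache$cp)
        grads$proj <- cbp[c("dW", "db")]
        dX <- dX + cbp$dX
      } else {
        dX <- dX + dZ
      }
    } else if (!is.null(blk$proj)) {
      cbp <- conv_backward(blk$proj, dZ, cache$cp, need_dx = FALSE)
      grads$proj <- cbp[c("dW", "db")]
    }
  }
  list(dX = dX, grads = grads)
}

nn_forward <- function(model, X, keep_cache = FALSE) {
  caches <- list()
  for (i in seq_along(model$blocks)) {
    bf <- block_forward(model$blocks[[i]], X)
    X <- bf$Y
    if (keep_cache) caches[[i]] <- bf$cache
  }
  d <- dim(X)  # S', T', B, C
  seq_x <- lapply(seq_len(d[2]), function(t) {
    m <- colMeans(array(X[, t, , , drop = FALSE], dim = d[c(1, 3, 4)]))
    t(matrix(m, d[3], d[4]))  # (C, B)
  })
  l1 <- bilstm_forward(model$lstm1, seq_x)
  l2 <- bilstm_forward(model$lstm2, l1$hs)
  M <- Reduce(`+`, l2$hs) / length(l2$hs)
  logits <- model$head$W %*% M + model$head$b
  probs <- softmax_cols(logits)
  out <- list(probs = probs)
  if (keep_cache) {
    out$cache <- list(blocks = caches, trunk_dim = d, l1 = l1, l2 = l2, M = M)
  }
  out
}

nn_loss_grads <- function(model, X, y_int) {
  fw <- nn_forward(model, X, keep_cache = TRUE)
  B <- ncol(fw$probs)
  p_true <- fw$probs[cbind(y_int, seq_len(B))]
  loss <- -mean(log(pmax(p_true, 1e-12)))
  dlogits <- fw$probs
  dlogits[cbind(y_int, seq_len(B))] <- dlogits[cbind(y_int, seq_len(B))] - 1
  dlogits <- dlogits / B

  grads <- list(head = list(
    dW = tcrossprod(dlogits, fw$cache$M),
    db = rowSums(dlogits)
  ))
  dM <- crossprod(model$head$W, dlogits)
  Tn <- length(fw$cache$l2$hs)
  dhs2 <- rep(list(dM / Tn), Tn)
  g2 <- bilstm_backward(model$lstm2, dhs2, fw$cache$l2$cache)
  grads$lstm2 <- g2[c("fwd", "bwd")]
  g1 <- bilstm_backward(model$lstm1, g2$dxs, fw$cache$l1$cache)
  grads$lstm1 <- g1[c("fwd", "bwd")]

  d <- fw$cache$trunk_dim              # (S', T', B, C)
  dTrunk <- array(0, dim = d)
  for (t in seq_len(d[2])) {
    dm <- t(g1$dxs[[t]]) / d[1]        # (B, C)
    dTrunk[, t, , ] <- array(rep(dm, each = d[1]), dim = d[c(1, 3, 4)])
  }
  grads$blocks <- vector("list", length(model$blocks))
  dX <- dTrunk
  for (i in rev(seq_along(model$blocks))) {
    bb <- block_backward(model$blocks[[i]], dX, fw$cache$blocks[[i]],
                         need_dx = i > 1L)
    grads$blocks[[i]] <- bb$grads
    dX <- bb$dX
  }
  list(loss = loss, grads = grads, probs = fw$probs)
}

# ---- parameter bookkeeping ------------------------------------------------

# Flat named list of every trainable array in the model.
nn_params <- function(model) {
  out <- list()
  for (i in seq_along(model$blocks)) {
    blk <- model$blocks[[i]]
    out[[sprintf("b%d.c1.W", i)]] <- blk$conv1$W
    out[[sprintf("b%d.c1.b", i)]] <- blk$conv1$b
    if (!is.null(blk$conv2)) {
      out[[sprintf("b%d.c2.W", i)]] <- blk$conv2$W
      out[[sprintf("b%d.c2.b", i)]] <- blk$conv2$b
    }
    if (!is.null(blk$proj)) {
      out[[sprintf("b%d.p.W", i)]] <- blk$proj$W
      out[[sprintf("b%d.p.b", i)]] <- blk$proj$b
    }
  }
  for (lname in c("lstm1", "lstm2")) {
    for (dir in c("fwd", "bwd")) {
      cell <- model[[lname]][[dir]]
      for (p in c("W", "U", "b")) {
        out[[paste(lname, dir, p, sep = ".")]] <- cell[[p]]
      }
    }
  }
  out$head.W <- model$head$W
  out$head.b <- model$head$b
  out
}

nn_set_params <- function(model, flat) {
  for (i in seq_along(model$blocks)) {
    model$blocks[[i]]$conv1$W <- flat[[sprintf("b%d.c1.W", i)]]
    model$blocks[[i]]$conv1$b <- flat[[sprintf("b%d.c1.b", i)]]
    if (!is.null(model$blocks[[i]]$conv2)) {
      model$blocks[[i]]$conv2$W <- flat[[sprintf("b%d.c2.W", i)]]
      model$blocks[[i]]$conv2$b <- flat[[sprintf("b%d.c2.b", i)]]
    }
    if (!is.null(model$blocks[[i]]$proj)) {
      model$blocks[[i]]$proj$W <- flat[[sprintf("b%d.p.W", i)]]
      model$blocks[[i]]$proj$b <- flat[[sprintf("b%d.p.b", i)]]
    }
  }
  for (lname in c("lstm1", "lstm2")) {
    for (dir in c("fwd", "bwd")) {
      for (p in c("W", "U", "b")) {
        model[[lname]][[dir]][[p]] <- flat[[paste(lname, dir, p, sep = ".")]]
      }
    }
  }
  model$head$W <- flat$head.W
  model$head$b <- flat$head.b
  model
}

# Grad structure -> flat named list matching nn_params().
nn_flat_grads <- function(model, grads) {
  out <- list()
  for (i in seq_along(grads$blocks)) {
    g <- grads$blocks[[i]]
    out[[sprintf("b%d.c1.W", i)]] <- g$conv1$dW
    out[[sprintf("b%d.c1.b", i)]] <- g$conv1$db
    if (!is.null(g$conv2)) {
      out[[sprintf("b%d.c2.W", i)]] <- g$conv2$dW
      out[[sprintf("b%d.c2.b", i)]] <- g$conv2$db
    }
    if (!is.null(g$proj)) {
      out[[sprintf("b%d.p.W", i)]] <- g$proj$dW
      out[[sprintf("b%d.p.b", i)]] <- g$proj$db
    }
  }
  for (lname in c("lstm1", "lstm2")) {
    for (dir in c("fwd", "bwd")) {
      g <- grads[[lname]][[dir]]
      out[[paste(lname, dir, "W", sep = ".")]] <- g$dW
      out[[paste(lname, dir, "U", sep = ".")]] <- g$dU
      out[[paste(lname, dir, "b", sep = ".")]] <- g$db
    }
  }
  out$head.W <- grads$head$dW
  out$head.b <- grads$head$db
  out
}

# ---- data plumbing --------------------------------------------------------

# Stack a list of (S, T, C) tensors into an (S, T, B, C) batch array,
# optionally subtracting a stored (S, T, C) center pattern from every record.
stack_tensors <- function(tensors, center = NULL, scale = NULL) {
  d <- dim(tensors[[1]])
  x <- array(unlist(tensors, use.names = FALSE), dim = c(d, length(tensors)))
  if (!is.null(center)) x <- x - as.vector(center)
  if (!is.null(scale)) x <- x / scale
  aperm(x, c(1, 2, 4, 3))
}

encode_labels <- function(labels, levels = NULL) {
  lab <- as.character(labels)
  if (is.null(levels)) levels <- sort(unique(lab))
  idx <- match(lab, levels)
  if (anyNA(idx)) {
    abort(sprintf(
      "unknown class label(s): %s (classifier knows only: %s)",
      paste(unique(lab[is.na(idx)]), collapse = ", "),
      paste(levels, collapse = ", ")
    ))
  }
  list(idx = idx, levels = levels)
}

# ---- training -------------------------------------------------------------

#' Train the concentration classifier
#'
#' Momentum stochastic gradient descent over mini-batches, with per-epoch
#' training loss and (optional) validation accuracy recorded in the model's
#' history. Training is fully reproducible from `seed`: the same seed gives
#' bitwise-identical shuffles, and therefore identical training curves.
#'
#' @param model An untrained (or previously trained) `gluconet`.
#' @param tensors List of `(scales, time, 4)` scalogram tensors.
#' @param labels Class labels (concentrations), one per tensor.
#' @param epochs Training epochs (default 30).
#' @param lr Learning rate (default 0.01).
#' @param momentum Momentum coefficient (default 0.9).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Seed for shuffling.
#' @param validation Optional list with `tensors` and `labels` scored after
#'   every epoch.
#' @param center Subtract the element-wise mean tensor of the training set
#'   from every input and divide by the pooled standard deviation of the
#'   centered training data (both stored in the model and reapplied at
#'   prediction time). Removes the common-mode scalogram pattern the five
#'   classes share and normalizes the gradient scale, which conditions the
#'   optimization; default `TRUE`.
#' @return The trained `gluconet`, with a `history` tibble
#'   (`epoch`, `loss`, `train_accuracy`, `val_accuracy`).
#' @export
train_classifier <- function(model, tensors, labels, epochs = 30L, lr = 0.01,
                             momentum = 0.9, batch_size = 32L, seed = 1L,
                             validation = NULL, center = TRUE) {
  if (length(tensors) == 0L) abort("empty training set")
  if (length(tensors) != length(labels)) {
    abort("`tensors` and `labels` lengths differ")
  }
  if (isTRUE(center) && is.null(model$center)) {
    model$center <- Reduce(`+`, lapply(tensors, unclass)) / length(tensors)
    sub <- tensors[seq_len(min(200L, length(tensors)))]
    model$input_scale <- sd(unlist(lapply(sub, function(x) {
      as.vector(unclass(x) - model$center)
    })))
    if (!is.finite(model$input_scale) || model$input_scale <= 0) {
      model$input_scale <- 1
    }
  }
  enc <- encode_labels(labels, model$class_levels)
  if (length(enc$levels) > model$n_classes) {
    abort("more classes in the data than network outputs")
  }
  model$class_levels <- enc$levels
  y <- enc$idx
  n <- length(tensors)
  params <- nn_params(model)
  vel <- lapply(params, function(p) p * 0)
  hist <- vector("list", epochs)
  with_seed_or_not(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        X <- stack_tensors(tensors[idx], model$center, model$input_scale)
        lg <- nn_loss_grads(model, X, y[idx])
        if (!is.finite(lg$loss)) {
          abort(sprintf("training diverged at epoch %d (non-finite loss)", ep))
        }
        flat <- nn_flat_grads(model, lg$grads)
        for (nm in names(params)) {
          vel[[nm]] <- momentum * vel[[nm]] - lr * flat[[nm]]
          params[[nm]] <- params[[nm]] + vel[[nm]]
        }
        model <- nn_set_params(model, params)
        ep_loss <- ep_loss + lg$loss * length(idx)
        pred <- max.col(t(lg$probs), ties.method = "first")
        ep_correct <- ep_correct + sum(pred == y[idx])
      }
      val_acc <- NA_real_
      if (!is.null(validation)) {
        val_acc <- evaluate_classifier(model, validation$tensors,
                                       validation$labels)
      }
      hist[[ep]] <- tibble::tibble(
        epoch = ep, loss = ep_loss / n,
        train_accuracy = ep_correct / n, val_accuracy = val_acc
      )
    }
  })
  model$history <- dplyr::bind_rows(hist)
  model
}

#' Classification accuracy on a labelled set
#'
#' @param model A trained `gluconet`.
#' @param tensors List of scalogram tensors.
#' @param labels True labels.
#' @param batch_size Evaluation batch size.
#' @return Fraction of correct predictions in `[0, 1]`.
#' @export
evaluate_classifier <- function(model, tensors, labels, batch_size = 64L) {
  if (length(tensors) == 0L) abort("empty evaluation set")
  enc <- encode_labels(labels, model$class_levels)
  pred <- predict(model, tensors, type = "class_index",
                  batch_size = batch_size)
  mean(pred == enc$idx)
}

#' Predict concentrations for new scalogram tensors
#'
#' @param object A trained `gluconet`.
#' @param tensors List of scalogram tensors.
#' @param type `"class"` (labels), `"prob"` (tibble of class probabilities)
#'   or `"class_index"`.
#' @param batch_size Batch size for the forward passes.
#' @param ... Unused.
#' @return Predicted labels, indices, or a probability tibble.
#' @export
predict.gluconet <- function(object, tensors,
                             type = c("class", "prob", "class_index"),
                             batch_size = 64L, ...) {
  type <- match.arg(type)
  n <- length(tensors)
  probs <- matrix(0, object$n_classes, n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    probs[, idx] <- nn_forward(
      object,
      stack_tensors(tensors[idx], object$center, object$input_scale)
    )$probs
  }
  if (type == "prob") {
    out <- tibble::as_tibble(t(probs), .name_repair = "minimal")
    names(out) <- object$class_levels %||% paste0("class", seq_len(nrow(probs)))
    return(out)
  }
  idx <- max.col(t(probs), ties.method = "first")
  if (type == "class_index") return(idx)
  (object$class_levels %||% as.character(seq_len(object$n_classes)))[idx]
}

#' @method tidy gluconet
#' @export
tidy.gluconet <- function(x, ...) {
  if (is.null(x$history)) {
    abort("model has no training history yet")
  }
  x$history
}

#' @method glance gluconet
#' @export
glance.gluconet <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = if (is.null(h)) 0L else nrow(h),
    final_loss = if (is.null(h)) NA_real_ else h$loss[nrow(h)],
    final_train_accuracy = if (is.null(h)) NA_real_ else
      h$train_accuracy[nrow(h)],
    final_val_accuracy = if (is.null(h)) NA_real_ else h$val_accuracy[nrow(h)],
    n_parameters = sum(vapply(nn_params(x), length, integer(1))),
    scale = x$scale
  )
}

#' Plot the training curves of a classifier
#'
#' @param object A trained `gluconet`.
#' @param ... Unused.
#' @return A ggplot of loss and accuracies per epoch.
#' @method autoplot gluconet
#' @export
autoplot.gluconet <- function(object, ...) {
  h <- tidy(object)
  df <- tidyr::pivot_longer(h, -"epoch", names_to = "metric")
  ggplot2::ggplot(stats::na.omit(df),
                  ggplot2::aes(.data$epoch, .data$value,
                               colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL, title = "training history") +
    ggplot2::theme_minimal()
}
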