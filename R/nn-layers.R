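# Neural-network layer primitives: 2-D convolution via im2col + BLAS matrix
# products, 2x2 mean pooling, ReLU, LSTM cells and a softmax head, each with
# a hand-written backward pass. Batches are stored as 4-D arrays
# (scale, time, batch, channel) — batch before channel so im2col patches can
# be gathered with a single vectorized subset, no transposes — and sequences
# as (feature, batch) matrices per time step.

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- convolution ----------------------------------------------------------

conv_init <- function(kh, kw, in_ch, out_ch, stride = 1L) {
  fan_in <- kh * kw * in_ch
  list(
    type = "conv", kh = kh, kw = kw, stride = as.integer(stride),
    pad = as.integer((kh - 1) / 2), in_ch = in_ch, out_ch = out_ch,
    W = matrix(rnorm(fan_in * out_ch, sd = sqrt(2 / fan_in)), fan_in, out_ch),
    b = numeric(out_ch)
  )
}

# Patch geometry shared by the forward and backward passes. Rows of the
# patch matrix run over (scale out, time out, batch); columns over
# (kernel scale offset, kernel time offset, channel).
conv_geom <- function(layer, d) {
  S <- d[1]; Tt <- d[2]; B <- d[3]; C <- d[4]
  p <- layer$pad; st <- layer$stride
  Sp <- S + 2L * p; Tp <- Tt + 2L * p
  Ho <- (Sp - layer$kh) %/% st + 1L
  Wo <- (Tp - layer$kw) %/% st + 1L
  i_idx <- (seq_len(Ho) - 1L) * st + 1L
  j_idx <- (seq_len(Wo) - 1L) * st + 1L
  # linear offsets into the padded (Sp, Tp, B, C) array
  row_base <- as.integer(
    rep(i_idx - 1L, times = Wo * B) +
      rep(rep((j_idx - 1L) * Sp, each = Ho), times = B) +
      rep((seq_len(B) - 1L) * (Sp * Tp), each = Ho * Wo)
  )
  col_base <- as.integer(
    rep(0:(layer$kh - 1L), times = layer$kw * C) +
      rep(rep(0:(layer$kw - 1L) * Sp, each = layer$kh), times = C) +
      rep((seq_len(C) - 1L) * (Sp * Tp * B), each = layer$kh * layer$kw)
  )
  list(Ho = Ho, Wo = Wo, i_idx = i_idx, j_idx = j_idx,
       dim_in = d, dim_pad = c(Sp, Tp, B, C),
       row_base = row_base, col_base = col_base)
}

conv_forward <- function(layer, X) {
  g <- conv_geom(layer, dim(X))
  p <- layer$pad
  if (p > 0L) {
    Xp <- array(0, dim = g$dim_pad)
    Xp[p + seq_len(g$dim_in[1]), p + seq_len(g$dim_in[2]), , ] <- X
  } else {
    Xp <- X
  }
  P <- im2col_gather(Xp, g$row_base, g$col_base)
  out <- P %*% layer$W
  out <- out + rep(layer$b, each = nrow(out))
  dim(out) <- c(g$Ho, g$Wo, g$dim_in[3], layer$out_ch)
  list(Y = out, cache = c(g, list(P = P)))
}

conv_backward <- function(layer, dY, cache, need_dx = TRUE) {
  B <- cache$dim_in[3]; C <- cache$dim_in[4]
  dYm <- dY
  dim(dYm) <- c(cache$Ho * cache$Wo * B, layer$out_ch)
  dW <- crossprod(cache$P, dYm)
  db <- colSums(dYm)
  if (!need_dx) return(list(dX = NULL, dW = dW, db = db))
  dP <- tcrossprod(dYm, layer$W)
  dXp <- col2im_scatter(dP, prod(cache$dim_pad), cache$row_base,
                        cache$col_base)
  dim(dXp) <- cache$dim_pad
  p <- layer$pad
  dX <- dXp[p + seq_len(cache$dim_in[1]), p + seq_len(cache$dim_in[2]), , ,
            drop = FALSE]
  dim(dX) <- cache$dim_in
  list(dX = dX, dW = dW, db = db)
}

# ---- mean pooling (2x2, stride 2; odd trailing rows/cols are cropped) -----

pool_forward <- function(X) {
  d <- dim(X)
  S2 <- d[1] %/% 2L; T2 <- d[2] %/% 2L
  X <- X[seq_len(2L * S2), seq_len(2L * T2), , , drop = FALSE]
  o1 <- seq(1L, 2L * S2, by = 2L); o2 <- seq(1L, 2L * T2, by = 2L)
  Y <- (X[o1, o2, , , drop = FALSE] + X[o1 + 1L, o2, , , drop = FALSE] +
        X[o1, o2 + 1L, , , drop = FALSE] + X[o1 + 1L, o2 + 1L, , , drop = FALSE]) / 4
  list(Y = Y, dim_in = d)
}

pool_backward <- function(dY, dim_in) {
  d2 <- dim(dY)
  dX <- array(0, dim = dim_in)
  dX[seq_len(2L * d2[1]), seq_len(2L * d2[2]), , ] <-
    dY[ceiling(seq_len(2L * d2[1]) / 2), ceiling(seq_len(2L * d2[2]) / 2), , ,
       drop = FALSE] / 4
  dX
}

# ---- LSTM -----------------------------------------------------------------

lstm_init <- function(d_in, hidden) {
  sdW <- sqrt(1 / d_in); sdU <- sqrt(1 / hidden)
  b <- numeric(4 * hidden)
  b[hidden + seq_len(hidden)] <- 1  # forget-gate bias
  list(
    W = matrix(rnorm(4 * hidden * d_in, sd = sdW), 4 * hidden, d_in),
    U = matrix(rnorm(4 * hidden * hidden, sd = sdU), 4 * hidden, hidden),
    b = b, hidden = hidden, d_in = d_in
  )
}

# xs: list over time of (d_in, B) matrices. Returns hidden states and caches.
lstm_forward <- function(cell, xs) {
  H <- cell$hidden
  B <- ncol(xs[[1]])
  h <- matrix(0, H, B); cst <- matrix(0, H, B)
  hs <- vector("list", length(xs)); caches <- vector("list", length(xs))
  for (t in seq_along(xs)) {
    z <- cell$W %*% xs[[t]] + cell$U %*% h + cell$b
    i <- sigmoid(z[seq_len(H), , drop = FALSE])
    f <- sigmoid(z[H + seq_len(H), , drop = FALSE])
    g <- tanh(z[2 * H + seq_len(H), , drop = FALSE])
    o <- sigmoid(z[3 * H + seq_len(H), , drop = FALSE])
    c_new <- f * cst + i * g
    tc <- tanh(c_new)
    caches[[t]] <- list(x = xs[[t]], h_prev = h, c_prev = cst,
                        i = i, f = f, g = g, o = o, tc = tc)
    cst <- c_new
    h <- o * tc
    hs[[t]] <- h
  }
  list(hs = hs, caches = caches)
}

# dhs: list over time of gradients w.r.t. the hidden outputs.
lstm_backward <- function(cell, dhs, caches) {
  H <- cell$hidden
  B <- ncol(dhs[[1]])
  dW <- matrix(0, nrow(cell$W), ncol(cell$W))
  dU <- matrix(0, nrow(cell$U), ncol(cell$U))
  db <- numeric(length(cell$b))
  dxs <- vector("list", length(dhs))
  dh_next <- matrix(0, H, B); dc_next <- matrix(0, H, B)
  for (t in rev(seq_along(dhs))) {
    cc <- caches[[t]]
    dh <- dhs[[t]] + dh_next
    do_ <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dz <- rbind(
      di * cc$i * (1 - cc$i),
      df * cc$f * (1 - cc$f),
      dg * (1 - cc$g^2),
      do_ * cc$o * (1 - cc$o)
    )
    dW <- dW + tcrossprod(dz, cc$x)
    dU <- dU + tcrossprod(dz, cc$h_prev)
    db <- db + rowSums(dz)
    dxs[[t]] <- crossprod(cell$W, dz)
    dh_next <- crossprod(cell$U, dz)
    dc_next <- dc * cc$f
  }
  list(dxs = dxs, dW = dW, dU = dU, db = db)
}

# Bidirectional wrapper: separate cells over the sequence and its reversal,
# hidden states concatenated per step.
bilstm_init <- function(d_in, hidden) {
  list(fwd = lstm_init(d_in, hidden), bwd = lstm_init(d_in, hidden))
}

bilstm_forward <- function(layer, xs) {
  Tn <- length(xs)
  ff <- lstm_forward(layer$fwd, xs)
  bb <- lstm_forward(layer$bwd, rev(xs))
  hs <- lapply(seq_len(Tn), function(t) rbind(ff$hs[[t]], bb$hs[[Tn - t + 1L]]))
  list(hs = hs, cache = list(ff = ff, bb = bb))
}

bilstm_backward <- function(layer, dhs, cache) {
  H <- layer$fwd$hidden
  Tn <- length(dhs)
  d_f <- lapply(dhs, function(d) d[seq_len(H), , drop = FALSE])
  d_b <- lapply(rev(dhs), function(d) d[H + seq_len(H), , drop = FALSE])
  gf <- lstm_backward(layer$fwd, d_f, cache$ff$caches)
  gb <- lstm_backward(layer$bwd, d_b, cache$bb$caches)
  dxs <- lapply(seq_len(Tn), function(t) gf$dxs[[t]] + gb$dxs[[Tn - t + 1L]])
  list(dxs = dxs, fwd = gf[c("dW", "dU", "db")], bwd = gb[c("dW", "dU", "db")])
}

# ---- dense + softmax ------------------------------------------------------

dense_init <- function(d_in, d_out) {
  list(W = matrix(rnorm(d_out * d_in, sd = sqrt(2 / d_in)), d_out, d_in),
       b = numeric(d_out))
}

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(e))
}
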