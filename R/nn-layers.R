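# Minimal dense/convolutional layer engine with hand-written backprop.
#
# Activations are stored as H x W x N x C arrays: with column-major storage
# this layout makes every reshape needed by im2col, batch-norm and the
# attention gate a plain matrix() view with no data movement, which is what
# keeps the black-box query loop fast. Convolutions use im2col so the inner
# loop is one matrix multiply; layers are environments so parameter updates
# happen in place. Nothing here is exported: the backbone module is the
# public surface.

nn_conv <- function(c_in, c_out, k = 3L, init_sd = NULL) {
  e <- new.env(parent = emptyenv())
  e$type <- "conv"
  e$k <- as.integer(k); e$c_in <- as.integer(c_in); e$c_out <- as.integer(c_out)
  sd0 <- init_sd %||% sqrt(2 / (k * k * c_in))  # He initialization
  e$W <- array(stats::rnorm(k * k * c_in * c_out, sd = sd0),
               dim = c(k, k, c_in, c_out))
  e$b <- numeric(c_out)
  e
}

# rows indexed by (h, w, n); column blocks by kernel offset (i within j),
# channels within each block (zero-padded "same" extraction). Must stay in
# lockstep with conv_w2(). The gather/scatter pair lives in src/conv.cpp.
im2col <- function(x, k) {
  d <- dim(x)
  im2col_cpp(as.numeric(x), d[1], d[2], d[3], d[4], k)
}

conv_w2 <- function(layer) {
  matrix(aperm(layer$W, c(3L, 1L, 2L, 4L)), ncol = layer$c_out)
}

conv_forward <- function(layer, x, training = FALSE) {
  d <- dim(x)
  if (d[4] != layer$c_in) {
    rls_stop(sprintf("conv expects %d input channels, got %d",
                     layer$c_in, d[4]))
  }
  X2 <- im2col(x, layer$k)
  Y2 <- X2 %*% conv_w2(layer)
  if (any(layer$b != 0)) Y2 <- Y2 + rep(layer$b, each = nrow(Y2))
  if (training) layer$cache <- list(X2 = X2, dims = d)
  array(Y2, dim = c(d[1], d[2], d[3], layer$c_out))
}

conv_backward <- function(layer, dy) {
  d <- layer$cache$dims
  H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  k <- layer$k; p <- (k - 1L) %/% 2L
  dY2 <- matrix(dy, H * W * N, layer$c_out)
  dW2 <- crossprod(layer$cache$X2, dY2)
  layer$db <- colSums(dY2)
  layer$dW <- aperm(array(dW2, dim = c(C, k, k, layer$c_out)),
                    c(2L, 3L, 1L, 4L))
  dX2 <- dY2 %*% t(conv_w2(layer))
  layer$cache <- NULL
  array(col2im_cpp(dX2, H, W, N, C, k), dim = c(H, W, N, C))
}

# Per-channel batch normalization over the (H, W, N) axes.
nn_batchnorm <- function(c_out, momentum = 0.9, eps = 1e-5) {
  e <- new.env(parent = emptyenv())
  e$type <- "batchnorm"
  e$gamma <- rep(1, c_out); e$beta <- rep(0, c_out)
  e$running_mean <- rep(0, c_out); e$running_var <- rep(1, c_out)
  e$momentum <- momentum; e$eps <- eps
  e
}

bn_forward <- function(layer, x, training = FALSE) {
  d <- dim(x); C <- d[4]
  m <- d[1] * d[2] * d[3]
  xm <- matrix(x, m, C)
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = m)
    va <- colMeans(xc^2)
    sd_ <- sqrt(va + layer$eps)
    xhat <- xc / rep(sd_, each = m)
    layer$running_mean <- layer$momentum * layer$running_mean +
      (1 - layer$momentum) * mu
    layer$running_var <- layer$momentum * layer$running_var +
      (1 - layer$momentum) * va
    layer$cache <- list(xhat = xhat, sd = sd_, dims = d)
  } else {
    sd_ <- sqrt(layer$running_var + layer$eps)
    xhat <- (xm - rep(layer$running_mean, each = m)) / rep(sd_, each = m)
  }
  ym <- xhat * rep(layer$gamma, each = m) + rep(layer$beta, each = m)
  array(ym, dim = d)
}

bn_backward <- function(layer, dy) {
  d <- layer$cache$dims; C <- d[4]
  m <- d[1] * d[2] * d[3]
  dym <- matrix(dy, m, C)
  xhat <- layer$cache$xhat
  layer$dgamma <- colSums(dym * xhat)
  layer$dbeta <- colSums(dym)
  g_over_sd <- layer$gamma / layer$cache$sd
  mean_dy <- colMeans(dym)
  mean_dyxhat <- colMeans(dym * xhat)
  dxm <- (dym - rep(mean_dy, each = m) - xhat * rep(mean_dyxhat, each = m)) *
    rep(g_over_sd, each = m)
  layer$cache <- NULL
  array(dxm, dim = d)
}

nn_relu <- function() {
  e <- new.env(parent = emptyenv())
  e$type <- "relu"
  e
}

relu_forward <- function(layer, x, training = FALSE) {
  if (training) layer$mask <- x > 0
  x * (x > 0)
}

relu_backward <- function(layer, dy) {
  out <- dy * layer$mask
  layer$mask <- NULL
  out
}

# Sigmoid channel attention: z_i = sigmoid(W_i h_i) where h_i is channel i's
# flattened spatial map; the gate multiplies that channel.
nn_attention <- function(c_out, hw, init_sd = 0.01) {
  e <- new.env(parent = emptyenv())
  e$type <- "attention"
  e$c_out <- as.integer(c_out); e$hw <- as.integer(hw)
  e$W <- matrix(stats::rnorm(c_out * hw, sd = init_sd), c_out, hw)
  e
}

att_forward <- function(layer, x, training = FALSE) {
  d <- dim(x); N <- d[3]; C <- d[4]; hw <- d[1] * d[2]
  M <- matrix(x, hw, N * C)                       # column (n, c), n fastest
  Wrep <- t(layer$W)[, rep(seq_len(C), each = N), drop = FALSE]
  s <- colSums(M * Wrep)
  z <- stats::plogis(s)
  yM <- M * rep(z, each = hw)
  if (training) layer$cache <- list(M = M, Wrep = Wrep, z = z, dims = d)
  array(yM, dim = d)
}

att_backward <- function(layer, dy) {
  cc <- layer$cache
  d <- cc$dims; N <- d[3]; C <- d[4]; hw <- d[1] * d[2]
  dyM <- matrix(dy, hw, N * C)
  dz <- colSums(dyM * cc$M)
  ds <- dz * cc$z * (1 - cc$z)
  dxM <- dyM * rep(cc$z, each = hw) + cc$Wrep * rep(ds, each = hw)
  Tm <- cc$M * rep(ds, each = hw)                 # (hw, N*C)
  A <- array(Tm, dim = c(hw, N, C))
  dWt <- matrix(0, hw, C)
  for (ch in seq_len(C)) {
    dWt[, ch] <- A[, , ch] %*% rep(1, N)
  }
  layer$dW <- t(dWt)
  layer$cache <- NULL
  array(dxM, dim = d)
}

attention_gates <- function(layer, x) {
  d <- dim(x); N <- d[3]; C <- d[4]; hw <- d[1] * d[2]
  M <- matrix(x, hw, N * C)
  Wrep <- t(layer$W)[, rep(seq_len(C), each = N), drop = FALSE]
  t(matrix(stats::plogis(colSums(M * Wrep)), N, C))  # (C, N)
}

# Global average pool (H, W, N, C) -> (C, N).
gap_forward <- function(x) {
  d <- dim(x)
  t(matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
}

gap_backward <- function(dy, dims) {
  hw <- dims[1] * dims[2]
  # dy is (C, N); expand to (H, W, N, C) with the n-fastest column order
  array(rep(as.numeric(t(dy)), each = hw) / hw, dim = dims)
}

nn_dense <- function(c_in, c_out, init_sd = 0) {
  e <- new.env(parent = emptyenv())
  e$type <- "dense"
  # zero init by default: an untrained head outputs uniform class probabilities
  e$W <- matrix(if (init_sd > 0) stats::rnorm(c_out * c_in, sd = init_sd) else 0,
                c_out, c_in)
  e$b <- numeric(c_out)
  e
}

dense_forward <- function(layer, x, training = FALSE) {
  if (training) layer$cache <- x
  layer$W %*% x + layer$b
}

dense_backward <- function(layer, dy) {
  layer$dW <- dy %*% t(layer$cache)
  layer$db <- rowSums(dy)
  out <- t(layer$W) %*% dy
  layer$cache <- NULL
  out
}

softmax_cols <- function(logits) {
  z <- logits - rep(apply(logits, 2, max), each = nrow(logits))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(e))
}

# Adam with classic L2 weight decay added to the gradient (the usual
# Adam + weight_decay configuration).
adam_step <- function(layer, params, lr, weight_decay, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    g <- layer[[paste0("d", p)]]
    if (is.null(g)) next
    if (weight_decay > 0 && p %in% c("W", "gamma")) {
      g <- g + weight_decay * layer[[p]]
    }
    mkey <- paste0("m_", p); vkey <- paste0("v_", p)
    if (is.null(layer[[mkey]])) {
      layer[[mkey]] <- g * 0
      layer[[vkey]] <- g * 0
    }
    layer[[mkey]] <- beta1 * layer[[mkey]] + (1 - beta1) * g
    layer[[vkey]] <- beta2 * layer[[vkey]] + (1 - beta2) * g^2
    mhat <- layer[[mkey]] / (1 - beta1^t)
    vhat <- layer[[vkey]] / (1 - beta2^t)
    layer[[p]] <- layer[[p]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(layer)
}

layer_param_names <- function(layer) {
  switch(layer$type,
         conv = c("W", "b"),
         batchnorm = c("gamma", "beta"),
         attention = "W",
         dense = c("W", "b"),
         character(0))
}
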