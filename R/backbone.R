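# Residual CNN backbone with sigmoid channel attention.
#
# Architecture: for each stage, a 3x3 convolution into the stage's channel
# width, batch norm, ReLU, then one residual block whose residual branch is
# convolution -> batch norm -> ReLU -> convolution (identity skip added).
# After the final stage a sigmoid gate per channel reweights the feature
# maps, global average pooling collapses space, and a linear head with
# softmax produces class probabilities. The default (2 stages, 8/16
# channels) is a desk-scale stand-in structurally faithful to a residual
# network at a size trainable on one CPU; depth and width are configurable.

residual_block <- function(channels) {
  list(conv1 = nn_conv(channels, channels),
       bn1 = nn_batchnorm(channels),
       relu = nn_relu(),
       conv2 = nn_conv(channels, channels))
}

# The residual branch F(x) = conv2(relu(bn1(conv1(x)))).
residual_branch <- function(block, x, training = FALSE) {
  h <- conv_forward(block$conv1, x, training)
  h <- bn_forward(block$bn1, h, training)
  h <- relu_forward(block$relu, h, training)
  conv_forward(block$conv2, h, training)
}

#' Forward pass through a residual block
#'
#' Computes `x + F(x, W)` where the residual branch `F` is
#' convolution, batch normalization, ReLU, convolution. The branch output
#' must have the same shape as the input (same-padding, equal channel
#' counts), so zeroing all branch weights makes the block an exact identity.
#'
#' @param block a residual block (element of `model$blocks` or built
#'   internally).
#' @param x input activation: a single `H x W x C` image array, or an
#'   internal `H x W x N x C` batch.
#' @param training logical; `TRUE` uses batch statistics in the branch's
#'   batch norm and caches activations for backprop.
#' @return array of the same shape as `x`.
#' @export
residual_forward <- function(block, x, training = FALSE) {
  single <- length(dim(x)) == 3L
  if (single) {
    d3 <- dim(x)
    # H x W x C image -> H x W x 1 x C batch (same linear element order)
    x <- array(x, dim = c(d3[1], d3[2], 1L, d3[3]))
  }
  f <- residual_branch(block, x, training)
  if (!identical(dim(f), dim(x))) {
    rls_stop(sprintf(
      "residual branch output shape (%s) does not match input (%s)",
      paste(dim(f), collapse = "x"), paste(dim(x), collapse = "x")))
  }
  out <- x + f
  if (single) out <- array(out, dim = dim(out)[c(1L, 2L, 4L)])
  out
}

residual_backward <- function(block, dy) {
  d <- conv_backward(block$conv2, dy)
  d <- relu_backward(block$relu, d)
  d <- bn_backward(block$bn1, d)
  dy + conv_backward(block$conv1, d)
}

#' Sigmoid attention weight
#'
#' `z = sigmoid(W %*% h)`: the scalar attention weight applied
#' multiplicatively to a feature map. `W` and `h` may be a weight vector and
#' feature vector (inner product) or conformable matrix/vector.
#'
#' @param h numeric feature vector.
#' @param W numeric weight vector or matrix conformable with `h`.
#' @return attention weight(s) in `(0, 1)`.
#' @export
attention_weight <- function(h, W) {
  s <- if (is.matrix(W)) as.numeric(W %*% h) else sum(W * h)
  stats::plogis(s)
}

#' Cross-entropy loss
#'
#' Mean over samples of the negative log-likelihood of the true class, with
#' probabilities clamped at `eps` before taking logs. For two classes this
#' is the binary form `-[y log p + (1-y) log(1-p)]` evaluated on the
#' positive-class probability; for more classes it is the categorical form
#' `-log p_true` (the binary expression does not normalize over > 2
#' classes).
#'
#' @param true_labels integer vector of 0-based class labels.
#' @param predicted_probs numeric matrix, one row per sample, one column per
#'   class (a vector is treated as positive-class probabilities of a binary
#'   problem).
#' @param eps clamp applied to probabilities before the log, default 1e-12.
#' @return mean loss, a non-negative scalar.
#' @export
cross_entropy_loss <- function(true_labels, predicted_probs, eps = 1e-12) {
  if (length(true_labels) == 0) data_stop("cross-entropy of an empty batch")
  if (is.vector(predicted_probs)) {
    predicted_probs <- cbind(1 - predicted_probs, predicted_probs)
  }
  if (nrow(predicted_probs) != length(true_labels)) {
    data_stop("true_labels and predicted_probs disagree in length")
  }
  idx <- cbind(seq_along(true_labels), as.integer(true_labels) + 1L)
  p_true <- pmin(pmax(predicted_probs[idx], eps), 1 - eps)
  if (ncol(predicted_probs) == 2L) {
    # binary form; equals -log p_true when rows sum to one
    y <- as.numeric(true_labels == 1L)
    p1 <- pmin(pmax(predicted_probs[, 2L], eps), 1 - eps)
    mean(-(y * log(p1) + (1 - y) * log(1 - p1)))
  } else {
    mean(-log(p_true))
  }
}

#' Construct an untrained backbone model
#'
#' @param input_shape integer `c(H, W, C)` of the images the model accepts.
#' @param n_classes number of output classes, `>= 2`.
#' @param channels integer vector of channel widths, one per residual stage.
#' @param seed optional RNG seed for weight initialization (the caller's RNG
#'   state is preserved).
#' @return an object of class `backbone_model`.
#' @export
backbone_model <- function(input_shape, n_classes, channels = c(8L, 16L),
                           seed = NULL) {
  if (n_classes < 2L) config_stop("n_classes must be >= 2")
  build <- function() {
    stages <- list()
    c_prev <- input_shape[3]
    hw <- input_shape[1] * input_shape[2]
    for (ch in channels) {
      stages[[length(stages) + 1L]] <- list(
        conv = nn_conv(c_prev, ch),
        bn = nn_batchnorm(ch),
        relu = nn_relu(),
        block = residual_block(ch))
      c_prev <- ch
    }
    list(stages = stages,
         attention = nn_attention(c_prev, hw),
         head = nn_dense(c_prev, n_classes))
  }
  net <- if (is.null(seed)) build() else with_seed(seed, build())
  structure(
    list(arch = list(input_shape = as.integer(input_shape),
                     n_classes = as.integer(n_classes),
                     channels = as.integer(channels)),
         net = net,
         epochs_trained = 0L,
         best_val_loss = NA_real_,
         history = data.frame()),
    class = "backbone_model")
}

#' @export
print.backbone_model <- function(x, ...) {
  cat(sprintf(
    "<backbone_model> input %s, %d classes, stages [%s], %d epoch(s) trained\n",
    paste(x$arch$input_shape, collapse = "x"), x$arch$n_classes,
    paste(x$arch$channels, collapse = ", "), x$epochs_trained))
  invisible(x)
}

model_layers <- function(model) {
  out <- list()
  for (st in model$net$stages) {
    out <- c(out, list(st$conv, st$bn,
                       st$block$conv1, st$block$bn1, st$block$conv2))
  }
  c(out, list(model$net$attention, model$net$head))
}

# In eval mode a conv followed by batch norm is one affine convolution:
# W' = W * gamma/sd per output channel, b' = (b - mean) * gamma/sd + beta.
fold_conv_bn <- function(conv, bn) {
  scale <- bn$gamma / sqrt(bn$running_var + bn$eps)
  list(k = conv$k, c_in = conv$c_in, c_out = conv$c_out,
       W = conv$W * rep(scale, each = conv$k * conv$k * conv$c_in),
       b = (conv$b - bn$running_mean) * scale + bn$beta)
}

backbone_logits <- function(model, x, training = FALSE) {
  if (!identical(dim(x)[c(1L, 2L, 4L)], as.integer(model$arch$input_shape))) {
    data_stop(sprintf("input shape %s does not match model input %s",
                      paste(dim(x)[c(1L, 2L, 4L)], collapse = "x"),
                      paste(model$arch$input_shape, collapse = "x")))
  }
  if (training) {
    for (st in model$net$stages) {
      x <- conv_forward(st$conv, x, TRUE)
      x <- bn_forward(st$bn, x, TRUE)
      x <- relu_forward(st$relu, x, TRUE)
      x <- residual_forward(st$block, x, TRUE)
    }
  } else {
    for (st in model$net$stages) {
      x <- conv_forward(fold_conv_bn(st$conv, st$bn), x)
      x <- x * (x > 0)
      h <- conv_forward(fold_conv_bn(st$block$conv1, st$block$bn1), x)
      h <- h * (h > 0)
      x <- x + conv_forward(st$block$conv2, h)
    }
  }
  x <- att_forward(model$net$attention, x, training)
  feat <- gap_forward(x)
  logits <- dense_forward(model$net$head, feat, training)
  if (training) {
    attr(logits, "gap_dims") <- dim(x)
  }
  logits
}

backbone_backward <- function(model, dlogits, gap_dims) {
  d <- dense_backward(model$net$head, dlogits)
  d <- gap_backward(d, gap_dims)
  d <- att_backward(model$net$attention, d)
  for (st in rev(model$net$stages)) {
    d <- residual_backward(st$block, d)
    d <- relu_backward(st$relu, d)
    d <- bn_backward(st$bn, d)
    d <- conv_backward(st$conv, d)
  }
  invisible(NULL)
}

# Stack a list of image arrays / image_samples into the internal
# H x W x N x C batch layout.
stack_images <- function(images) {
  imgs <- lapply(images, function(s) {
    if (inherits(s, "image_sample")) s$pixels else as_image_array(s)
  })
  d <- dim(imgs[[1]])
  x <- array(0, dim = c(d[1], d[2], length(imgs), d[3]))
  for (i in seq_along(imgs)) x[, , i, ] <- imgs[[i]]
  x
}

# Folded conv weights of every stage in the matrix shape the fused C++
# forward expects.
folded_layers <- function(model) {
  lapply(model$net$stages, function(st) {
    s <- fold_conv_bn(st$conv, st$bn)
    b1 <- fold_conv_bn(st$block$conv1, st$block$bn1)
    w2 <- function(f) matrix(aperm(f$W, c(3L, 1L, 2L, 4L)), ncol = f$c_out)
    list(k = st$conv$k,
         sW = w2(s), sb = s$b,
         b1W = w2(b1), b1b = b1$b,
         b2W = conv_w2(st$block$conv2), b2b = st$block$conv2$b)
  })
}

#' Class probabilities for a batch of images
#'
#' @param model a trained [backbone_model()].
#' @param images list of images (`image_sample` or arrays), or one
#'   internal `H x W x N x C` batch array.
#' @return `N x n_classes` matrix of softmax probabilities, rows summing to 1.
#' @export
predict_proba_batch <- function(model, images) {
  x <- if (is.array(images) && length(dim(images)) == 4L) images
       else stack_images(if (is.list(images)) images else list(images))
  d <- dim(x)
  if (!identical(d[c(1L, 2L, 4L)], as.integer(model$arch$input_shape))) {
    data_stop(sprintf("input shape %s does not match model input %s",
                      paste(d[c(1L, 2L, 4L)], collapse = "x"),
                      paste(model$arch$input_shape, collapse = "x")))
  }
  backbone_forward_cpp(as.numeric(x), d[1], d[2], d[3], d[4],
                       folded_layers(model), model$net$attention$W,
                       model$net$head$W, model$net$head$b)
}

#' Class probabilities for one image
#'
#' The softmax class distribution for a single image; this query is the only
#' model access the reinforcement-learning module uses (black-box contract).
#'
#' @param model a [backbone_model()].
#' @param image an [image_sample()] or `H x W x C` array.
#' @return numeric probability vector of length `n_classes`, summing to 1.
#' @export
predict_proba <- function(model, image) {
  as.numeric(predict_proba_batch(model, list(image)))
}

# Data augmentation for one batch array (in place, returns new array).
augment_batch <- function(x, flags) {
  N <- dim(x)[3]
  for (i in seq_len(N)) {
    img <- x[, , i, , drop = FALSE]
    dim(img) <- dim(x)[c(1L, 2L, 4L)]
    if (isTRUE(flags$rotations)) {
      k <- sample(0:3, 1)
      if (k > 0) for (r in seq_len(k)) {
        img <- aperm(img, c(2L, 1L, 3L))[dim(img)[2]:1, , , drop = FALSE]
      }
    }
    if (isTRUE(flags$flips) && stats::runif(1) < 0.5) {
      img <- img[, dim(img)[2]:1, , drop = FALSE]
    }
    if (isTRUE(flags$brightness)) {
      img <- clip01(img + stats::runif(1, -0.1, 0.1))
    }
    ns <- flags$noise_sd %||% 0
    if (ns > 0) {
      img <- clip01(img + array(stats::rnorm(length(img), 0, ns), dim(img)))
    }
    x[, , i, ] <- img
  }
  x
}

#' Training configuration for the backbone
#'
#' Defaults follow the usual Adam recipe for this problem class: learning
#' rate 0.001, weight decay 1e-4, batch size 32, up to 100 epochs with early
#' stopping on validation loss.
#'
#' @param learning_rate Adam learning rate, `> 0`.
#' @param weight_decay L2 penalty added to weight gradients.
#' @param batch_size minibatch size, `>= 1`.
#' @param max_epochs maximum number of epochs (0 returns the model
#'   unchanged).
#' @param early_stopping_patience epochs without validation improvement
#'   before stopping (`Inf` disables).
#' @param val_fraction fraction of the data held out for validation.
#' @param augment list of augmentation settings: logical flags `rotations`,
#'   `flips`, `brightness`, plus `noise_sd` (standard deviation of
#'   fresh-per-batch Gaussian pixel noise; 0 disables). Noise augmentation
#'   teaches invariance to small off-feature perturbations, which keeps the
#'   attack surface aligned with the discriminative region.
#' @param seed RNG seed driving weight init, shuffling, and augmentation.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, weight_decay = 1e-4,
                         batch_size = 32L, max_epochs = 100L,
                         early_stopping_patience = 10L, val_fraction = 0.2,
                         augment = list(rotations = FALSE, flips = FALSE,
                                        brightness = FALSE, noise_sd = 0),
                         seed = 1L) {
  if (learning_rate <= 0) config_stop("learning_rate must be > 0")
  if (batch_size < 1L) config_stop("batch_size must be >= 1")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stopping_patience = early_stopping_patience,
                 val_fraction = val_fraction, augment = augment,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train the backbone by supervised learning
#'
#' Minimizes the cross-entropy loss with Adam. A stratified validation split
#' monitors generalization; training stops at `max_epochs` or when the
#' validation loss has not improved for `early_stopping_patience` epochs.
#' All randomness (shuffling, augmentation) is driven by `config$seed`, so a
#' fixed seed reproduces the run.
#'
#' @param model a [backbone_model()].
#' @param dataset list of [image_sample()] objects with at least 2 classes
#'   present.
#' @param config a [train_config()].
#' @return the trained model; `$history` holds one row per epoch
#'   (`train_loss`, `train_acc`, `val_loss`).
#' @export
train_supervised <- function(model, dataset, config = train_config()) {
  labels <- vapply(dataset, function(s) s$label, integer(1))
  if (length(unique(labels)) < 2L) {
    data_stop("training requires at least 2 classes present in the dataset")
  }
  if (config$max_epochs == 0L) {
    model$history <- data.frame()
    return(model)
  }
  x_all <- stack_images(dataset)
  n <- length(dataset)
  layers <- model_layers(model)

  with_seed(config$seed, {
    # stratified validation split
    val_idx <- integer(0)
    if (config$val_fraction > 0) {
      for (cl in unique(labels)) {
        ids <- which(labels == cl)
        nv <- max(1L, floor(length(ids) * config$val_fraction))
        val_idx <- c(val_idx, sample(ids, nv))
      }
    }
    train_idx <- setdiff(seq_len(n), val_idx)
    best_val <- Inf; wait <- 0L; adam_t <- 0L
    hist <- vector("list", config$max_epochs)

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(train_idx)
      ep_loss <- 0; ep_correct <- 0L
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        ids <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        xb <- x_all[, , ids, , drop = FALSE]
        aug_on <- isTRUE(config$augment$rotations) ||
          isTRUE(config$augment$flips) || isTRUE(config$augment$brightness) ||
          (config$augment$noise_sd %||% 0) > 0
        if (aug_on) xb <- augment_batch(xb, config$augment)
        yb <- labels[ids]
        logits <- backbone_logits(model, xb, training = TRUE)
        probs <- softmax_cols(logits)
        loss <- cross_entropy_loss(yb, t(probs))
        onehot <- matrix(0, nrow(probs), ncol(probs))
        onehot[cbind(yb + 1L, seq_along(yb))] <- 1
        dlogits <- (probs - onehot) / length(yb)
        backbone_backward(model, dlogits, attr(logits, "gap_dims"))
        adam_t <- adam_t + 1L
        for (ly in layers) {
          adam_step(ly, layer_param_names(ly), config$learning_rate,
                    config$weight_decay, adam_t)
        }
        ep_loss <- ep_loss + loss * length(ids)
        ep_correct <- ep_correct + sum(apply(probs, 2, which.max) - 1L == yb)
      }
      val_loss <- NA_real_
      if (length(val_idx) > 0) {
        vp <- predict_proba_batch(model, x_all[, , val_idx, , drop = FALSE])
        val_loss <- cross_entropy_loss(labels[val_idx], vp)
      }
      hist[[epoch]] <- data.frame(
        epoch = epoch,
        train_loss = ep_loss / length(ord),
        train_acc = ep_correct / length(ord),
        val_loss = val_loss)
      if (!is.na(val_loss)) {
        if (val_loss < best_val - 1e-8) {
          best_val <- val_loss; wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= config$early_stopping_patience) {
            hist <- hist[seq_len(epoch)]
            break
          }
        }
      }
    }
    model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
    model$epochs_trained <- nrow(model$history)
    model$best_val_loss <- if (is.finite(best_val)) best_val else NA_real_
  })
  model
}

#' Save / load a backbone checkpoint
#'
#' Checkpoints are a single versioned JSON file holding the architecture
#' descriptor, all parameters (including batch-norm running statistics), and
#' training metadata.
#'
#' @param model a [backbone_model()].
#' @param path file path for the checkpoint.
#' @return `path` invisibly (`save_checkpoint`); the restored model
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(model, path) {
  dump_layer <- function(ly) {
    out <- list(type = ly$type)
    for (p in c(layer_param_names(ly), "running_mean", "running_var")) {
      if (!is.null(ly[[p]])) {
        out[[p]] <- list(dim = dim(ly[[p]]) %||% length(ly[[p]]),
                         data = as.numeric(ly[[p]]))
      }
    }
    out
  }
  payload <- list(
    format = "rlsaliency-checkpoint", version = 1L,
    arch = model$arch,
    epochs_trained = model$epochs_trained,
    best_val_loss = model$best_val_loss,
    history = model$history,
    layers = lapply(model_layers(model), dump_layer))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) data_stop(sprintf("checkpoint '%s' not found", path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  if (!identical(payload$format, "rlsaliency-checkpoint")) {
    data_stop(sprintf("'%s' is not an rlsaliency checkpoint", path))
  }
  model <- backbone_model(payload$arch$input_shape, payload$arch$n_classes,
                          payload$arch$channels, seed = 0L)
  layers <- model_layers(model)
  stored <- payload$layers
  if (length(stored) != length(layers)) {
    data_stop("checkpoint layer count does not match the architecture")
  }
  for (i in seq_along(layers)) {
    ly <- layers[[i]]; st <- stored[[i]]
    for (p in c(layer_param_names(ly), "running_mean", "running_var")) {
      if (!is.null(st[[p]])) {
        v <- as.numeric(st[[p]]$data)
        dm <- as.integer(st[[p]]$dim)
        ly[[p]] <- if (length(dm) > 1L) array(v, dim = dm) else v
      }
    }
  }
  model$epochs_trained <- payload$epochs_trained %||% 0L
  model$best_val_loss <- payload$best_val_loss %||% NA_real_
  if (!is.null(payload$history) && length(payload$history) > 0) {
    model$history <- as.data.frame(payload$history)
  }
  model
}
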