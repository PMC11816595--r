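test_that("a residual block with a zeroed branch is the identity", {
  block <- rlsaliency:::residual_block(2L)
  block$conv1$W[] <- 0; block$conv1$b[] <- 0
  block$conv2$W[] <- 0; block$conv2$b[] <- 0
  set.seed(2)
  x <- array(stats::runif(4 * 4 * 2), dim = c(4, 4, 2))
  expect_identical(residual_forward(block, x), x)
})

test_that("the skip connection adds the branch output", {
  # hand-set branch computing the constant 0.5 on a 1x1x1 input
  block <- rlsaliency:::residual_block(1L)
  block$conv1$W[] <- 0; block$conv1$b[] <- 0
  block$conv2$W[] <- 0; block$conv2$b <- 0.5
  x <- array(2.0, dim = c(1, 1, 1))
  expect_equal(as.numeric(residual_forward(block, x)), 2.5, tolerance = 1e-12)

  # random input: branch evaluated separately, then added by hand
  block2 <- rlsaliency:::residual_block(2L)
  set.seed(3)
  x2 <- array(stats::runif(4 * 4 * 2), dim = c(4, 4, 1, 2))
  f <- rlsaliency:::residual_branch(block2, x2)
  expect_equal(residual_forward(block2, x2), x2 + f, tolerance = 1e-6)
})

test_that("attention weights are the sigmoid of the projection", {
  expect_equal(attention_weight(c(0, 0), c(1, 1)), 0.5)
  expect_gte(attention_weight(20, 1), 1 - 1e-8)
  expect_equal(attention_weight(c(0.3, 0.1), c(1, -1)),
               stats::plogis(0.2), tolerance = 1e-9)
  expect_equal(attention_weight(c(0.3, 0.1), c(1, -1)), 0.549834,
               tolerance = 1e-6)
  z <- attention_weight(stats::rnorm(5), stats::rnorm(5))
  expect_true(z > 0 && z < 1)
})

test_that("cross-entropy matches closed forms and rejects empty input", {
  expect_lte(cross_entropy_loss(1L, matrix(c(0, 1), 1)), 1e-11)
  expect_equal(cross_entropy_loss(1L, matrix(c(0.5, 0.5), 1)), log(2),
               tolerance = 1e-12)
  # batch of three, summed by hand
  probs <- rbind(c(0.1, 0.9), c(0.8, 0.2), c(0.3, 0.7))
  expect_equal(cross_entropy_loss(c(1L, 0L, 1L), probs),
               mean(-log(c(0.9, 0.8, 0.7))), tolerance = 1e-12)
  expect_equal(cross_entropy_loss(c(1L, 0L, 1L), probs), 0.2283930,
               tolerance = 1e-6)
  # categorical generalization beyond two classes
  p3 <- rbind(c(0.2, 0.5, 0.3), c(0.6, 0.2, 0.2))
  expect_equal(cross_entropy_loss(c(1L, 0L), p3),
               mean(-log(c(0.5, 0.6))), tolerance = 1e-12)
  expect_error(cross_entropy_loss(integer(0), matrix(0, 0, 2)), "empty")
})

test_that("predict_proba lies on the simplex and matches its logits", {
  model <- backbone_model(c(8L, 8L, 1L), 3L, channels = c(4L), seed = 5)
  img <- array(stats::runif(64), dim = c(8, 8, 1))
  p <- predict_proba(model, img)
  expect_length(p, 3L)
  # untrained zero-initialized head gives the uniform distribution
  expect_equal(p, rep(1 / 3, 3), tolerance = 1e-12)

  # after training the head is nonzero; probabilities = softmax(logits)
  model2 <- study_backbone()
  ds <- study_test_set()[1:5]
  for (s in ds) {
    p2 <- predict_proba(model2, s)
    expect_equal(sum(p2), 1, tolerance = 1e-6)
    expect_true(all(p2 >= 0))
    lg <- rlsaliency:::backbone_logits(
      model2, rlsaliency:::stack_images(list(s)))
    expect_equal(p2, as.numeric(exp(lg) / sum(exp(lg))), tolerance = 1e-9)
  }
  expect_error(predict_proba(model2, array(0.5, dim = c(4, 4, 1))), "shape")
})

test_that("attention gates of a live model stay strictly inside (0,1)", {
  model <- study_backbone()
  x <- rlsaliency:::stack_images(study_test_set()[1:4])
  for (st in model$net$stages) {
    x <- rlsaliency:::conv_forward(st$conv, x)
    x <- rlsaliency:::bn_forward(st$bn, x)
    x <- rlsaliency:::relu_forward(st$relu, x)
    x <- residual_forward(st$block, x)
  }
  z <- rlsaliency:::attention_gates(model$net$attention, x)
  expect_true(all(z > 0 & z < 1))
})

test_that("training honors the epoch budget, trends down and early-stops", {
  ds <- generate_synthetic_dataset(synthetic_spec(n_per_class = 6, seed = 31))
  model <- backbone_model(c(16L, 16L, 1L), 2L, seed = 8)

  un <- train_supervised(model, ds, train_config(max_epochs = 0L, seed = 1))
  expect_equal(nrow(un$history), 0L)
  expect_equal(predict_proba(un, ds[[1]]), rep(0.5, 2), tolerance = 1e-12)

  expect_error(train_supervised(model, ds[1:6], train_config(seed = 1)),
               "2 classes")

  # widely separated classes, zero noise: training reaches accuracy 1
  params <- list(
    list(radius_mean = 3, radius_sd = 0, intensity_mean = -0.4,
         intensity_sd = 0, center_jitter = 1),
    list(radius_mean = 3, radius_sd = 0, intensity_mean = 0.4,
         intensity_sd = 0, center_jitter = 1))
  sep <- generate_synthetic_dataset(
    synthetic_spec(n_per_class = 12, background = 0.5,
                   background_noise_sd = 0, seed = 33,
                   class_feature_params = params))
  m2 <- train_supervised(backbone_model(c(16L, 16L, 1L), 2L, seed = 9), sep,
                         train_config(max_epochs = 30L, batch_size = 8L,
                                      seed = 9))
  expect_equal(m2$history$train_acc[nrow(m2$history)], 1.0)
  expect_lt(m2$history$train_loss[nrow(m2$history)],
            m2$history$train_loss[1])

  # early stopping fires on a plateaued validation loss
  m3 <- train_supervised(
    backbone_model(c(16L, 16L, 1L), 2L, seed = 10), sep,
    train_config(max_epochs = 100L, early_stopping_patience = 2L,
                 batch_size = 8L, seed = 10))
  expect_lt(nrow(m3$history), 100L)
})

test_that("checkpoints round-trip the model exactly", {
  model <- study_backbone()
  path <- file.path(withr::local_tempdir(), "ckpt.json")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  img <- study_test_set()[[1]]
  expect_equal(predict_proba(back, img), predict_proba(model, img),
               tolerance = 1e-12)
  expect_equal(back$epochs_trained, model$epochs_trained)
  expect_error(load_checkpoint(file.path(tempdir(), "missing.json")),
               "not found")
})
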