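# Finite-difference check of the hand-written backpropagation. Perturbs a
# sample of entries in every parameter tensor and compares the analytic
# gradient against central differences.
check_gradients <- function(model, X, y_int, n_probe = 4, h = 1e-5, tol = 1e-4) {
  layers <- model$layers
  loss_fn <- function(ls) {
    set.seed(99)  # fix the dropout mask across evaluations
    gloriafall:::nn_loss_grads(ls, X, y_int, l2 = 0.01, training = TRUE)$loss
  }
  set.seed(99)
  res <- gloriafall:::nn_loss_grads(layers, X, y_int, l2 = 0.01, training = TRUE)
  worst <- 0
  for (l in seq_along(layers)) {
    g <- res$grads[[l]]
    if (is.null(g)) next
    for (pn in names(g)) {
      set.seed(1000 + l)
      idx <- sample(length(layers[[l]]$params[[pn]]),
                    min(n_probe, length(layers[[l]]$params[[pn]])))
      for (i in idx) {
        lp <- layers; lm <- layers
        lp[[l]]$params[[pn]][i] <- lp[[l]]$params[[pn]][i] + h
        lm[[l]]$params[[pn]][i] <- lm[[l]]$params[[pn]][i] - h
        num <- (loss_fn(lp) - loss_fn(lm)) / (2 * h)
        ana <- g[[pn]][i]
        # denominator floor 1e-3: a conv bias feeding batch norm has an
        # exactly-zero true gradient, where a pure relative error degenerates
        rel <- abs(num - ana) / max(1e-3, abs(num) + abs(ana))
        worst <- max(worst, rel)
      }
    }
  }
  expect_lt(worst, tol)
}

test_that("backpropagation matches finite differences (both architectures)", {
  ds <- tiny_dataset(8, window_length = 20L, seed = 2)
  y_int <- as.integer(ds$labels) - 1L
  for (arch in c("cnn", "cnn_bilstm")) {
    cfg <- classifier_config(architecture = arch,
                             conv_blocks = list(c(3, 5, 2), c(4, 3, 2)),
                             use_third_block = FALSE, dense_units = 6L,
                             dropout_rate = 0.3, lstm_units = 3L,
                             window_length = 20L, seed = 4L)
    model <- build_model(cfg)
    check_gradients(model, ds$windows, y_int)
  }
})

test_that("build_model shapes, probability contract and manifest", {
  model <- build_model(classifier_config(seed = 2))  # full 6 x 150 network
  ds <- simulate_motion_dataset(motion_dataset_spec(4, seed = 11))
  pred <- predict(model, ds$windows)
  expect_identical(dim(pred$probabilities), c(4L, 2L))
  expect_equal(rowSums(pred$probabilities), rep(1, 4), tolerance = 1e-6)
  expect_true(all(pred$probabilities >= 0 & pred$probabilities <= 1))

  # forward pass of zeros stays finite
  zeros <- array(0, c(6, 150, 2))
  expect_true(all(is.finite(predict(model, zeros)$probabilities)))

  # third block toggles exactly one conv block in the manifest
  m3 <- model_manifest(build_model(classifier_config(use_third_block = TRUE)))
  m2 <- model_manifest(build_model(classifier_config(use_third_block = FALSE)))
  expect_equal(sum(m3$type == "conv_time") - sum(m2$type == "conv_time"), 1)

  # pooling that exhausts the time axis fails at build time
  expect_error(build_model(classifier_config(
    conv_blocks = list(c(4, 9, 4), c(4, 3, 4)), window_length = 16L,
    use_third_block = FALSE)), "time axis")

  # the hybrid never has fewer parameters than the CNN at equal conv config
  expect_gte(count_parameters(build_model(classifier_config("cnn_bilstm"))),
             count_parameters(build_model(classifier_config("cnn"))))
})

test_that("training separates the synthetic classes and is reproducible", {
  ds <- tiny_dataset(80, seed = 8)
  norm <- normalize_windows(ds$windows, "per_channel_z")
  cfg <- tiny_classifier_config(seed = 3L)
  m1 <- train_classifier(build_model(cfg), norm, ds$labels)
  expect_gte(tail(m1$history$train_acc, 1), 0.98)

  # same seed, same data -> identical final loss and parameters
  m2 <- train_classifier(build_model(cfg), norm, ds$labels)
  expect_identical(tail(m1$history$train_loss, 1), tail(m2$history$train_loss, 1))

  # normalization stats travel with the model
  expect_false(is.null(m1$norm_stats))

  expect_error(train_classifier(build_model(cfg), norm,
                                rep("fall", 80)), "both classes")
})

test_that("prediction thresholds behave at the extremes", {
  ds <- tiny_dataset(30, seed = 21)
  norm <- normalize_windows(ds$windows, "per_channel_z")
  model <- train_classifier(build_model(tiny_classifier_config(seed = 6L)),
                            norm, ds$labels)
  expect_true(all(predict(model, ds$windows, threshold = 0)$labels == "fall"))
  expect_true(all(predict(model, ds$windows, threshold = 1)$labels == "no_fall"))

  # held-out windows from the same process classify almost perfectly
  ds_new <- tiny_dataset(40, seed = 77)
  pred <- predict(model, ds_new$windows)
  expect_gte(mean(pred$labels == ds_new$labels), 0.9)

  expect_error(predict(model, array(0, c(6, 99, 3))), "does not match")
})
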