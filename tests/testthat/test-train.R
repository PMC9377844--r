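test_that("binary cross-entropy matches its closed forms", {
  # all-0.5 predictions give log(2) regardless of the targets
  y <- matrix(c(1, 0, 1, 1), 2)
  expect_equal(binary_cross_entropy(y, matrix(0.5, 2, 2)), log(2))
  expect_equal(binary_cross_entropy(1 - y, matrix(0.5, 2, 2)), log(2))

  # single cell, y = 1, p = 0.5
  expect_equal(binary_cross_entropy(matrix(1), matrix(0.5)), log(2))

  # perfect prediction is (numerically) zero
  expect_lt(binary_cross_entropy(y, y), 1.1e-7)

  # moving p from 0.5 toward y strictly decreases the loss
  losses <- vapply(c(0.5, 0.7, 0.9, 0.99), function(p) {
    binary_cross_entropy(matrix(1), matrix(p))
  }, numeric(1))
  expect_true(all(diff(losses) < 0))

  expect_error(binary_cross_entropy(matrix(1), matrix(0.5, 2, 1)),
               "identical shapes")
})

test_that("early stopping keeps the best epoch and obeys patience", {
  # strictly improving validation loss never stops
  es <- es_init(patience = 3)
  for (e in 1:10) es <- es_update(es, e, 1 / e)
  expect_false(es$stop)
  expect_equal(es$best_epoch, 10L)

  # stops after `patience` epochs without improvement, keeping the best
  es <- es_init(patience = 3)
  losses <- c(0.5, 0.4, 0.41, 0.42, 0.43)
  for (e in seq_along(losses)) es <- es_update(es, e, losses[e])
  expect_true(es$stop)
  expect_equal(es$best_epoch, 2L)
  expect_equal(es$best, 0.4)

  expect_error(train_config(epochs = 5, patience = 10), "patience")
  expect_error(train_config(threshold = 1), "threshold")
})

test_that("training fits a separable synthetic task and is reproducible", {
  data <- prepared_synth(n = 240, seed = 42)
  cfg <- train_config(epochs = 6, batch_size = 64, learning_rate = 1e-3,
                      optimizer = "rmsprop", patience = 6, windowed = FALSE,
                      seed = 7)
  model <- build_mrf(canonical_mrf_config(length(data$classes)), seed = 7)
  fit <- train_mrf(model, data$train, data$val, cfg)

  # history bookkeeping
  expect_s3_class(fit$history, "tbl_df")
  expect_lte(nrow(fit$history), 6)
  expect_named(fit$history,
               c("epoch", "train_loss", "val_loss", "train_auc", "val_auc"))

  # first-epoch loss sits near the log(2) initialization anchor
  expect_lt(abs(fit$history$train_loss[1] - log(2)), 0.15)

  # the separable task is learned quickly
  expect_gt(max(fit$history$val_auc), 0.85)

  # returned weights are those of the best validation epoch
  expect_equal(fit$best_epoch, which.min(fit$history$val_loss))

  # broom/ggplot2 accessors work on the fitted object
  expect_identical(tidy(fit), fit$history)
  expect_equal(glance(fit)$best_epoch, fit$best_epoch)
  expect_s3_class(autoplot(fit), "ggplot")

  # bitwise reproducibility of the whole training run
  fit2 <- train_mrf(build_mrf(canonical_mrf_config(length(data$classes)),
                              seed = 7),
                    data$train, data$val, cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$params, fit2$params)

  # train/eval agreement with dropout disabled: predictions from the fitted
  # model are deterministic
  x <- records_to_array(data$test$records)
  expect_identical(predict_proba(fit, x), predict_proba(fit, x))

  expect_error(train_mrf(model, list(records = list(), labels = data$train$labels),
                         data$val, cfg), "empty")
})

test_that("grid search ranks cells deterministically and beats chance", {
  data <- prepared_synth(n = 200, seed = 13)
  grid_args <- list(model_config = tiny_mrf_config(length(data$classes)),
                    train = data$train, val = data$val,
                    batch_sizes = 16, learning_rates = c(1e-3, 1e-2),
                    optimizers = "adam", epochs = 4, seed = 3)
  r1 <- do.call(grid_search_mrf, grid_args)
  expect_equal(nrow(r1), 2)
  expect_true(all(diff(r1$best_val_loss) >= 0)) # ranked, argmin first

  # deterministic re-run returns the same ranking
  r2 <- do.call(grid_search_mrf, grid_args)
  expect_identical(r1, r2)

  # a 1-cell grid returns that cell
  r3 <- grid_search_mrf(tiny_mrf_config(length(data$classes)),
                        data$train, data$val, batch_sizes = 64,
                        learning_rates = 1e-3, optimizers = "adam",
                        epochs = 2, seed = 3)
  expect_equal(nrow(r3), 1)
  expect_equal(r3$batch_size, 64)

  # some cell outperforms a random-scores AUC baseline of about 0.5
  baseline <- withr::with_seed(5, {
    roc_auc(matrix(runif(prod(dim(data$val$labels))),
                   nrow(data$val$labels)), data$val$labels)$macro
  })
  expect_gt(max(r1$best_val_auc), baseline)

  expect_error(grid_search_mrf(tiny_mrf_config(2), data$train, data$val,
                               batch_sizes = numeric(), epochs = 1),
               "non-empty")
})

test_that("windowed training consumes the random-segment stream", {
  data <- prepared_synth(n = 120, seed = 21)
  cfg <- train_config(epochs = 2, batch_size = 32, learning_rate = 1e-3,
                      windowed = TRUE, patience = 2, seed = 4)
  fit <- train_mrf(build_mrf(tiny_mrf_config(length(data$classes)), seed = 4),
                   data$train, data$val, cfg)
  expect_equal(nrow(fit$history), 2)
  # windowed prediction: record-level rows, probabilities in [0, 1]
  p <- predict(fit, data$test$records, windowed = TRUE)
  expect_equal(nrow(p), length(data$test$records))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(colnames(p), data$classes)
  # binary predictions threshold strictly
  b <- predict(fit, data$test$records, windowed = TRUE, type = "binary")
  expect_true(all(b %in% c(0, 1)))
})
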