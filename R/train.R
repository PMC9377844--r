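#' Binary cross-entropy for multilabel targets
#'
#' Mean over all (record, label) cells of
#' `-(y log p + (1 - y) log(1 - p))`, with probabilities clipped to
#' `[eps, 1 - eps]` for numerical stability. With every prediction at 0.5 the
#' loss equals `log(2)` regardless of the targets — a useful initialization
#' anchor.
#'
#' @param targets Binary matrix (records x classes).
#' @param probabilities Matrix of predicted probabilities, same shape.
#' @param eps Clipping constant. Default 1e-7.
#' @return Non-negative scalar loss.
#' @examples
#' binary_cross_entropy(matrix(1), matrix(0.5)) # log(2)
#' @export
binary_cross_entropy <- function(targets, probabilities, eps = 1e-7) {
  if (!identical(dim(targets), dim(probabilities))) {
    abort("`targets` and `probabilities` must have identical shapes.")
  }
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  -mean(targets * log(p) + (1 - targets) * log(1 - p))
}

#' Training configuration
#'
#' @param epochs Maximum number of epochs. Default 100.
#' @param batch_size Minibatch size. Default 128.
#' @param learning_rate Step size. Default 1e-4.
#' @param optimizer One of `"rmsprop"`, `"adam"`, `"sgd"` (momentum 0.9).
#'   Default `"rmsprop"` — the grid-search optimum alongside batch 128 and
#'   learning rate 1e-4.
#' @param patience Early-stopping tolerance: training stops after this many
#'   epochs without a validation-loss improvement. Default 10.
#' @param threshold Decision threshold carried into evaluation. Default 0.5.
#' @param windowed Train on random fixed-length segments (`TRUE`) or whole
#'   records (`FALSE`).
#' @param window_s Training window length in seconds. Default 2.5.
#' @param seed Seed for shuffling, segment sampling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100, batch_size = 128, learning_rate = 1e-4,
                         optimizer = c("rmsprop", "adam", "sgd"),
                         patience = 10, threshold = 0.5, windowed = FALSE,
                         window_s = 2.5, seed = 1) {
  optimizer <- match.arg(optimizer)
  if (patience > epochs) abort("`patience` must not exceed `epochs`.")
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1).")
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, optimizer = optimizer,
         patience = as.integer(patience), threshold = threshold,
         windowed = isTRUE(windowed), window_s = window_s,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

# -- optimizers: slot-parallel updates over the named parameter list ---------

optimizer_init <- function(name, params) {
  zeros <- lapply(params, function(p) p * 0) # preserves each slot's shape
  switch(name,
         sgd = list(name = name, v = zeros),
         rmsprop = list(name = name, s = zeros),
         adam = list(name = name, m = zeros, v = zeros, t = 0L))
}

optimizer_step <- function(opt, params, grads, lr) {
  eps <- 1e-7
  if (opt$name == "sgd") {
    for (nm in names(params)) {
      opt$v[[nm]] <- 0.9 * opt$v[[nm]] - lr * grads[[nm]]
      params[[nm]] <- params[[nm]] + opt$v[[nm]]
    }
  } else if (opt$name == "rmsprop") {
    for (nm in names(params)) {
      opt$s[[nm]] <- 0.9 * opt$s[[nm]] + 0.1 * grads[[nm]]^2
      params[[nm]] <- params[[nm]] - lr * grads[[nm]] / sqrt(opt$s[[nm]] + eps)
    }
  } else {
    opt$t <- opt$t + 1L
    for (nm in names(params)) {
      opt$m[[nm]] <- 0.9 * opt$m[[nm]] + 0.1 * grads[[nm]]
      opt$v[[nm]] <- 0.999 * opt$v[[nm]] + 0.001 * grads[[nm]]^2
      mhat <- opt$m[[nm]] / (1 - 0.9^opt$t)
      vhat <- opt$v[[nm]] / (1 - 0.999^opt$t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(opt = opt, params = params)
}

# Macro AUC for monitoring; NA (rather than an error) when no label has both
# classes in the split, so degenerate toy splits still train.
safe_macro_auc <- function(scores, truth) {
  tryCatch(roc_auc(scores, truth)$macro, error = function(e) NA_real_)
}

# Early-stopping bookkeeping: tracks the best validation loss and how many
# epochs have passed since it improved.
es_init <- function(patience) {
  list(best = Inf, best_epoch = 0L, since = 0L, patience = patience,
       stop = FALSE)
}

es_update <- function(es, epoch, val_loss) {
  if (val_loss < es$best) {
    es$best <- val_loss
    es$best_epoch <- epoch
    es$since <- 0L
  } else {
    es$since <- es$since + 1L
    if (es$since >= es$patience) es$stop <- TRUE
  }
  es
}

#' Train an MRF-CNN
#'
#' Minimizes mean binary cross-entropy with the configured optimizer.
#' In windowed mode each training record contributes one uniformly placed
#' fixed-length segment per epoch (resampled every epoch); validation is
#' scored on the deterministic sliding-window grid with element-wise-maximum
#' aggregation to record level. In nonwindowed mode whole records are used
#' throughout. Early stopping monitors validation loss with the configured
#' patience, and the weights from the best validation epoch are returned.
#'
#' @param model An `mrf_model` from [build_mrf()].
#' @param train,val Lists with elements `records` (list of [ecg_record()])
#'   and `labels` (multihot matrix, classes in the model's column order).
#' @param config A [train_config()].
#' @param verbose Print one line per epoch to stderr.
#' @return The fitted `mrf_model`; `$history` holds a tibble with per-epoch
#'   train/validation loss and macro AUC, and `$best_epoch` the epoch whose
#'   weights were kept.
#' @export
train_mrf <- function(model, train, val, config = train_config(),
                      verbose = FALSE) {
  stopifnot(inherits(model, "mrf_model"), inherits(config, "train_config"))
  if (length(train$records) == 0) abort("Training split is empty.")
  if (ncol(train$labels) != model$config$classes) {
    abort("Label matrix width must match the model's class count.")
  }
  classes <- colnames(train$labels)
  n <- length(train$records)
  x_train_full <- if (config$windowed) NULL else records_to_array(train$records)
  if (config$windowed) {
    val_grid <- segment_dataset(val$records, window_s = config$window_s)
    val_ids <- vapply(val$records, `[[`, character(1), "id")
  } else {
    x_val <- records_to_array(val$records)
  }
  opt <- optimizer_init(config$optimizer, model$params)
  es <- es_init(config$patience)
  best_params <- model$params
  best_state <- model$state
  history <- vector("list", config$epochs)
  rng_seed <- derive_seed(config$seed, 101L)
  for (epoch in seq_len(config$epochs)) {
    epoch_seed <- derive_seed(rng_seed, epoch)
    x_epoch <- if (config$windowed) {
      sample_segments(train$records, window_s = config$window_s,
                      seed = epoch_seed)$segments
    } else {
      x_train_full
    }
    losses <- c()
    preds <- matrix(NA_real_, n, ncol(train$labels))
    withr::with_seed(epoch_seed, {
      ord <- sample.int(n)
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        xb <- x_epoch[, , idx, drop = FALSE]
        yb <- train$labels[idx, , drop = FALSE]
        fw <- mrf_forward(model$params, model$state, model$config, xb,
                          training = TRUE)
        model$state <- fw$state
        losses <- c(losses, binary_cross_entropy(yb, fw$probs))
        preds[idx, ] <- fw$probs
        dlogits <- (fw$probs - yb) / length(yb)
        grads <- mrf_backward(model$params, model$config, fw$cache, dlogits)
        step <- optimizer_step(opt, model$params, grads,
                               config$learning_rate)
        opt <- step$opt
        model$params <- step$params
      }
    })
    train_loss <- mean(losses)
    train_auc <- safe_macro_auc(preds, train$labels)
    if (config$windowed) {
      seg_probs <- predict_proba(model, val_grid$segments)
      val_probs <- aggregate_predictions(seg_probs, val_grid$origin)
      val_probs <- val_probs[val_ids, , drop = FALSE]
    } else {
      val_probs <- predict_proba(model, x_val)
    }
    val_loss <- binary_cross_entropy(val$labels, val_probs)
    val_auc <- safe_macro_auc(val_probs, val$labels)
    history[[epoch]] <- tibble(epoch = epoch, train_loss = train_loss,
                               val_loss = val_loss, train_auc = train_auc,
                               val_auc = val_auc)
    if (verbose) {
      message(sprintf(
        "epoch %3d  train loss %.4f auc %.4f | val loss %.4f auc %.4f",
        epoch, train_loss, train_auc, val_loss, val_auc))
    }
    es <- es_update(es, epoch, val_loss)
    if (es$best_epoch == epoch) {
      best_params <- model$params
      best_state <- model$state
    }
    if (es$stop) break
  }
  model$params <- best_params
  model$state <- best_state
  model$history <- dplyr::bind_rows(history)
  model$best_epoch <- es$best_epoch
  model$train_config <- config
  attr(model, "classes") <- classes
  model
}

#' Hyperparameter grid search
#'
#' Trains one model per cell of the Cartesian grid on identical data and
#' seed, ranking cells by their best validation loss. The published search
#' space is batch sizes \{16, 32, 64, 128, 256\}, learning rates \{1e-2,
#' 1e-3, 1e-4, 1e-5\} and optimizers \{Adam, SGD, RMSProp\}.
#'
#' @param model_config An `mrf_config` used to build a fresh model per cell.
#' @param train,val Data as in [train_mrf()].
#' @param batch_sizes,learning_rates,optimizers Grid axes (non-empty).
#' @param epochs Training budget per cell.
#' @param seed Shared seed for every cell.
#' @param windowed Passed to [train_config()].
#' @return A tibble ranked by best validation loss (then AUC), one row per
#'   cell, with the winning cell first.
#' @export
grid_search_mrf <- function(model_config, train, val,
                            batch_sizes = c(16, 32, 64, 128, 256),
                            learning_rates = c(1e-2, 1e-3, 1e-4, 1e-5),
                            optimizers = c("adam", "sgd", "rmsprop"),
                            epochs = 100, seed = 1, windowed = FALSE) {
  if (!length(batch_sizes) || !length(learning_rates) || !length(optimizers)) {
    abort("All grid axes must be non-empty.")
  }
  grid <- expand.grid(batch_size = batch_sizes,
                      learning_rate = learning_rates,
                      optimizer = optimizers, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- train_config(epochs = epochs, batch_size = grid$batch_size[i],
                        learning_rate = grid$learning_rate[i],
                        optimizer = grid$optimizer[i],
                        patience = min(10, epochs), windowed = windowed,
                        seed = seed)
    fit <- train_mrf(build_mrf(model_config, seed = seed), train, val, cfg)
    best <- fit$history[which.min(fit$history$val_loss), ]
    tibble(batch_size = grid$batch_size[i],
           learning_rate = grid$learning_rate[i],
           optimizer = grid$optimizer[i],
           best_val_loss = best$val_loss, best_val_auc = best$val_auc,
           best_epoch = best$epoch, epochs_run = nrow(fit$history))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$best_val_loss, dplyr::desc(.data$best_val_auc))
}
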