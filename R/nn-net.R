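#' Build (initialize) an MRF-CNN model
#'
#' Allocates the network weights for an [mrf_config()]: He-style Gaussian
#' initialization for convolution and hidden dense weights, a small Gaussian
#' for the output layer, zero biases, and unit-gain batch normalization.
#'
#' @param config An `mrf_config`.
#' @param seed Integer seed for the weight draw.
#' @return An object of class `mrf_model`: the config, a named parameter
#'   list, the batch-norm moving statistics, and (after [train_mrf()]) the
#'   training history.
#' @examples
#' m <- build_mrf(canonical_mrf_config(5), seed = 1)
#' @export
build_mrf <- function(config, seed = 1) {
  stopifnot(inherits(config, "mrf_config"))
  br <- config$branches
  params <- list()
  state <- list()
  with_seed(derive_seed(seed, 3L), {
    c_in <- config$leads
    for (b in 1:5) {
      f <- config$filters[b]
      r <- config$reductions[b]
      for (i in 1:5) {
        k <- br$kernel[i]
        params[[sprintf("b%d_conv%d_W", b, i)]] <-
          array(rnorm(f * c_in * k, sd = sqrt(2 / (c_in * k))), c(f, c_in, k))
        params[[sprintf("b%d_conv%d_b", b, i)]] <- numeric(f)
      }
      params[[sprintf("b%d_red_W", b)]] <-
        matrix(rnorm(r * 5 * f, sd = sqrt(2 / (5 * f))), r, 5 * f)
      params[[sprintf("b%d_red_b", b)]] <- numeric(r)
      params[[sprintf("b%d_bn_gamma", b)]] <- rep(1, r)
      params[[sprintf("b%d_bn_beta", b)]] <- numeric(r)
      state[[sprintf("b%d_bn_mean", b)]] <- numeric(r)
      state[[sprintf("b%d_bn_var", b)]] <- rep(1, r)
      c_in <- r
    }
    params$fc1_W <- matrix(rnorm(config$dense * c_in, sd = sqrt(2 / c_in)),
                           config$dense, c_in)
    params$fc1_b <- numeric(config$dense)
    params$out_W <- matrix(rnorm(config$classes * config$dense,
                                 sd = sqrt(1 / config$dense)),
                           config$classes, config$dense)
    params$out_b <- numeric(config$classes)
  })
  structure(
    list(config = config, params = params, state = state, history = NULL),
    class = "mrf_model"
  )
}

#' @export
print.mrf_model <- function(x, ...) {
  p <- count_params(x$config)
  cat(sprintf("<mrf_model> %d classes, %d parameters (%s)\n",
              x$config$classes, p$total,
              if (is.null(x$history)) "untrained" else "trained"))
  invisible(x)
}

# Full forward pass. `x` is a (leads, L, batch) array. Returns sigmoid
# probabilities (batch x classes) plus the caches backprop needs.
mrf_forward <- function(params, state, config, x, training = FALSE,
                        keep_cache = training) {
  d <- dim(x)
  if (d[1] != config$leads) {
    abort(sprintf("Input has %d leads; the model expects %d.",
                  d[1], config$leads))
  }
  if (d[2] %/% 32L < 1L) {
    abort(sprintf(
      "Input length %d too short for 5 pooling halvings (need >= 32).", d[2]))
  }
  br <- config$branches
  cache <- if (keep_cache) vector("list", 5L) else NULL
  for (b in 1:5) {
    branch_out <- vector("list", 5L)
    branch_cache <- if (keep_cache) vector("list", 5L) else NULL
    L <- dim(x)[2]
    B <- dim(x)[3]
    for (i in 1:5) {
      cv <- conv1d_fwd(x, params[[sprintf("b%d_conv%d_W", b, i)]],
                       params[[sprintf("b%d_conv%d_b", b, i)]],
                       br$dilation[i])
      branch_out[[i]] <- mat3(cv$out)
      if (keep_cache) branch_cache[[i]] <- cv$cache
    }
    conc <- do.call(rbind, branch_out)
    red <- params[[sprintf("b%d_red_W", b)]] %*% conc +
      params[[sprintf("b%d_red_b", b)]]
    bn <- bn_fwd(arr3(red, L, B),
                 params[[sprintf("b%d_bn_gamma", b)]],
                 params[[sprintf("b%d_bn_beta", b)]],
                 state[[sprintf("b%d_bn_mean", b)]],
                 state[[sprintf("b%d_bn_var", b)]], training)
    if (training) {
      state[[sprintf("b%d_bn_mean", b)]] <- bn$run_mean
      state[[sprintf("b%d_bn_var", b)]] <- bn$run_var
    }
    act <- leaky_fwd(bn$out, config$slope)
    pool <- maxpool_fwd(act$out)
    drop <- dropout_fwd(pool$out,
                        if (config$kinds[b] == "small") config$dropout else 0,
                        training)
    if (keep_cache) {
      cache[[b]] <- list(branches = branch_cache, conc = conc, bn = bn$cache,
                         act = act$cache, pool = pool$cache,
                         drop = drop$cache)
    }
    x <- drop$out
  }
  gap <- gap_fwd(x)
  fc1 <- dense_fwd(gap$out, params$fc1_W, params$fc1_b)
  act1 <- leaky_fwd(fc1$out, config$slope)
  out <- dense_fwd(act1$out, params$out_W, params$out_b)
  probs <- sigmoid(out$out) # (classes, batch)
  if (keep_cache) {
    cache$head <- list(gap = gap$cache, fc1 = fc1$cache, act1 = act1$cache,
                       out = out$cache)
  }
  list(probs = t(probs), logits = t(out$out), cache = cache, state = state)
}

# Backward pass from d(loss)/d(logits) (batch x classes). Returns gradients
# for every parameter, in the layout of `params`.
mrf_backward <- function(params, config, cache, dlogits) {
  grads <- list()
  dz <- t(dlogits) # (classes, batch)
  hb <- cache$head
  d_out <- dense_bwd(dz, params$out_W, hb$out)
  grads$out_W <- d_out$dW
  grads$out_b <- d_out$db
  da1 <- leaky_bwd(d_out$dx, hb$act1)
  d_fc1 <- dense_bwd(da1, params$fc1_W, hb$fc1)
  grads$fc1_W <- d_fc1$dW
  grads$fc1_b <- d_fc1$db
  dx <- gap_bwd(d_fc1$dx, hb$gap)
  for (b in 5:1) {
    cb <- cache[[b]]
    dx <- dropout_bwd(dx, cb$drop)
    dx <- maxpool_bwd(dx, cb$pool)
    dx <- leaky_bwd(dx, cb$act)
    bn <- bn_bwd(dx, cb$bn)
    grads[[sprintf("b%d_bn_gamma", b)]] <- bn$dgamma
    grads[[sprintf("b%d_bn_beta", b)]] <- bn$dbeta
    dred <- mat3(bn$dx)
    W_red <- params[[sprintf("b%d_red_W", b)]]
    grads[[sprintf("b%d_red_W", b)]] <- dred %*% t(cb$conc)
    grads[[sprintf("b%d_red_b", b)]] <- rowSums(dred)
    dconc <- t(W_red) %*% dred
    f <- config$filters[b]
    dx <- NULL
    for (i in 1:5) {
      rows <- (i - 1L) * f + seq_len(f)
      dyi <- dconc[rows, , drop = FALSE]
      dims <- cb$branches[[i]]$dims
      cv <- conv1d_bwd(arr3(dyi, dims[2], dims[3]),
                       params[[sprintf("b%d_conv%d_W", b, i)]],
                       cb$branches[[i]])
      grads[[sprintf("b%d_conv%d_W", b, i)]] <- cv$dW
      grads[[sprintf("b%d_conv%d_b", b, i)]] <- cv$db
      dx <- if (is.null(dx)) cv$dx else dx + cv$dx
    }
  }
  grads
}

# Forward in chunks with dropout off and frozen batch-norm statistics.
predict_proba <- function(model, x, batch_size = 256) {
  d <- dim(x)
  out <- matrix(NA_real_, d[3], model$config$classes)
  for (start in seq(1, d[3], by = batch_size)) {
    idx <- start:min(start + batch_size - 1, d[3])
    fw <- mrf_forward(model$params, model$state, model$config,
                      x[, , idx, drop = FALSE], training = FALSE,
                      keep_cache = FALSE)
    out[idx, ] <- fw$probs
  }
  out
}

#' Predict class probabilities for ECG records
#'
#' @param object A trained (or freshly built) `mrf_model`.
#' @param newdata A list of [ecg_record()] objects, a `segment_batch`, or a
#'   `(leads, length, n)` array.
#' @param windowed If `TRUE`, records are cut on the 2.5 s / 50%-overlap
#'   sliding-window grid, scored per segment, and aggregated to record level
#'   by the element-wise maximum. If `FALSE`, whole records are scored in one
#'   pass.
#' @param window_s,overlap Sliding-window geometry for `windowed = TRUE`.
#' @param type `"prob"` for probabilities, `"binary"` for thresholded
#'   multihot predictions (strictly greater than `threshold`).
#' @param threshold Decision threshold for `type = "binary"`. Default 0.5.
#' @param batch_size Forward-pass chunk size.
#' @param ... Unused.
#' @return A numeric `records x classes` matrix.
#' @export
predict.mrf_model <- function(object, newdata, windowed = FALSE,
                              window_s = 2.5, overlap = 0.5,
                              type = c("prob", "binary"), threshold = 0.5,
                              batch_size = 256, ...) {
  type <- match.arg(type)
  if (windowed) {
    if (!inherits(newdata, "segment_batch")) {
      newdata <- segment_dataset(newdata, window_s = window_s,
                                 overlap = overlap)
    }
    probs <- predict_proba(object, newdata$segments, batch_size)
    probs <- aggregate_predictions(probs, newdata$origin)
  } else {
    ids <- NULL
    if (inherits(newdata, "segment_batch")) {
      ids <- newdata$origin
      newdata <- newdata$segments
    } else if (is.list(newdata) && !is.array(newdata)) {
      ids <- vapply(newdata, `[[`, character(1), "id")
      newdata <- records_to_array(newdata)
    }
    probs <- predict_proba(object, newdata, batch_size)
    rownames(probs) <- ids
  }
  colnames(probs) <- attr(object, "classes") %||% colnames(probs)
  if (type == "binary") binarize(probs, threshold) else probs
}

# Stack equally shaped records into a (leads, length, n) array.
records_to_array <- function(records) {
  d <- dim(records[[1]]$signal)
  array(unlist(lapply(records, `[[`, "signal"), use.names = FALSE),
        dim = c(d[1], d[2], length(records)))
}
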