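# Layer primitives for the 1D CNN. Activations are stored as arrays of
# dimension (channels, length, batch); a (C, L*B) matrix view of the same
# memory is used for BLAS products. Every *_fwd returns the output plus the
# cache its *_bwd needs; gradients are exact (verified against finite
# differences in the test suite).

mat3 <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1], d[2] * d[3])
  x
}

arr3 <- function(x, L, B) {
  dim(x) <- c(nrow(x), L, B)
  x
}

# -- dilated 1D convolution, "same" padding (odd kernels only) ---------------

conv1d_fwd <- function(x, W, b, dilation) {
  d <- dim(x) # (C_in, L, B)
  k <- dim(W)[3]
  P <- dilation * (k - 1) / 2
  if (P > 0) {
    xp <- array(0, c(d[1], d[2] + 2 * P, d[3]))
    xp[, P + seq_len(d[2]), ] <- x
  } else {
    xp <- x
  }
  y <- matrix(0, dim(W)[1], d[2] * d[3])
  for (j in seq_len(k)) {
    o <- (j - 1) * dilation
    xs <- xp[, o + seq_len(d[2]), , drop = FALSE]
    dim(xs) <- c(d[1], d[2] * d[3])
    y <- y + W[, , j] %*% xs
  }
  y <- y + b
  list(out = arr3(y, d[2], d[3]),
       cache = list(xp = xp, dims = d, k = k, dilation = dilation, P = P))
}

conv1d_bwd <- function(dy, W, cache) {
  d <- cache$dims
  dy <- mat3(dy) # (C_out, L*B)
  dW <- array(0, dim(W))
  dxp <- array(0, dim(cache$xp))
  for (j in seq_len(cache$k)) {
    o <- (j - 1) * cache$dilation
    idx <- o + seq_len(d[2])
    xs <- cache$xp[, idx, , drop = FALSE]
    dim(xs) <- c(d[1], d[2] * d[3])
    dW[, , j] <- dy %*% t(xs)
    dxp[, idx, ] <- dxp[, idx, ] + arr3(t(W[, , j]) %*% dy, d[2], d[3])
  }
  dx <- if (cache$P > 0) dxp[, cache$P + seq_len(d[2]), , drop = FALSE] else dxp
  dim(dx) <- d
  list(dx = dx, dW = dW, db = rowSums(dy))
}

# -- batch normalization (per channel over length x batch) -------------------

bn_fwd <- function(x, gamma, beta, run_mean, run_var, training,
                   eps = 1e-5, momentum = 0.1) {
  d <- dim(x)
  xm <- mat3(x)
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    v <- pmax(v, 0)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * invstd
  y <- gamma * xhat + beta
  list(out = arr3(y, d[2], d[3]), run_mean = run_mean, run_var = run_var,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma, dims = d,
                    training = training))
}

bn_bwd <- function(dy, cache) {
  d <- cache$dims
  dy <- mat3(dy)
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  if (cache$training) {
    dx <- (cache$gamma * cache$invstd) *
      (dy - rowMeans(dy) - cache$xhat * rowMeans(dy * cache$xhat))
  } else {
    dx <- (cache$gamma * cache$invstd) * dy
  }
  list(dx = arr3(dx, d[2], d[3]), dgamma = dgamma, dbeta = dbeta)
}

# -- leaky rectifier ---------------------------------------------------------

leaky_fwd <- function(x, slope) {
  scale <- slope + (1 - slope) * (x > 0)
  list(out = x * scale, cache = scale)
}

leaky_bwd <- function(dy, cache) {
  dy * cache
}

# -- max pooling, window = stride = 2, floor semantics on odd widths ---------

maxpool_fwd <- function(x) {
  d <- dim(x)
  L2 <- d[2] %/% 2
  a <- x[, seq(1, 2 * L2 - 1, by = 2), , drop = FALSE]
  b <- x[, seq(2, 2 * L2, by = 2), , drop = FALSE]
  first <- a >= b # ties route to the first element
  list(out = pmax(a, b), cache = list(first = first, dims = d, L2 = L2))
}

maxpool_bwd <- function(dy, cache) {
  d <- cache$dims
  dx <- array(0, d)
  dx[, seq(1, 2 * cache$L2 - 1, by = 2), ] <- dy * cache$first
  dx[, seq(2, 2 * cache$L2, by = 2), ] <- dy * !cache$first
  dx
}

# -- inverted dropout --------------------------------------------------------

dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) {
    return(list(out = x, cache = NULL))
  }
  mask <- array(stats::rbinom(length(x), 1L, 1 - p) / (1 - p), dim(x))
  list(out = x * mask, cache = mask)
}

dropout_bwd <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

# -- global average pooling over the temporal axis ---------------------------

gap_fwd <- function(x) {
  d <- dim(x)
  y <- matrix(0, d[1], d[3])
  for (l in seq_len(d[2])) y <- y + matrix(x[, l, ], d[1], d[3])
  list(out = y / d[2], cache = d)
}

gap_bwd <- function(dy, cache) {
  d <- cache
  dx <- array(0, d)
  g <- dy / d[2]
  for (l in seq_len(d[2])) dx[, l, ] <- g
  dx
}

# -- dense -------------------------------------------------------------------

dense_fwd <- function(x, W, b) {
  list(out = W %*% x + b, cache = x)
}

dense_bwd <- function(dy, W, cache) {
  list(dx = t(W) %*% dy, dW = dy %*% t(cache), db = rowSums(dy))
}

sigmoid <- function(z) 1 / (1 + exp(-z))
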