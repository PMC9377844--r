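# Internal helpers shared across modules.

# Deterministic sub-seed derivation: keeps every stream reproducible from one
# user-facing seed while avoiding correlated streams. Result is always a valid
# 32-bit seed.
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  x <- (as.double(seed) %% 2147483647) + 1
  for (k in c(index, 97L)) {
    x <- (x * 48271 + as.double(k) * 16807) %% 2147483647
  }
  as.integer(x)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

is_binary_matrix <- function(m) {
  is.matrix(m) && is.numeric(m) && all(m %in% c(0, 1))
}

# Largest-remainder apportionment of n into parts proportional to `fractions`.
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
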