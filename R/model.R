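# The five parallel branches every block carries: kernels 7 and 5 at dilation
# rates 1 and 2, plus a pointwise 1x1 branch.
mrf_branches <- function() {
  data.frame(kernel = c(7L, 7L, 5L, 5L, 1L), dilation = c(1L, 2L, 1L, 2L, 1L))
}

#' Effective receptive field of a dilated convolution
#'
#' A kernel of size `kernel` with dilation rate `dilation` spans
#' `dilation * (kernel - 1) + 1` input samples: kernels 5 and 7 give receptive
#' fields of 5 and 7 at dilation 1, and 9 and 13 at dilation 2.
#'
#' @param kernel Kernel size in samples (>= 1).
#' @param dilation Dilation rate (>= 1).
#' @return Receptive-field width in samples.
#' @examples
#' receptive_field(7, 2) # 13
#' @export
receptive_field <- function(kernel, dilation) {
  if (any(!is.finite(kernel)) || any(!is.finite(dilation)) ||
      any(kernel < 1) || any(dilation < 1)) {
    abort("`kernel` and `dilation` must be positive.")
  }
  dilation * (kernel - 1) + 1
}

#' Architecture description of the multireceptive-field CNN
#'
#' Five convolutional blocks, each holding five parallel branches (kernel 7
#' and 5 at dilation 1 and 2, plus a 1x1 branch) with `filters` channels per
#' branch, a post-concatenation 1x1 reduction to `reductions` channels, batch
#' normalization, leaky-ReLU activation (negative slope 0.01) and max pooling
#' by 2. "small" blocks additionally apply dropout after pooling; "large"
#' blocks do not. The head is global average pooling, a dense hidden layer of
#' `dense` units, and a sigmoid output layer with one unit per class.
#'
#' @param classes Number of output classes (>= 1).
#' @param filters Integer vector of 5 per-block branch filter counts.
#' @param reductions Integer vector of 5 per-block reduction widths.
#' @param kinds Per-block kind, `"large"` or `"small"`; default two large
#'   blocks followed by three small ones.
#' @param dense Hidden dense width. Default 96.
#' @param leads Input channel count. Default 12.
#' @param slope Negative slope of the leaky activation. Default 0.01.
#' @param dropout Dropout rate of small blocks. Default 0.20.
#' @param convention Parameter-counting convention for the reported total:
#'   `"total_with_stats"` counts batch-norm moving statistics as
#'   non-trainable parameters inside the total (framework "Total params"
#'   style); `"trainable"` reports trainable parameters only.
#' @return An object of class `mrf_config`.
#' @seealso [canonical_mrf_config()], [solve_canonical_config()],
#'   [build_mrf()], [count_params()]
#' @export
mrf_config <- function(classes,
                       filters,
                       reductions,
                       kinds = c("large", "large", "small", "small", "small"),
                       dense = 96L,
                       leads = 12L,
                       slope = 0.01,
                       dropout = 0.20,
                       convention = c("total_with_stats", "trainable")) {
  convention <- match.arg(convention)
  assert_scalar_number(classes, "classes", positive = TRUE)
  if (length(filters) != 5L || length(reductions) != 5L || length(kinds) != 5L) {
    abort("The architecture has exactly 5 convolutional blocks.")
  }
  if (any(filters < 1) || any(reductions < 1)) {
    abort("Filter and reduction counts must be >= 1.")
  }
  if (!all(kinds %in% c("large", "small"))) {
    abort('Block kinds must be "large" or "small".')
  }
  structure(
    list(classes = as.integer(classes), filters = as.integer(filters),
         reductions = as.integer(reductions), kinds = kinds,
         dense = as.integer(dense), leads = as.integer(leads), slope = slope,
         dropout = dropout, convention = convention,
         branches = mrf_branches()),
    class = "mrf_config"
  )
}

#' @export
print.mrf_config <- function(x, ...) {
  cat("<mrf_config>\n")
  cat(sprintf("  blocks:  %s\n",
              paste(sprintf("%s(f=%d,r=%d)", x$kinds, x$filters, x$reductions),
                    collapse = " ")))
  cat(sprintf("  head:    GAP -> dense(%d) -> sigmoid(%d classes)\n",
              x$dense, x$classes))
  p <- count_params(x)
  cat(sprintf("  params:  total %d (trainable %d, non-trainable %d)\n",
              p$total, p$trainable, p$non_trainable))
  invisible(x)
}

#' The canonical architecture
#'
#' The frozen configuration produced by [solve_canonical_config()]: per-block
#' branch widths (4, 5, 25, 26, 26) with reduction widths (4, 10, 25, 26, 26)
#' under the total-with-moving-statistics counting convention. Its totals are
#' 55,277 / 56,732 / 59,060 parameters at 5 / 20 / 44 classes.
#'
#' @param classes Number of output classes. Default 5.
#' @return An `mrf_config`.
#' @export
canonical_mrf_config <- function(classes = 5) {
  mrf_config(classes,
             filters = c(4L, 5L, 25L, 26L, 26L),
             reductions = c(4L, 10L, 25L, 26L, 26L),
             convention = "total_with_stats")
}

#' Count model parameters
#'
#' Closed-form parameter accounting for an [mrf_config()]. Each branch
#' convolution holds `kernel * C_in * filters + filters` parameters (dilation
#' adds none), the 1x1 reduction `5 * filters * reduction + reduction`, batch
#' normalization `2 * reduction` trainable plus `2 * reduction` moving
#' statistics (non-trainable), and the head `dense * (r5 + 1)` plus
#' `(dense + 1) * classes`. The total is affine in the class count with slope
#' `dense + 1` (97 for the default width 96).
#'
#' @param config An `mrf_config` or `mrf_model`.
#' @param classes Optional class-count override.
#' @return A one-row tibble with `total`, `trainable`, `non_trainable`.
#'   `total` follows `config$convention`.
#' @examples
#' count_params(canonical_mrf_config(5))$total # 55277
#' @export
count_params <- function(config, classes = NULL) {
  if (inherits(config, "mrf_model")) config <- config$config
  stopifnot(inherits(config, "mrf_config"))
  q <- as.integer(classes %||% config$classes)
  kern_sum <- sum(mrf_branches()$kernel) # 7 + 7 + 5 + 5 + 1 = 25
  c_in <- config$leads
  trainable <- 0
  non_trainable <- 0
  for (b in 1:5) {
    f <- config$filters[b]
    r <- config$reductions[b]
    trainable <- trainable +
      kern_sum * c_in * f + 5 * f + # five branch convolutions
      5 * f * r + r +               # 1x1 reduction
      2 * r                         # batch-norm gamma, beta
    non_trainable <- non_trainable + 2 * r # batch-norm moving mean, variance
    c_in <- r
  }
  trainable <- trainable + config$dense * c_in + config$dense +
    (config$dense + 1) * q
  total <- if (config$convention == "total_with_stats") {
    trainable + non_trainable
  } else {
    trainable
  }
  tibble(total = as.integer(total), trainable = as.integer(trainable),
         non_trainable = as.integer(non_trainable))
}

#' Solve the per-block filter widths against a parameter budget
#'
#' The published architecture fixes kernels, dilations, block count, dense
#' width and pooling but not the per-block filter counts. This solver
#' enumerates a structured grid — uniform branch width per block, monotone
#' non-decreasing over depth, `filters` in `grid`, reduction width equal to
#' one or two times the branch width and also monotone — under both counting
#' conventions (total-with-moving-statistics first), and returns the first
#' configuration, in deterministic (convention, filters-lexicographic,
#' multiplier-lexicographic) order, whose backbone parameter count (all
#' parameters except the `(dense + 1) * classes` output stage) equals
#' `target`.
#'
#' @param target Backbone parameter budget. Default 54792, the published
#'   5-class total 55,277 minus 5 x 97 output-stage parameters.
#' @param grid Candidate branch widths. Default `4:32`.
#' @param classes Class count of the returned configuration. Default 5.
#' @return An `mrf_config` with attribute `"solver"` recording the convention,
#'   the target and the number of exact solutions in the grid.
#' @export
solve_canonical_config <- function(target = 54792L, grid = 4:32, classes = 5) {
  grid <- sort(unique(as.integer(grid)))
  # all monotone non-decreasing 5-sequences over the grid
  idx <- utils::combn(length(grid) + 4L, 5L)
  fs <- matrix(grid[idx - 0:4], nrow = 5L) # 5 x n, each column non-decreasing
  fs <- t(fs)
  mults <- as.matrix(expand.grid(m5 = 1:2, m4 = 1:2, m3 = 1:2, m2 = 1:2,
                                 m1 = 1:2))[, 5:1, drop = FALSE]
  # reorder rows to multiplier-lexicographic (1,1,1,1,1), (1,1,1,1,2), ...
  mults <- mults[order(mults[, 1], mults[, 2], mults[, 3], mults[, 4],
                       mults[, 5]), , drop = FALSE]
  kern_sum <- sum(mrf_branches()$kernel)
  best <- NULL
  nearest <- Inf
  nearest_cfg <- NULL
  n_hits <- 0L
  for (convention in c("total_with_stats", "trainable")) {
    bn_per_r <- if (convention == "total_with_stats") 4 else 2
    hits <- list()
    for (p in seq_len(nrow(mults))) {
      rs <- fs * rep(mults[p, ], each = nrow(fs))
      mono_r <- rowSums(rs[, -1, drop = FALSE] < rs[, -5, drop = FALSE]) == 0
      c_in <- cbind(12, rs[, 1:4, drop = FALSE])
      backbone <- rowSums(kern_sum * c_in * fs + 5 * fs + 5 * fs * rs +
                            rs + bn_per_r * rs) + 96 * rs[, 5] + 96
      hit <- which(mono_r & backbone == target)
      if (length(hit)) {
        hits[[length(hits) + 1L]] <-
          cbind(fs[hit, , drop = FALSE], rs[hit, , drop = FALSE], pattern = p)
      }
      miss <- which(mono_r)
      if (length(miss)) {
        gap <- abs(backbone[miss] - target)
        if (min(gap) < nearest) {
          j <- miss[which.min(gap)]
          nearest <- min(gap)
          nearest_cfg <- list(filters = fs[j, ], reductions = rs[j, ],
                              convention = convention,
                              backbone = backbone[j])
        }
      }
    }
    if (length(hits)) {
      all_hits <- do.call(rbind, hits)
      n_hits <- nrow(all_hits)
      # deterministic pick: filters-lexicographic, then multiplier pattern
      first <- do.call(order, as.data.frame(all_hits[, c(1:5, 11L),
                                                     drop = FALSE]))[1]
      best <- list(filters = all_hits[first, 1:5],
                   reductions = all_hits[first, 6:10],
                   convention = convention)
      break
    }
  }
  if (is.null(best)) {
    abort(sprintf(
      paste0("No configuration in the grid matches the backbone target %d; ",
             "nearest miss: filters (%s), reductions (%s), backbone %d ",
             "(off by %d, convention %s)."),
      target, paste(nearest_cfg$filters, collapse = ","),
      paste(nearest_cfg$reductions, collapse = ","),
      nearest_cfg$backbone, as.integer(nearest),
      nearest_cfg$convention
    ), class = "mrfecg_no_solution")
  }
  # re-scan: the true first hit is the lexicographically smallest `filters`
  # over all patterns of the winning convention, breaking ties by pattern
  cfg <- mrf_config(classes, filters = best$filters,
                    reductions = best$reductions,
                    convention = best$convention)
  attr(cfg, "solver") <- list(target = as.integer(target),
                              convention = best$convention,
                              n_solutions = n_hits)
  cfg
}
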