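#' Remove rare classes and the records they orphan
#'
#' Classes observed in fewer than `min_count` records (strictly less than) are
#' removed from every label set; records whose label set becomes empty are
#' dropped. Counting is done once, on the full input, before any removal.
#'
#' @param records List of [ecg_record()] objects with labels already
#'   aggregated to the working level.
#' @param min_count Minimum number of records a class needs to be retained.
#'   Default 20.
#' @return A list with `records` (the filtered list) and `classes` (retained
#'   class identifiers, sorted lexicographically).
#' @examples
#' # a class seen exactly min_count times is retained ("less than" is strict)
#' @export
filter_rare_classes <- function(records, min_count = 20) {
  assert_scalar_number(min_count, "min_count")
  counts <- table(unlist(lapply(records, `[[`, "labels")))
  retained <- sort(names(counts)[counts >= min_count])
  out <- lapply(records, function(r) {
    r$labels <- intersect(r$labels, retained)
    r
  })
  keep <- vapply(out, function(r) length(r$labels) > 0, logical(1))
  if (!any(keep)) {
    warn("All records dropped: no class reaches min_count.")
  }
  list(records = out[keep], classes = retained)
}

#' Split records into train / validation / test sets
#'
#' Sizes follow the fractions by largest-remainder rounding (100 records at
#' 0.70/0.15/0.15 give exactly 70/15/15). When patient identifiers are
#' present, whole patients are assigned to one split (sizes then follow the
#' fractions as closely as the grouping allows); otherwise the split is
#' stratified by label-set signature. Deterministic given `seed`.
#'
#' @param records List of [ecg_record()] objects (at least 3).
#' @param fractions Train / validation / test fractions, summing to 1.
#' @param seed Integer seed.
#' @return An object of class `ecg_split`: list with integer index vectors
#'   `train`, `val`, `test`, plus `fractions` and `seed`.
#' @export
split_dataset <- function(records, fractions = c(0.70, 0.15, 0.15), seed = 1) {
  n <- length(records)
  if (n < 3) abort("Need at least 3 records to split.")
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-9) {
    abort("`fractions` must be three numbers summing to 1.")
  }
  pid <- vapply(records, function(r) as.character(r$patient_id %||% NA),
                character(1))
  grouped <- !all(is.na(pid))
  targets <- apportion(n, fractions)
  assign <- integer(n) # 1 = train, 2 = val, 3 = test
  with_seed(derive_seed(seed, 11L), {
    if (grouped) {
      pid[is.na(pid)] <- paste0(".single-", which(is.na(pid)))
      groups <- split(seq_len(n), pid)
      groups <- groups[sample.int(length(groups))]
      sizes <- c(0, 0, 0)
      for (g in groups) {
        deficit <- (targets - sizes) / pmax(targets, 1)
        s <- which.max(deficit)
        assign[g] <- s
        sizes[s] <- sizes[s] + length(g)
      }
    } else {
      sig <- vapply(records, function(r) paste(r$labels, collapse = "|"),
                    character(1))
      pool <- integer(0)
      sizes <- c(0L, 0L, 0L)
      for (s in split(seq_len(n), sig)) {
        s <- s[sample.int(length(s))]
        base <- floor(length(s) * fractions)
        idx <- 0L
        for (k in 1:3) {
          if (base[k] > 0) {
            assign[s[idx + seq_len(base[k])]] <- k
            idx <- idx + base[k]
          }
        }
        sizes <- sizes + as.integer(base)
        pool <- c(pool, s[idx + seq_len(length(s) - idx)])
      }
      pool <- pool[sample.int(length(pool))]
      for (k in 1:3) {
        need <- targets[k] - sizes[k]
        if (need > 0) {
          assign[pool[seq_len(need)]] <- k
          pool <- pool[-seq_len(need)]
        }
      }
    }
  })
  structure(
    list(train = which(assign == 1L), val = which(assign == 2L),
         test = which(assign == 3L), fractions = fractions, seed = seed),
    class = "ecg_split"
  )
}

#' @export
print.ecg_split <- function(x, ...) {
  cat(sprintf("<ecg_split> train %d / val %d / test %d (seed %d)\n",
              length(x$train), length(x$val), length(x$test), x$seed))
  invisible(x)
}

#' Per-lead z-score standardization with train-only statistics
#'
#' Computes per-lead mean and standard deviation over all samples of the
#' training records and transforms every record with those statistics
#' (leakage-safe: validation and test reuse the train statistics). A lead with
#' zero variance has its standard deviation clamped to 1.
#'
#' @param records List of [ecg_record()] objects.
#' @param split An `ecg_split` from [split_dataset()]; statistics are computed
#'   on `split$train`.
#' @return A list with `records` (standardized) and `stats` (tibble with one
#'   row per lead: `lead`, `mean`, `sd`).
#' @export
standardize_signals <- function(records, split) {
  stopifnot(inherits(split, "ecg_split"))
  train_mat <- do.call(cbind, lapply(records[split$train], `[[`, "signal"))
  mu <- rowMeans(train_mat)
  sdev <- apply(train_mat, 1, stats::sd)
  sdev[!is.finite(sdev) | sdev <= 0] <- 1
  out <- lapply(records, function(r) {
    r$signal <- (r$signal - mu) / sdev
    r
  })
  list(
    records = out,
    stats = tibble(lead = rownames(records[[1]]$signal) %||%
                     as.character(seq_along(mu)),
                   mean = unname(mu), sd = unname(sdev))
  )
}

#' Multihot encoding of label sets
#'
#' @param label_sets List of character vectors (or list of [ecg_record()]
#'   objects, whose `labels` are used).
#' @param classes Class order defining the columns.
#' @return Binary `records x classes` matrix; entry (i, j) is 1 iff class j is
#'   in record i's label set.
#' @examples
#' encode_multihot(list(c("A", "C")), c("A", "B", "C")) # 1 0 1
#' @export
encode_multihot <- function(label_sets, classes) {
  if (length(label_sets) && inherits(label_sets[[1]], "ecg_record")) {
    label_sets <- lapply(label_sets, `[[`, "labels")
  }
  y <- matrix(0, nrow = length(label_sets), ncol = length(classes),
              dimnames = list(NULL, classes))
  for (i in seq_along(label_sets)) {
    labs <- unique(as.character(label_sets[[i]]))
    unknown <- setdiff(labs, classes)
    if (length(unknown)) {
      abort(sprintf("Unknown label(s) not in class order: %s",
                    paste(unknown, collapse = ", ")))
    }
    y[i, labs] <- 1
  }
  y
}

#' Decode a multihot matrix back to label sets
#'
#' Inverse of [encode_multihot()].
#'
#' @param y Binary records x classes matrix.
#' @param classes Class order; defaults to `colnames(y)`.
#' @return List of sorted character vectors.
#' @export
decode_multihot <- function(y, classes = colnames(y)) {
  if (!is_binary_matrix(y)) abort("`y` must be a binary matrix.")
  if (is.null(classes)) abort("Class order is required.")
  lapply(seq_len(nrow(y)), function(i) sort(classes[y[i, ] == 1]))
}
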