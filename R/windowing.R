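#' Cut a record into fixed-length overlapping windows
#'
#' Windows of `round(window_s * rate)` samples are anchored at sample 0 and
#' advanced by a stride of `round(W * (1 - overlap))`; a trailing stretch too
#' short for a full window is ignored. A 10 s record at 100 Hz with 2.5 s
#' windows and 50% overlap yields exactly 7 segments starting at samples
#' 0, 125, ..., 750.
#'
#' @param record An [ecg_record()].
#' @param window_s Window length in seconds. Default 2.5.
#' @param overlap Overlap fraction in `[0, 1)`. Default 0.5.
#' @return An object of class `segment_batch`: list with `segments`
#'   (`leads x window x n_segments` array), `origin` (record id per segment),
#'   `starts` (0-based start samples), `window_s`, `overlap`, `rate`.
#' @export
segment_record <- function(record, window_s = 2.5, overlap = 0.5) {
  stopifnot(inherits(record, "ecg_record"))
  if (overlap < 0 || overlap >= 1) abort("`overlap` must lie in [0, 1).")
  w <- round(window_s * record$rate)
  len <- ncol(record$signal)
  if (len < w) {
    abort(sprintf("Record %s (%d samples) is shorter than the window (%d).",
                  record$id, len, w))
  }
  stride <- round(w * (1 - overlap))
  if (stride < 1) abort("Stride must be at least one sample.")
  starts <- seq(0L, len - w, by = stride)
  segs <- array(0, dim = c(nrow(record$signal), w, length(starts)))
  for (i in seq_along(starts)) {
    segs[, , i] <- record$signal[, (starts[i] + 1):(starts[i] + w)]
  }
  structure(
    list(segments = segs, origin = rep(record$id, length(starts)),
         starts = starts, window_s = window_s, overlap = overlap,
         rate = record$rate),
    class = "segment_batch"
  )
}

#' Segment every record of a dataset on the full sliding-window grid
#'
#' @param records List of [ecg_record()] objects with identical lead counts,
#'   rates and lengths.
#' @inheritParams segment_record
#' @return A `segment_batch` whose `origin` maps each segment to its record id.
#' @export
segment_dataset <- function(records, window_s = 2.5, overlap = 0.5) {
  batches <- lapply(records, segment_record, window_s = window_s,
                    overlap = overlap)
  structure(
    list(
      segments = array(
        unlist(lapply(batches, `[[`, "segments"), use.names = FALSE),
        dim = c(dim(batches[[1]]$segments)[1:2],
                sum(vapply(batches, function(b) dim(b$segments)[3], numeric(1))))
      ),
      origin = unlist(lapply(batches, `[[`, "origin"), use.names = FALSE),
      starts = unlist(lapply(batches, `[[`, "starts"), use.names = FALSE),
      window_s = window_s, overlap = overlap, rate = batches[[1]]$rate
    ),
    class = "segment_batch"
  )
}

#' Aggregate per-segment probabilities to record level
#'
#' Combines the probability vectors of all segments belonging to one record by
#' the element-wise maximum, producing a single record-level prediction.
#'
#' @param probs Numeric `segments x classes` matrix of probabilities in
#'   `[0, 1]`.
#' @param origin Vector of record ids, one per segment row.
#' @return `records x classes` matrix of aggregated probabilities, rows in
#'   first-appearance order of `origin`.
#' @examples
#' p <- rbind(c(0.2, 0.9), c(0.7, 0.1))
#' aggregate_predictions(p, c("r1", "r1")) # 0.7 0.9
#' @export
aggregate_predictions <- function(probs, origin) {
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = length(origin))
  if (nrow(probs) == 0 || length(origin) == 0) {
    abort("Cannot aggregate an empty prediction group.")
  }
  if (nrow(probs) != length(origin)) {
    abort("`origin` must have one entry per probability row.")
  }
  if (any(probs < 0 | probs > 1)) abort("Probabilities must lie in [0, 1].")
  ids <- unique(origin)
  out <- matrix(NA_real_, length(ids), ncol(probs),
                dimnames = list(ids, colnames(probs)))
  groups <- split(seq_along(origin), factor(origin, levels = ids))
  for (i in seq_along(groups)) {
    out[i, ] <- apply(probs[groups[[i]], , drop = FALSE], 2, max)
  }
  out
}

#' Sample random fixed-length training segments
#'
#' Draws one window per record per repetition with a uniformly distributed
#' start offset in `[0, L - W]` — the training-time counterpart of the
#' deterministic inference grid of [segment_record()]. Each emitted segment
#' carries its record's id so the full record-level label vector can be
#' attached.
#'
#' @param records List of [ecg_record()] objects.
#' @param window_s Window length in seconds.
#' @param n_per_record Number of independent draws per record. Default 1.
#' @param seed Integer seed; fixed seed gives an identical stream.
#' @return A `segment_batch` (ordering: all records' first draw, then second
#'   draw, ...).
#' @export
sample_segments <- function(records, window_s = 2.5, n_per_record = 1,
                            seed = 1) {
  w <- round(window_s * records[[1]]$rate)
  n <- length(records)
  lens <- vapply(records, function(r) ncol(r$signal), numeric(1))
  if (any(lens < w)) abort("All records must be at least one window long.")
  starts <- with_seed(derive_seed(seed, 23L), {
    vapply(rep(lens, times = n_per_record),
           function(L) sample.int(L - w + 1L, 1L) - 1L, integer(1))
  })
  leads <- nrow(records[[1]]$signal)
  segs <- array(0, dim = c(leads, w, n * n_per_record))
  ids <- character(n * n_per_record)
  for (k in seq_len(n * n_per_record)) {
    r <- records[[((k - 1L) %% n) + 1L]]
    segs[, , k] <- r$signal[, (starts[k] + 1):(starts[k] + w)]
    ids[k] <- r$id
  }
  structure(
    list(segments = segs, origin = ids, starts = starts, window_s = window_s,
         overlap = NA_real_, rate = records[[1]]$rate),
    class = "segment_batch"
  )
}

#' @export
print.segment_batch <- function(x, ...) {
  d <- dim(x$segments)
  cat(sprintf("<segment_batch> %d segments of %d leads x %d samples (%g s @ %g Hz)\n",
              d[3], d[1], d[2], x$window_s, x$rate))
  invisible(x)
}
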