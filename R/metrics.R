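#' Threshold probabilities into multihot predictions
#'
#' An entry is 1 iff its score is strictly greater than the threshold
#' (a score exactly at the threshold maps to 0).
#'
#' @param scores Probability matrix in `[0, 1]`.
#' @param threshold Decision threshold. Default 0.5.
#' @return Binary matrix of the same shape.
#' @export
binarize <- function(scores, threshold = 0.5) {
  if (any(scores < 0 | scores > 1)) abort("Scores must lie in [0, 1].")
  out <- (scores > threshold) * 1
  dimnames(out) <- dimnames(scores)
  out
}

#' Per-label confusion counts
#'
#' Reduces the multilabel problem to one binary classifier per label and
#' tabulates the 2x2 confusion counts per column. For every label,
#' TP + FP + FN + TN equals the number of evaluated records.
#'
#' @param truth,predicted Binary `records x classes` matrices.
#' @return A tibble with columns `label`, `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_per_label <- function(truth, predicted) {
  if (!is_binary_matrix(truth) || !is_binary_matrix(predicted)) {
    abort("`truth` and `predicted` must be binary matrices.")
  }
  if (!identical(dim(truth), dim(predicted))) {
    abort("`truth` and `predicted` must have identical shapes.")
  }
  labels <- colnames(truth) %||% as.character(seq_len(ncol(truth)))
  tibble(
    label = labels,
    tp = as.integer(colSums(truth == 1 & predicted == 1)),
    fp = as.integer(colSums(truth == 0 & predicted == 1)),
    fn = as.integer(colSums(truth == 1 & predicted == 0)),
    tn = as.integer(colSums(truth == 0 & predicted == 0))
  )
}

# B(tp, fp, fn, tn) for one measure; zero-denominator cells return 0.
measure_fun <- function(measure) {
  div0 <- function(num, den) ifelse(den > 0, num / den, 0)
  switch(measure,
         accuracy = function(tp, fp, fn, tn) div0(tp + tn, tp + fp + fn + tn),
         precision = function(tp, fp, fn, tn) div0(tp, tp + fp),
         recall = function(tp, fp, fn, tn) div0(tp, tp + fn),
         f1 = function(tp, fp, fn, tn) {
           p <- div0(tp, tp + fp)
           r <- div0(tp, tp + fn)
           ifelse(p + r > 0, 2 * p * r / (p + r), 0)
         },
         abort(sprintf("Unknown measure: %s", measure)))
}

#' Per-label accuracy, precision, recall and F1 from confusion counts
#'
#' Standard definitions: accuracy `(TP + TN) / n`, precision `TP / (TP + FP)`,
#' recall `TP / (TP + FN)`, F1 the harmonic mean of precision and recall.
#' Zero-denominator cases return 0.
#'
#' @param counts Confusion tibble from [confusion_per_label()].
#' @return The tibble with columns `accuracy`, `precision`, `recall`, `f1`
#'   appended.
#' @export
label_metrics <- function(counts) {
  for (m in c("accuracy", "precision", "recall", "f1")) {
    counts[[m]] <- measure_fun(m)(counts$tp, counts$fp, counts$fn, counts$tn)
  }
  counts
}

#' Macro and micro averages of a label-based measure
#'
#' Macro averages the per-label measure with equal label weight; micro applies
#' the measure to the summed counts.
#'
#' @param counts Confusion tibble from [confusion_per_label()].
#' @param measure One of `"accuracy"`, `"precision"`, `"recall"`, `"f1"`.
#' @return Named list with `macro` and `micro`.
#' @export
macro_micro <- function(counts, measure = "f1") {
  f <- measure_fun(measure)
  list(
    macro = mean(f(counts$tp, counts$fp, counts$fn, counts$tn)),
    micro = f(sum(counts$tp), sum(counts$fp), sum(counts$fn), sum(counts$tn))
  )
}

#' Example-based precision, recall and F1
#'
#' Per-record set-overlap metrics averaged over records:
#' precision `|Y ∩ P| / |P|`, recall `|Y ∩ P| / |Y|`, F1 the harmonic mean of
#' the two averages. A record with an empty prediction set contributes 0 to
#' precision; records with empty truth sets are not admitted (they are
#' dropped upstream during preparation).
#'
#' @param truth,predicted Binary `records x classes` matrices, or lists of
#'   character label sets.
#' @return Named list with `precision`, `recall`, `f1`.
#' @examples
#' example_based(list(c("a", "b")), list(c("b", "c"))) # all 0.5
#' @export
example_based <- function(truth, predicted) {
  if (is.list(truth)) {
    classes <- sort(unique(unlist(c(truth, predicted))))
    truth <- encode_multihot(truth, classes)
    predicted <- encode_multihot(predicted, classes)
  }
  if (!identical(dim(truth), dim(predicted))) {
    abort("`truth` and `predicted` must have identical shapes.")
  }
  if (nrow(truth) == 0) abort("At least one record is required.")
  y_size <- rowSums(truth)
  if (any(y_size == 0)) {
    abort("Records with empty truth label sets are not admitted.")
  }
  inter <- rowSums(truth * predicted)
  p_size <- rowSums(predicted)
  prec <- mean(ifelse(p_size > 0, inter / p_size, 0))
  rec <- mean(inter / y_size)
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1)
}

#' Per-label and macro ROC AUC
#'
#' AUC computed as the Mann-Whitney probability that a randomly chosen
#' positive record outscores a randomly chosen negative one, with ties
#' credited 1/2. Labels lacking either a positive or a negative record are
#' excluded from the macro average and reported.
#'
#' @param scores Numeric `records x classes` score matrix.
#' @param truth Binary matrix of the same shape.
#' @return A list of class `label_auc`: `per_label` (tibble with `label`,
#'   `n_pos`, `n_neg`, `auc`), `macro` (mean over included labels), and
#'   `excluded` (labels without both classes).
#' @export
roc_auc <- function(scores, truth) {
  if (!identical(dim(scores), dim(truth))) {
    abort("`scores` and `truth` must have identical shapes.")
  }
  labels <- colnames(truth) %||% as.character(seq_len(ncol(truth)))
  aucs <- vapply(seq_len(ncol(truth)), function(j) {
    y <- truth[, j]
    n_pos <- sum(y == 1)
    n_neg <- sum(y == 0)
    if (n_pos == 0 || n_neg == 0) return(NA_real_)
    r <- rank(scores[, j]) # average ranks give half credit to ties
    (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }, numeric(1))
  per_label <- tibble(label = labels,
                      n_pos = as.integer(colSums(truth == 1)),
                      n_neg = as.integer(colSums(truth == 0)),
                      auc = aucs)
  if (all(is.na(aucs))) {
    abort("No label has both a positive and a negative record.")
  }
  structure(
    list(per_label = per_label, macro = mean(aucs, na.rm = TRUE),
         excluded = labels[is.na(aucs)]),
    class = "label_auc"
  )
}

#' @export
print.label_auc <- function(x, ...) {
  cat(sprintf("<label_auc> macro AUC %.4f over %d labels%s\n", x$macro,
              sum(!is.na(x$per_label$auc)),
              if (length(x$excluded))
                sprintf(" (excluded: %s)", paste(x$excluded, collapse = ", "))
              else ""))
  invisible(x)
}

#' Maximum example-based F1 over decision thresholds
#'
#' Scans a threshold grid, binarizing scores at each threshold (strictly
#' greater than) and computing example-based F1; returns the maximum and the
#' threshold attaining it. The default grid is the sorted set of distinct
#' scores plus 0 and 1, which maximizes exactly; `thresholds` can be set to a
#' coarser grid (e.g. `seq(0, 1, 0.01)`) for speed.
#'
#' @param scores Probability matrix.
#' @param truth Binary matrix of the same shape.
#' @param thresholds Optional numeric grid in `[0, 1]`.
#' @return Named list with `f_max` and `threshold`.
#' @export
f_max <- function(scores, truth, thresholds = NULL) {
  if (is.null(thresholds)) {
    thresholds <- sort(unique(c(0, as.numeric(scores), 1)))
  }
  if (!length(thresholds) || any(thresholds < 0 | thresholds > 1)) {
    abort("`thresholds` must be a non-empty grid inside [0, 1].")
  }
  f1s <- vapply(thresholds, function(t) {
    example_based(truth, binarize(scores, t))$f1
  }, numeric(1))
  best <- which.max(f1s)
  list(f_max = f1s[best], threshold = thresholds[best])
}

#' Full multilabel evaluation report
#'
#' Combines the label-based suite (per-label confusion counts, accuracy,
#' precision, recall, F1, AUC; macro and micro averages), the example-based
#' metrics at the decision threshold, and the example-based F_max over all
#' distinct score thresholds.
#'
#' @param scores Probability matrix (records x classes).
#' @param truth Binary matrix of the same shape.
#' @param threshold Decision threshold for the label-based and example-based
#'   metrics. Default 0.5 (strictly greater than).
#' @return An object of class `metric_report`: `per_label` tibble, `summary`
#'   tibble (rows macro / micro / example-based), `f_max`, `auc` (macro),
#'   `threshold`.
#' @export
evaluate_predictions <- function(scores, truth, threshold = 0.5) {
  pred <- binarize(scores, threshold)
  counts <- label_metrics(confusion_per_label(truth, pred))
  auc <- roc_auc(scores, truth)
  counts$auc <- auc$per_label$auc
  measures <- c("accuracy", "precision", "recall", "f1")
  mm <- lapply(measures, macro_micro, counts = counts)
  eb <- example_based(truth, pred)
  fm <- f_max(scores, truth)
  summary <- tibble(
    averaging = c("macro", "micro", "example_based"),
    accuracy = c(mm[[1]]$macro, mm[[1]]$micro, NA),
    precision = c(mm[[2]]$macro, mm[[2]]$micro, eb$precision),
    recall = c(mm[[3]]$macro, mm[[3]]$micro, eb$recall),
    f1 = c(mm[[4]]$macro, mm[[4]]$micro, eb$f1),
    auc = c(auc$macro, NA, NA)
  )
  structure(
    list(per_label = counts, summary = summary, f_max = fm$f_max,
         f_max_threshold = fm$threshold, macro_auc = auc$macro,
         threshold = threshold),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  cat(sprintf("F_max %.4f at threshold %.4f; macro AUC %.4f\n",
              x$f_max, x$f_max_threshold, x$macro_auc))
  invisible(x)
}
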