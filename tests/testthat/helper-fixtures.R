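# Shared fixtures, all generated in code at test time.

# A tiny architecture with the canonical block/branch structure but minimal
# widths, for fast forward/backward tests.
tiny_mrf_config <- function(classes = 2, kinds = rep("large", 5)) {
  mrf_config(classes, filters = rep(2L, 5), reductions = rep(2L, 5),
             kinds = kinds)
}

# Records with hand-planted labels, small enough for prep-module tests.
toy_records <- function(labels_list, n_samples = 40, rate = 100,
                        patient_ids = NULL, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_along(labels_list), function(i) {
      ecg_record(sprintf("rec-%03d", i),
                 matrix(rnorm(2 * n_samples), 2, n_samples),
                 rate, labels_list[[i]],
                 patient_id = if (is.null(patient_ids)) NA else patient_ids[i])
    })
  })
}

# A small separable synthetic dataset prepared end to end (filter, split,
# standardize, encode), shared by training-related tests.
prepared_synth <- function(n = 240, seed = 42, noise_sd = 0.05,
                           strength = 1.5) {
  ds <- generate_dataset(synth_config(n, noise_sd = noise_sd,
                                      effect_strength = strength,
                                      seed = seed))
  f <- filter_rare_classes(ds$records, 10)
  split <- split_dataset(f$records, seed = seed)
  std <- standardize_signals(f$records, split)
  y <- encode_multihot(std$records, f$classes)
  list(records = std$records, labels = y, classes = f$classes, split = split,
       train = list(records = std$records[split$train],
                    labels = y[split$train, , drop = FALSE]),
       val = list(records = std$records[split$val],
                  labels = y[split$val, , drop = FALSE]),
       test = list(records = std$records[split$test],
                   labels = y[split$test, , drop = FALSE]))
}

# Independent brute-force oracles for the metric suite ----------------------

oracle_label_metrics <- function(truth, pred) {
  q <- ncol(truth)
  out <- data.frame(tp = integer(q), fp = integer(q), fn = integer(q),
                    tn = integer(q), accuracy = numeric(q),
                    precision = numeric(q), recall = numeric(q),
                    f1 = numeric(q))
  for (j in seq_len(q)) {
    tp <- fp <- fn <- tn <- 0
    for (i in seq_len(nrow(truth))) {
      if (truth[i, j] == 1 && pred[i, j] == 1) tp <- tp + 1
      if (truth[i, j] == 0 && pred[i, j] == 1) fp <- fp + 1
      if (truth[i, j] == 1 && pred[i, j] == 0) fn <- fn + 1
      if (truth[i, j] == 0 && pred[i, j] == 0) tn <- tn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    out[j, ] <- list(tp, fp, fn, tn,
                     (tp + tn) / (tp + fp + fn + tn), prec, rec,
                     if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
  }
  out
}

# AUC by exhaustive positive-negative pair enumeration (ties credit 1/2).
oracle_auc <- function(scores, y) {
  pos <- which(y == 1)
  neg <- which(y == 0)
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (scores[p] > scores[n]) + 0.5 * (scores[p] == scores[n])
    }
  }
  total / (length(pos) * length(neg))
}

oracle_example_based <- function(truth_sets, pred_sets) {
  n <- length(truth_sets)
  prec <- rec <- numeric(n)
  for (i in seq_len(n)) {
    inter <- length(intersect(truth_sets[[i]], pred_sets[[i]]))
    prec[i] <- if (length(pred_sets[[i]]) > 0)
      inter / length(pred_sets[[i]]) else 0
    rec[i] <- inter / length(truth_sets[[i]])
  }
  p <- mean(prec); r <- mean(rec)
  list(precision = p, recall = r,
       f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
}

# random multilabel instance with no empty truth rows
random_instance <- function(n_max = 10, q_max = 5) {
  n <- sample(2:n_max, 1)
  q <- sample(2:q_max, 1)
  truth <- matrix(rbinom(n * q, 1, 0.4), n, q)
  empty <- rowSums(truth) == 0
  truth[empty, sample(q, 1)] <- 1
  truth[1, 1] <- 1 # keep at least one label with both classes present
  truth[2, 1] <- 0
  if (sum(truth[2, ]) == 0) truth[2, q] <- 1 # and no empty truth rows
  scores <- matrix(round(runif(n * q), 2), n, q)
  list(truth = truth, scores = scores, pred = (scores > 0.5) * 1)
}
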