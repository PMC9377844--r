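test_that("per-label confusion counts partition the records", {
  truth <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
  pred <- cbind(a = c(1, 0, 1, 0), b = c(1, 0, 1, 0))
  cc <- confusion_per_label(truth, pred)
  expect_equal(cc$tp, c(1L, 2L))
  expect_equal(cc$fn, c(1L, 0L))
  expect_equal(cc$fp, c(1L, 0L))
  expect_equal(cc$tn, c(1L, 2L))
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, c(4L, 4L))

  perfect <- confusion_per_label(truth, truth)
  expect_true(all(perfect$fp == 0 & perfect$fn == 0))
  expect_error(confusion_per_label(truth, pred * 0.5), "binary")
})

test_that("label metrics follow the standard confusion-count forms", {
  cc <- tibble::tibble(label = "x", tp = 2L, fp = 1L, fn = 1L, tn = 6L)
  lm <- label_metrics(cc)
  expect_equal(lm$precision, 2 / 3)
  expect_equal(lm$recall, 2 / 3)
  expect_equal(lm$f1, 2 / 3)
  expect_equal(lm$accuracy, 0.8)

  # degenerate label with no positives anywhere: 0 by convention, accuracy 1
  deg <- label_metrics(tibble::tibble(label = "d", tp = 0L, fp = 0L,
                                      fn = 0L, tn = 10L))
  expect_equal(c(deg$precision, deg$recall, deg$f1), c(0, 0, 0))
  expect_equal(deg$accuracy, 1)

  perfect <- label_metrics(tibble::tibble(label = "p", tp = 5L, fp = 0L,
                                          fn = 0L, tn = 5L))
  expect_equal(c(perfect$accuracy, perfect$precision, perfect$recall,
                 perfect$f1), rep(1, 4))
})

test_that("macro and micro averaging behave as mean and pooled forms", {
  one <- tibble::tibble(label = "x", tp = 3L, fp = 1L, fn = 2L, tn = 4L)
  mm <- macro_micro(one, "f1")
  expect_equal(mm$macro, mm$micro)

  two <- tibble::tibble(label = c("a", "b"), tp = c(5L, 0L), fp = c(0L, 3L),
                        fn = c(0L, 2L), tn = c(5L, 5L))
  expect_equal(macro_micro(two, "f1")$macro, 0.5) # mean of 1 and 0
})

test_that("metric suite agrees with brute-force oracles on random instances", {
  withr::with_seed(101, {
    for (i in 1:100) {
      inst <- random_instance()
      oracle <- oracle_label_metrics(inst$truth, inst$pred)
      got <- label_metrics(confusion_per_label(inst$truth, inst$pred))
      expect_equal(got$tp, oracle$tp)
      expect_equal(got$precision, oracle$precision)
      expect_equal(got$recall, oracle$recall)
      expect_equal(got$f1, oracle$f1)
      expect_equal(got$accuracy, oracle$accuracy)

      for (meas in c("accuracy", "precision", "recall", "f1")) {
        mm <- macro_micro(got, meas)
        expect_equal(mm$macro, mean(oracle[[meas]]))
        pooled <- oracle_label_metrics(
          matrix(as.numeric(inst$truth), ncol = 1),
          matrix(as.numeric(inst$pred), ncol = 1))
        expect_equal(mm$micro, pooled[[meas]])
      }

      # example-based vs set oracle
      classes <- as.character(seq_len(ncol(inst$truth)))
      t_sets <- decode_multihot(inst$truth, classes)
      p_sets <- decode_multihot(inst$pred, classes)
      eb <- example_based(inst$truth, inst$pred)
      eo <- oracle_example_based(t_sets, p_sets)
      expect_equal(eb$precision, eo$precision)
      expect_equal(eb$recall, eo$recall)
      expect_equal(eb$f1, eo$f1)

      # AUC vs exhaustive pair enumeration
      got_auc <- roc_auc(inst$scores, inst$truth)
      for (j in seq_len(ncol(inst$truth))) {
        expect_equal(got_auc$per_label$auc[j],
                     oracle_auc(inst$scores[, j], inst$truth[, j]))
      }

      # F_max vs exhaustive scan over all distinct score thresholds
      fm <- f_max(inst$scores, inst$truth)
      grid <- sort(unique(c(0, as.numeric(inst$scores), 1)))
      brute <- max(vapply(grid, function(t) {
        oracle_example_based(t_sets,
                             decode_multihot((inst$scores > t) * 1, classes))$f1
      }, numeric(1)))
      expect_equal(fm$f_max, brute)
      # F_max dominates F1 at the default threshold
      expect_gte(fm$f_max, example_based(inst$truth, inst$pred)$f1)
    }
  })
})

test_that("example-based metrics follow the set-overlap definitions", {
  eb <- example_based(list(c("a", "b")), list(c("b", "c")))
  expect_equal(eb$precision, 0.5)
  expect_equal(eb$recall, 0.5)
  expect_equal(eb$f1, 0.5)

  # perfect prediction
  sets <- list(c("a"), c("a", "b"))
  perfect <- example_based(sets, sets)
  expect_equal(unlist(perfect), c(precision = 1, recall = 1, f1 = 1))

  # one perfect and one fully wrong record average to 0.5
  mixed <- example_based(cbind(c(1, 1), c(0, 0)), cbind(c(1, 0), c(0, 1)))
  expect_equal(mixed$precision, 0.5)
  expect_equal(mixed$recall, 0.5)

  expect_error(example_based(matrix(0, 1, 2), matrix(1, 1, 2)), "empty truth")
  expect_error(example_based(matrix(numeric(), 0, 2),
                             matrix(numeric(), 0, 2)), "At least one record")
})

test_that("AUC matches the Mann-Whitney statistic and its invariances", {
  truth <- matrix(c(0, 0, 1, 1), ncol = 1)
  scores <- matrix(c(0.1, 0.4, 0.35, 0.8), ncol = 1)
  expect_equal(roc_auc(scores, truth)$macro, 0.75)

  # perfect separation and inversion
  expect_equal(roc_auc(matrix(c(0.1, 0.2, 0.8, 0.9), ncol = 1), truth)$macro, 1)
  expect_equal(roc_auc(matrix(c(0.9, 0.8, 0.2, 0.1), ncol = 1), truth)$macro, 0)

  # invariant under strictly monotone transforms of the scores
  withr::with_seed(55, {
    s <- matrix(runif(40), ncol = 2)
    y <- matrix(rbinom(40, 1, 0.5), ncol = 2)
    a1 <- roc_auc(s, y)$per_label$auc
    a2 <- roc_auc(plogis(5 * s - 1), y)$per_label$auc
    expect_equal(a1, a2)
  })

  # single-class labels are excluded and reported
  y2 <- cbind(a = c(1, 1, 0, 0), b = c(1, 1, 1, 1))
  r <- roc_auc(scores[, c(1, 1)], y2)
  expect_equal(r$excluded, "b")
  expect_equal(r$macro, r$per_label$auc[1])
  expect_error(roc_auc(matrix(0.5, 2, 1), matrix(1, 2, 1)), "positive and a negative")
})

test_that("binarization is strict and metric invariances hold", {
  expect_equal(as.numeric(binarize(matrix(c(0.4, 0.5, 0.6), 1))), c(0, 0, 1))
  expect_equal(as.numeric(binarize(matrix(c(0, 0.01), 1), 0)), c(0, 1))
  b <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(binarize(b, 0.5), b) # idempotent on binary scores

  withr::with_seed(77, {
    inst <- random_instance(8, 4)
    # macro metrics invariant under label permutation
    perm <- sample(ncol(inst$truth))
    m1 <- macro_micro(confusion_per_label(inst$truth, inst$pred), "f1")
    m2 <- macro_micro(confusion_per_label(inst$truth[, perm, drop = FALSE],
                                          inst$pred[, perm, drop = FALSE]),
                      "f1")
    expect_equal(m1, m2)
    # example-based metrics invariant under record permutation
    rp <- sample(nrow(inst$truth))
    expect_equal(example_based(inst$truth, inst$pred),
                 example_based(inst$truth[rp, , drop = FALSE],
                               inst$pred[rp, , drop = FALSE]))
  })
})

test_that("evaluate_predictions assembles a coherent report", {
  withr::with_seed(91, {
    inst <- random_instance(10, 4)
    rep <- evaluate_predictions(inst$scores, inst$truth)
    expect_s3_class(rep, "metric_report")
    expect_equal(nrow(rep$per_label), ncol(inst$truth))
    expect_true(all(rep$summary$f1 >= 0 & rep$summary$f1 <= 1, na.rm = TRUE))
    expect_gte(rep$f_max,
               rep$summary$f1[rep$summary$averaging == "example_based"])
    # tidy/glance accessors
    expect_identical(tidy(rep), rep$per_label)
    g <- glance(rep)
    expect_equal(g$f_max, rep$f_max)
    expect_equal(g$macro_auc, rep$macro_auc)
  })
})
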