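test_that("label aggregation follows the diagnostic hierarchy", {
  h <- ptbxl_hierarchy()
  expect_equal(nrow(h), 44)
  expect_setequal(unique(h$superclass), c("CD", "HYP", "MI", "NORM", "STTC"))
  expect_equal(length(unique(h$subclass)), 23)

  recs <- toy_records(list(c("ASMI", "ILMI"), "NORM", c("IRBBB", "LVH")))
  sup <- aggregate_labels(recs, h, "superdiagnostic")
  expect_equal(sup[[1]]$labels, "MI") # two infarction statements collapse
  expect_equal(sup[[2]]$labels, "NORM")
  sub <- aggregate_labels(recs, h, "subdiagnostic")
  expect_equal(sub[[3]]$labels, c("IRBBB", "LVH"))
  expect_equal(aggregate_labels(recs, h, "diagnostic")[[1]]$labels,
               c("ASMI", "ILMI"))

  # unmapped labels error unless declared non-diagnostic
  bad <- toy_records(list(c("NORM", "SR")))
  expect_error(aggregate_labels(bad, h, "superdiagnostic"), "SR")
  ok <- aggregate_labels(bad, h, "superdiagnostic", non_diagnostic = "SR")
  expect_equal(ok[[1]]$labels, "NORM")
})

test_that("rare-class filtering uses a strict threshold and drops orphans", {
  labels <- c(rep(list("A"), 20), rep(list("B"), 19), rep(list("C"), 20),
              rep(list(c("A", "B")), 5))
  recs <- toy_records(labels)
  f <- filter_rare_classes(recs, 20)
  # A has 25, C has 20 (exactly min_count: retained), B has 24: retained too
  expect_setequal(f$classes, c("A", "B", "C"))

  labels2 <- c(rep(list("A"), 25), rep(list("B"), 19), rep(list("C"), 20))
  f2 <- filter_rare_classes(toy_records(labels2), 20)
  expect_identical(f2$classes, c("A", "C")) # sorted, B < 20 removed
  expect_equal(length(f2$records), 45) # records labelled only B dropped
  # no retained class drops below min_count after filtering
  counts <- table(unlist(lapply(f2$records, `[[`, "labels")))
  expect_true(all(counts >= 20))

  # min_count 0 is the identity
  f0 <- filter_rare_classes(recs, 0)
  expect_equal(length(f0$records), length(recs))
  expect_warning(filter_rare_classes(toy_records(list("X")), 5), "dropped")
})

test_that("split sizes follow largest-remainder rounding and are disjoint", {
  recs <- toy_records(rep(list("A"), 100))
  s <- split_dataset(recs, seed = 7)
  expect_equal(lengths(s[c("train", "val", "test")]),
               c(train = 70L, val = 15L, test = 15L))

  recs101 <- toy_records(rep(list("A"), 101))
  s101 <- split_dataset(recs101, seed = 7)
  sizes <- lengths(s101[c("train", "val", "test")])
  expect_equal(sum(sizes), 101)
  expect_true(all(abs(sizes - 101 * c(0.7, 0.15, 0.15)) <= 1))

  # disjoint cover
  all_idx <- sort(c(s$train, s$val, s$test))
  expect_identical(all_idx, 1:100)

  # determinism
  expect_identical(split_dataset(recs, seed = 7), split_dataset(recs, seed = 7))
  expect_false(identical(split_dataset(recs, seed = 7)$train,
                         split_dataset(recs, seed = 8)$train))

  expect_error(split_dataset(recs[1:2]), "at least 3")
  expect_error(split_dataset(recs, fractions = c(0.5, 0.3, 0.1)), "summing to 1")
})

test_that("patient grouping keeps every patient inside one split", {
  pids <- rep(sprintf("p%02d", 1:20), each = 5)
  recs <- toy_records(rep(list("A"), 100), patient_ids = pids)
  s <- split_dataset(recs, seed = 3)
  for (part in c("train", "val", "test")) {
    in_part <- unique(pids[s[[part]]])
    others <- setdiff(1:100, s[[part]])
    expect_length(intersect(in_part, unique(pids[others])), 0)
  }
  expect_equal(sum(lengths(s[c("train", "val", "test")])), 100)
})

test_that("standardization is train-only, closed-form and idempotent", {
  # closed form: train lead pooled over 3 copies of x maps to (x - 3) / sd
  x <- c(1, 2, 3, 4, 5)
  sdx <- sd(rep(x, 3)) # statistics pool all train samples
  mk <- function(v1, v2, id) ecg_record(id, matrix(c(v1, v2), 2, byrow = TRUE),
                                        100, "A")
  recs <- lapply(1:3, function(i) mk(x, 2 * x, i))
  split <- structure(list(train = 1:3, val = integer(), test = integer()),
                     class = "ecg_split")
  std <- standardize_signals(recs, split)
  expect_equal(unname(std$records[[1]]$signal[1, ]), (x - 3) / sdx)
  expect_equal(std$stats$mean, c(3, 6))

  # train stats applied unchanged to held-out records
  recs2 <- c(recs, list(mk(x + 10, x, 4)))
  split2 <- structure(list(train = 1:3, val = 4L, test = integer()),
                      class = "ecg_split")
  std2 <- standardize_signals(recs2, split2)
  expect_equal(unname(std2$records[[4]]$signal[1, ]), (x + 10 - 3) / sdx)

  # per-lead train moments after transform
  pooled <- do.call(cbind, lapply(std$records, `[[`, "signal"))
  expect_equal(unname(rowMeans(pooled)), c(0, 0), tolerance = 1e-6)
  expect_equal(unname(apply(pooled, 1, sd)), c(1, 1), tolerance = 1e-6)

  # standardizing already-standardized data is the identity (to tolerance)
  std_twice <- standardize_signals(std$records, split)
  expect_equal(std_twice$records[[2]]$signal, std$records[[2]]$signal,
               tolerance = 1e-6)

  # constant lead: zero-centered, sd clamped to 1 leaves zeros
  recs3 <- lapply(1:3, function(i) ecg_record(i, rbind(rep(2, 5), x), 100, "A"))
  std3 <- standardize_signals(recs3, split)
  expect_equal(std3$records[[1]]$signal[1, ], rep(0, 5))
})

test_that("multihot encoding is the set-membership indicator and inverts", {
  y <- encode_multihot(list(c("A", "C")), c("A", "B", "C"))
  expect_equal(as.numeric(y), c(1, 0, 1))
  expect_equal(as.numeric(encode_multihot(list(character()), c("A", "B"))),
               c(0, 0))
  expect_error(encode_multihot(list("Z"), c("A")), "Unknown label")

  # decode o encode is the identity on random label sets
  classes <- LETTERS[1:6]
  withr::with_seed(31, {
    for (rep in 1:20) {
      sets <- lapply(1:8, function(i) {
        sort(sample(classes, sample(0:4, 1)))
      })
      y <- encode_multihot(sets, classes)
      expect_equal(rowSums(y), lengths(sets))
      expect_equal(decode_multihot(y, classes), sets)
    }
  })
})
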