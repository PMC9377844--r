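#' Run a reproducible end-to-end experiment
#'
#' Composes the pipeline: obtain data (synthetic generation or a PTB-XL-style
#' directory), aggregate labels to the working level, filter rare classes,
#' split 70/15/15, standardize with train statistics, train the model, and
#' evaluate on the held-out test set. Everything needed to re-run the
#' experiment is written to `out_dir`: the resolved configuration snapshot
#' (YAML), the training history (CSV), the per-label and summary metrics
#' (CSV), and the model checkpoint (RDS).
#'
#' @param data Either a [synth_config()] (synthetic source) or a path to a
#'   PTB-XL-style directory (real source).
#' @param out_dir Output directory; refuses to overwrite an existing
#'   experiment unless `force = TRUE`.
#' @param model_config An `mrf_config`; class count is adjusted to the data
#'   after filtering. Default [canonical_mrf_config()].
#' @param config A [train_config()]; its `windowed` flag selects the
#'   sliding-window scenario for both training and record-level evaluation.
#' @param level Label aggregation level for real data.
#' @param min_count Rare-class threshold. Default 20.
#' @param fractions Split fractions. Default `c(0.70, 0.15, 0.15)`.
#' @param seed Seed for splitting (training uses `config$seed`).
#' @param force Overwrite an existing output directory.
#' @param verbose Per-epoch logging.
#' @return Invisibly, a list with the fitted `model`, the `metric_report` on
#'   the test split, the `split` and the retained `classes`.
#' @export
run_experiment <- function(data, out_dir,
                           model_config = NULL,
                           config = train_config(),
                           level = "superdiagnostic",
                           min_count = 20,
                           fractions = c(0.70, 0.15, 0.15),
                           seed = 1, force = FALSE, verbose = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    abort(sprintf(
      "Output directory %s already holds an experiment; use force = TRUE.",
      out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out_dir, "INCOMPLETE")
  writeLines(format(Sys.time()), marker)

  if (inherits(data, "synth_config")) {
    ds <- generate_dataset(data)
    records <- ds$records
    source_desc <- list(type = "synthetic", n_records = data$n_records,
                        seed = data$seed,
                        classes = names(data$classes),
                        prevalence = as.list(data$prevalence),
                        noise_sd = data$noise_sd,
                        effect_strength = data$effect_strength)
  } else {
    records <- load_ptbxl(data)
    records <- aggregate_labels(records, ptbxl_hierarchy(), level)
    source_desc <- list(type = "ptbxl", root = as.character(data),
                        level = level)
  }
  filtered <- filter_rare_classes(records, min_count)
  records <- filtered$records
  classes <- filtered$classes
  split <- split_dataset(records, fractions, seed = seed)
  std <- standardize_signals(records, split)
  records <- std$records
  y <- encode_multihot(records, classes)

  if (is.null(model_config)) model_config <- canonical_mrf_config(length(classes))
  if (model_config$classes != length(classes)) {
    model_config$classes <- length(classes)
  }
  model <- build_mrf(model_config, seed = config$seed)
  fit <- train_mrf(model,
                   train = list(records = records[split$train],
                                labels = y[split$train, , drop = FALSE]),
                   val = list(records = records[split$val],
                              labels = y[split$val, , drop = FALSE]),
                   config = config, verbose = verbose)

  test_probs <- predict(fit, records[split$test], windowed = config$windowed,
                        window_s = config$window_s)
  report <- evaluate_predictions(test_probs, y[split$test, , drop = FALSE],
                                 threshold = config$threshold)

  snapshot <- list(
    source = source_desc,
    scenario = list(windowed = config$windowed, window_s = config$window_s,
                    aggregation = if (config$windowed) "elementwise_max"
                                  else "none"),
    classes = as.list(classes),
    min_count = min_count, fractions = as.list(fractions),
    split_seed = seed,
    model = list(filters = as.list(model_config$filters),
                 reductions = as.list(model_config$reductions),
                 kinds = as.list(model_config$kinds),
                 dense = model_config$dense,
                 classes = model_config$classes,
                 slope = model_config$slope,
                 total_params = count_params(model_config)$total),
    training = unclass(config),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("mrfecg"))
  )
  yaml::write_yaml(snapshot, file.path(out_dir, "config.yaml"))
  readr::write_csv(fit$history, file.path(out_dir, "history.csv"))
  readr::write_csv(tidy(report), file.path(out_dir, "metrics_per_label.csv"))
  readr::write_csv(glance(report), file.path(out_dir, "metrics_summary.csv"))
  saveRDS(fit, file.path(out_dir, "model.rds"))
  file.remove(marker)
  invisible(list(model = fit, report = report, split = split,
                 classes = classes))
}
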