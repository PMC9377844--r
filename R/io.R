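#' Write a synthetic dataset to a directory
#'
#' One flat signal container (`signals.bin`, little-endian float32, records in
#' manifest order, lead-major within each record) plus a CSV manifest
#' (`manifest.csv`: record id, comma-joined labels, shape, rate, optional
#' split assignment) and the class order (`classes.txt`).
#'
#' @param dataset An `ecg_dataset` (see [generate_dataset()]).
#' @param dir Output directory, created if needed.
#' @param split Optional `ecg_split`; adds a `split` column to the manifest.
#' @return Invisibly, `dir`.
#' @export
write_ecg_dataset <- function(dataset, dir, split = NULL) {
  stopifnot(inherits(dataset, "ecg_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- dataset_manifest(dataset)
  if (!is.null(split)) {
    assign <- rep(NA_character_, nrow(manifest))
    assign[split$train] <- "train"
    assign[split$val] <- "val"
    assign[split$test] <- "test"
    manifest$split <- assign
  }
  con <- file(file.path(dir, "signals.bin"), "wb")
  on.exit(close(con))
  for (r in dataset$records) {
    # lead-major: all samples of lead 1, then lead 2, ...
    writeBin(as.numeric(t(r$signal)), con, size = 4L, endian = "little")
  }
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  writeLines(dataset$classes, file.path(dir, "classes.txt"))
  invisible(dir)
}

#' Read a dataset written by [write_ecg_dataset()]
#'
#' Round-trips exactly at float32 precision.
#'
#' @param dir Directory containing `signals.bin`, `manifest.csv`,
#'   `classes.txt`.
#' @return An `ecg_dataset`; when the manifest carries a `split` column, an
#'   `ecg_split` is attached as attribute `"split"`.
#' @export
read_ecg_dataset <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE,
                              col_types = readr::cols(
                                record_id = readr::col_character(),
                                labels = readr::col_character()))
  classes <- readLines(file.path(dir, "classes.txt"), warn = FALSE)
  con <- file(file.path(dir, "signals.bin"), "rb")
  on.exit(close(con))
  records <- lapply(seq_len(nrow(manifest)), function(i) {
    nl <- manifest$n_leads[i]
    ns <- manifest$n_samples[i]
    v <- readBin(con, what = "numeric", size = 4L, endian = "little",
                 n = nl * ns)
    if (length(v) < nl * ns) abort("signals.bin is truncated.")
    sig <- t(matrix(v, nrow = ns, ncol = nl)) # undo lead-major flattening
    rownames(sig) <- lead_names(nl)
    labs <- manifest$labels[i]
    labs <- if (is.na(labs) || !nzchar(labs)) character()
            else strsplit(labs, ",", fixed = TRUE)[[1]]
    ecg_record(manifest$record_id[i], sig, manifest$rate[i], labs)
  })
  label_sets <- lapply(records, `[[`, "labels")
  ds <- structure(
    list(records = records, labels = encode_multihot(label_sets, classes),
         classes = classes, config = NULL),
    class = "ecg_dataset"
  )
  rownames(ds$labels) <- manifest$record_id
  if ("split" %in% names(manifest)) {
    attr(ds, "split") <- structure(
      list(train = which(manifest$split == "train"),
           val = which(manifest$split == "val"),
           test = which(manifest$split == "test"),
           fractions = NULL, seed = NA),
      class = "ecg_split"
    )
  }
  ds
}
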