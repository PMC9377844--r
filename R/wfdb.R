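# Minimal WFDB support: header (.hea) plus format-16 signal (.dat) files,
# the combination used by PTB-XL. Values are returned in physical units
# (mV) via (adc - baseline) / gain.

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n_sig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  n_samp <- as.integer(top[4])
  sig <- lapply(lines[1 + seq_len(n_sig)], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    gain_spec <- f[3]
    gain <- as.numeric(sub("^([-0-9.eE+]+).*$", "\\1", gain_spec))
    baseline <- if (grepl("\\(", gain_spec)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_spec))
    } else if (length(f) >= 5) as.numeric(f[5]) else 0
    list(file = f[1], format = as.integer(f[2]), gain = gain,
         baseline = baseline,
         description = if (length(f) >= 9) paste(f[9:length(f)], collapse = " ")
                       else NA_character_)
  })
  list(record = top[1], n_sig = n_sig, fs = fs, n_samp = n_samp, signals = sig)
}

#' Read one WFDB record (header + format-16 signal file)
#'
#' @param path Path to the record without extension (or to the `.hea` file).
#' @param labels Optional label set to attach.
#' @param patient_id Optional patient identifier.
#' @return An [ecg_record()] with the signal in physical units (mV).
#' @export
read_wfdb_record <- function(path, labels = character(), patient_id = NA) {
  path <- sub("\\.hea$", "", path)
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) {
    abort(sprintf("WFDB header not found for record: %s", path))
  }
  h <- parse_wfdb_header(hea)
  fmts <- vapply(h$signals, `[[`, integer(1), "format")
  if (!all(fmts == 16L)) {
    abort(sprintf("Only WFDB format 16 is supported (record %s).", h$record))
  }
  dat <- file.path(dirname(hea), h$signals[[1]]$file)
  if (!file.exists(dat)) {
    abort(sprintf("WFDB signal file not found: %s", dat))
  }
  adc <- readBin(dat, what = "integer", size = 2L, signed = TRUE,
                 endian = "little", n = h$n_sig * h$n_samp)
  if (length(adc) < h$n_sig * h$n_samp) {
    abort(sprintf("Signal file %s is truncated.", dat))
  }
  m <- matrix(as.numeric(adc), nrow = h$n_sig) # interleaved frames -> rows
  gain <- vapply(h$signals, `[[`, numeric(1), "gain")
  base <- vapply(h$signals, `[[`, numeric(1), "baseline")
  m <- (m - base) / gain
  desc <- vapply(h$signals, `[[`, character(1), "description")
  rownames(m) <- ifelse(is.na(desc), lead_names(h$n_sig), desc)
  ecg_record(basename(path), m, h$fs, labels, patient_id)
}

#' Write one record as a WFDB header + format-16 signal pair
#'
#' Values are quantized to `round(signal * gain)` ADC units, so a round trip
#' through [read_wfdb_record()] reproduces the signal to within `0.5 / gain`.
#'
#' @param record An [ecg_record()].
#' @param path Output path without extension.
#' @param gain ADC units per mV. Default 1000.
#' @return Invisibly, `path`.
#' @export
write_wfdb_record <- function(record, path, gain = 1000) {
  stopifnot(inherits(record, "ecg_record"))
  adc <- round(record$signal * gain)
  if (any(abs(adc) > 32767)) abort("Signal exceeds 16-bit ADC range.")
  name <- basename(path)
  header <- c(
    sprintf("%s %d %g %d", name, nrow(adc), record$rate, ncol(adc)),
    sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 %s",
            name, gain, as.integer(adc[, 1]), rownames(adc))
  )
  writeLines(header, paste0(path, ".hea"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(adc), con, size = 2L, endian = "little")
  invisible(path)
}

# Parse the python-dict-like scp_codes column of ptbxl_database.csv,
# e.g. "{'NORM': 100.0, 'SR': 0.0}" -> c("NORM", "SR").
parse_scp_codes <- function(x) {
  m <- regmatches(x, gregexpr("'([^']+)'", x))[[1]]
  gsub("'", "", m)
}

#' Load a PTB-XL-style dataset directory
#'
#' Reads `ptbxl_database.csv` and the referenced WFDB waveform files at the
#' requested sampling rate (100 Hz: 1000 samples; 500 Hz: 5000 samples per
#' 10 s record). Labels are the record's SCP statements; with
#' `diagnostic_only = TRUE` (default) they are restricted to the diagnostic
#' statements of `hierarchy`.
#'
#' @param root Dataset root directory containing `ptbxl_database.csv`.
#' @param rate 100 or 500 (Hz).
#' @param hierarchy Label hierarchy; defaults to `scp_statements.csv` under
#'   `root` when present, else [ptbxl_hierarchy()].
#' @param diagnostic_only Drop non-diagnostic (form/rhythm) statements.
#' @return List of [ecg_record()] objects with patient ids attached.
#' @export
load_ptbxl <- function(root, rate = 100, hierarchy = NULL,
                       diagnostic_only = TRUE) {
  if (!rate %in% c(100, 500)) abort("`rate` must be 100 or 500 Hz.")
  meta_path <- file.path(root, "ptbxl_database.csv")
  if (!file.exists(meta_path)) {
    abort(sprintf("Metadata not found: %s", meta_path))
  }
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  if (is.null(hierarchy)) {
    scp <- file.path(root, "scp_statements.csv")
    hierarchy <- if (file.exists(scp)) hierarchy_from_scp_statements(scp)
                 else ptbxl_hierarchy()
  }
  fn_col <- if (rate == 100) "filename_lr" else "filename_hr"
  if (!fn_col %in% names(meta)) {
    abort(sprintf("Metadata lacks column %s.", fn_col))
  }
  lapply(seq_len(nrow(meta)), function(i) {
    labs <- parse_scp_codes(meta$scp_codes[i])
    if (diagnostic_only) labs <- intersect(labs, hierarchy$diagnostic)
    rec <- read_wfdb_record(file.path(root, meta[[fn_col]][i]), labels = labs,
                            patient_id = meta$patient_id[i])
    rec$id <- as.character(meta$ecg_id[i])
    rec
  })
}
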