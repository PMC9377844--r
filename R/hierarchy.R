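#' Diagnostic statement hierarchy of the PTB-XL dataset
#'
#' The 44 diagnostic SCP-ECG statements arranged into 23 subclasses and the
#' 5 superclasses CD (conduction disturbance), HYP (hypertrophy),
#' MI (myocardial infarction), NORM and STTC (ST/T change). Each diagnostic
#' statement maps to exactly one subclass and one superclass.
#'
#' @return A tibble with columns `diagnostic`, `subclass`, `superclass` and
#'   one row per diagnostic statement.
#' @examples
#' h <- ptbxl_hierarchy()
#' nrow(h) # 44
#' @export
ptbxl_hierarchy <- function() {
  rows <- list(
    # superclass CD
    c("IRBBB", "IRBBB", "CD"), c("IVCD", "IVCD", "CD"),
    c("CRBBB", "CRBBB", "CD"), c("CLBBB", "CLBBB", "CD"),
    c("LAFB", "LAFB/LPFB", "CD"), c("LPFB", "LAFB/LPFB", "CD"),
    c("WPW", "WPW", "CD"), c("ILBBB", "ILBBB", "CD"),
    c("3AVB", "_AVB", "CD"), c("2AVB", "_AVB", "CD"), c("AVB", "_AVB", "CD"),
    # superclass HYP
    c("LVH", "LVH", "HYP"), c("LAO/LAE", "LAO/LAE", "HYP"),
    c("RVH", "RVH", "HYP"), c("RAO/LAE", "RAO/LAE", "HYP"),
    c("SEHYP", "SEHYP", "HYP"),
    # superclass MI
    c("INJLA", "AMI", "MI"), c("ASMI", "AMI", "MI"), c("INJAL", "AMI", "MI"),
    c("AMI", "AMI", "MI"), c("ALMI", "AMI", "MI"), c("INJAS", "AMI", "MI"),
    c("LMI", "LMI", "MI"),
    c("IPLMI", "IMI", "MI"), c("IPMI", "IMI", "MI"), c("ILMI", "IMI", "MI"),
    c("INJIL", "IMI", "MI"), c("IMI", "IMI", "MI"), c("INJIN", "IMI", "MI"),
    c("PMI", "PMI", "MI"),
    # superclass NORM
    c("NORM", "NORM", "NORM"),
    # superclass STTC
    c("NDT", "STTC", "STTC"), c("DIG", "STTC", "STTC"),
    c("ANEUR", "STTC", "STTC"), c("EL", "STTC", "STTC"),
    c("LNGQT", "STTC", "STTC"),
    c("NST_", "NST_", "STTC"), c("ISC_", "ISC_", "STTC"),
    c("ISCIN", "ISCI", "STTC"), c("ISCIL", "ISCI", "STTC"),
    c("ISCAL", "ISCA", "STTC"), c("ISCAS", "ISCA", "STTC"),
    c("ISCLA", "ISCA", "STTC"), c("ISCAN", "ISCA", "STTC")
  )
  m <- do.call(rbind, rows)
  tibble(diagnostic = m[, 1], subclass = m[, 2], superclass = m[, 3])
}

#' Build a label hierarchy from a PTB-XL `scp_statements.csv`
#'
#' Reads the statement dictionary shipped with PTB-XL and keeps the rows
#' flagged as diagnostic, yielding the same three-level mapping as
#' [ptbxl_hierarchy()] but sourced from the dataset itself.
#'
#' @param path Path to `scp_statements.csv`.
#' @return A tibble with columns `diagnostic`, `subclass`, `superclass`.
#' @export
hierarchy_from_scp_statements <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  code_col <- names(df)[1]
  keep <- !is.na(df$diagnostic) & df$diagnostic == 1
  tibble(
    diagnostic = as.character(df[[code_col]][keep]),
    subclass = as.character(df$diagnostic_subclass[keep]),
    superclass = as.character(df$diagnostic_class[keep])
  )
}

#' Rewrite record label sets at a chosen hierarchy level
#'
#' Maps each diagnostic statement to itself (`level = "diagnostic"`), to its
#' subclass, or to its superclass, collapsing duplicates with set semantics.
#' Labels listed in `non_diagnostic` (form/rhythm statements) are dropped;
#' any other label missing from the hierarchy is an error.
#'
#' @param records List of [ecg_record()] objects.
#' @param hierarchy A hierarchy tibble such as [ptbxl_hierarchy()].
#' @param level One of `"superdiagnostic"`, `"subdiagnostic"`, `"diagnostic"`.
#' @param non_diagnostic Character vector of known non-diagnostic statements
#'   to drop silently.
#' @return The records with rewritten label sets.
#' @examples
#' r <- ecg_record("x", matrix(0 + 1e-12, 1, 4), 100, c("ASMI", "ILMI"))
#' aggregate_labels(list(r), ptbxl_hierarchy(), "superdiagnostic")[[1]]$labels
#' @export
aggregate_labels <- function(records, hierarchy,
                             level = c("superdiagnostic", "subdiagnostic",
                                       "diagnostic"),
                             non_diagnostic = character()) {
  level <- match.arg(level)
  target <- switch(level,
                   superdiagnostic = hierarchy$superclass,
                   subdiagnostic = hierarchy$subclass,
                   diagnostic = hierarchy$diagnostic)
  map <- stats::setNames(target, hierarchy$diagnostic)
  lapply(records, function(r) {
    labs <- setdiff(r$labels, non_diagnostic)
    unmapped <- setdiff(labs, names(map))
    if (length(unmapped)) {
      abort(sprintf("Unmapped diagnostic label(s) in record %s: %s",
                    r$id, paste(unmapped, collapse = ", ")))
    }
    r$labels <- sort(unique(unname(map[labs])))
    r
  })
}
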