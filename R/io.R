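# Tabular and JSON I/O: drug tables, DDI triplet tables (CSV/TSV with
# delimiter auto-detection), split-plan serialization, metric reports.

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a drug table
#'
#' Expects header columns `drug_id` and `smiles`; the delimiter (comma or
#' tab) is auto-detected unless given.
#'
#' @param path CSV/TSV file path.
#' @param sep Optional delimiter override.
#' @return data.frame with `drug_id`, `smiles`.
#' @export
read_drug_table <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  need <- c("drug_id", "smiles")
  if (!all(need %in% names(df))) {
    stop(sprintf("read_drug_table: %s must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  df$drug_id <- as.character(df$drug_id)
  df$smiles <- as.character(df$smiles)
  df
}

#' Read a DDI triplet table
#'
#' Expects header columns `drug_a`, `drug_b` and either `label` (0/1) or
#' `type` (collapsed to binary by [canonical_triplets()]).
#'
#' @inheritParams read_drug_table
#' @return Canonical triplet data.frame.
#' @export
read_ddi_table <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  canonical_triplets(df)
}

#' Serialize a split plan to JSON
#'
#' Records the mode, seed and assignments so a split can be reproduced and
#' shared across models.
#'
#' @param plan A `split_plan`.
#' @param path Output JSON path.
#' @export
write_split_plan <- function(plan, path) {
  stopifnot(inherits(plan, "split_plan"))
  obj <- unclass(plan)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a split plan from JSON
#'
#' @param path JSON path written by [write_split_plan()].
#' @return A `split_plan`.
#' @export
read_split_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$triplets <- as.data.frame(obj$triplets, stringsAsFactors = FALSE)
  if (!is.null(obj$negatives)) {
    obj$negatives <- as.data.frame(obj$negatives, stringsAsFactors = FALSE)
  }
  structure(obj, class = "split_plan")
}

#' Write a metrics report (plus provenance) to JSON
#'
#' @param report A `metrics_report`.
#' @param path Output JSON path.
#' @param extra Optional named list appended to the record (seed, config
#'   hash, ...).
#' @export
write_metrics_report <- function(report, path, extra = list()) {
  stopifnot(inherits(report, "metrics_report"))
  obj <- c(unclass(report), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
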