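#' Build or validate a drug-response table
#'
#' A response table is a tibble of per-sample drug measurements: IC50 (uM)
#' and/or dose-response AUC, with patient lineage (patient id, ordinal time
#' point) so repeated samples from one patient can be deduplicated. One row
#' per (sample, drug).
#'
#' @param data A data frame with columns `sample_id`, `patient_id`,
#'   `time_point`, `drug`, and at least one of `ic50_uM`, `auc`.
#' @return A validated tibble with a `binary_class` column (initially `NA`).
#' @export
response_table <- function(data) {
  data <- as_tibble(data)
  needed <- c("sample_id", "patient_id", "time_point", "drug")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(sprintf("response table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (!"ic50_uM" %in% names(data)) data$ic50_uM <- NA_real_
  if (!"auc" %in% names(data)) data$auc <- NA_real_
  if (!"binary_class" %in% names(data)) data$binary_class <- NA_character_
  if (any(is.na(data$ic50_uM) & is.na(data$auc))) {
    abort("each row needs at least one of ic50_uM, auc")
  }
  if (any(!is.na(data$ic50_uM) & data$ic50_uM <= 0)) {
    abort("ic50_uM must be positive")
  }
  key <- paste(data$sample_id, data$drug, sep = "\r")
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate (sample_id, drug) row(s): %s",
                  paste(head(unique(data$sample_id[duplicated(key)]), 5),
                        collapse = ", ")))
  }
  data[c("sample_id", "patient_id", "time_point", "drug",
         "ic50_uM", "auc", "binary_class")]
}

#' Read a response table from TSV
#'
#' Expected columns: `sample_id`, `patient_id`, `time_point`, `drug`,
#' `ic50_uM`, `auc`.
#'
#' @param path TSV path.
#' @return A response tibble (see [response_table()]).
#' @export
load_response_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  response_table(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE))
}

#' Write a response table to TSV
#' @param x Response tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Binarize IC50 into sensitive / resistant / excluded classes
#'
#' Samples are called sensitive when IC50 <= `sensitive_max` (1 uM) and
#' resistant when IC50 >= `resistant_min` (10 uM), both boundaries inclusive;
#' values strictly between the thresholds are labeled `excluded` and dropped
#' from classification downstream.
#'
#' @param table Response tibble.
#' @param drug Drug name to binarize; other drugs' rows pass through.
#' @param sensitive_max Upper IC50 bound (uM) for the sensitive class.
#' @param resistant_min Lower IC50 bound (uM) for the resistant class.
#' @return The tibble with `binary_class` filled for `drug` rows.
#' @export
binarize_response <- function(table, drug, sensitive_max = 1,
                              resistant_min = 10) {
  table <- response_table(table)
  if (sensitive_max >= resistant_min) {
    abort("`sensitive_max` must be strictly below `resistant_min`")
  }
  sel <- table$drug == drug
  if (any(sel & is.na(table$ic50_uM))) {
    abort(sprintf("missing ic50_uM for drug '%s'", drug))
  }
  ic <- table$ic50_uM[sel]
  cls <- ifelse(ic <= sensitive_max, "sensitive",
                ifelse(ic >= resistant_min, "resistant", "excluded"))
  table$binary_class[sel] <- cls
  table
}

#' Keep only the latest time point within each patient and response group
#'
#' When one patient contributes several samples assigned to the same response
#' group, only the sample with the maximal time point is retained; samples of
#' the same patient falling in different groups are all kept. Ties at the
#' maximal time point are ambiguous and raise an error naming the samples.
#'
#' @param table Response tibble with `binary_class` assigned.
#' @return The deduplicated tibble (never more rows; idempotent).
#' @export
deduplicate_by_latest_timepoint <- function(table) {
  table <- response_table(table)
  if (all(is.na(table$binary_class))) {
    abort("binary_class must be assigned before deduplication (see binarize_response)")
  }
  grp <- paste(table$patient_id, table$drug, table$binary_class, sep = "\r")
  keep <- rep(TRUE, nrow(table))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2) next
    tp <- table$time_point[idx]
    top <- idx[tp == max(tp)]
    if (length(top) > 1) {
      abort(sprintf("tied maximal time_point within a patient/response group: %s",
                    paste(table$sample_id[top], collapse = ", ")))
    }
    keep[setdiff(idx, top)] <- FALSE
  }
  table[keep, ]
}
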