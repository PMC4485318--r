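#' Validate survival records
#'
#' Survival records carry per-patient follow-up: `sample_id`, `time` (study
#' time units, strictly positive), `event` (1 = outcome observed, 0 =
#' censored) and `endpoint` (`"DMFS"` distant metastasis-free survival or
#' `"RFS"` recurrence-free survival).
#'
#' @param df A data frame with columns `sample_id`, `time`, `event`,
#'   `endpoint`.
#' @return The validated data frame, classed `survival_records`.
#' @export
survival_records <- function(df) {
  need <- c("sample_id", "time", "event", "endpoint")
  if (!all(need %in% names(df)))
    validation_error("survival records need columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    validation_error("duplicate sample ids in survival records")
  if (!is.numeric(df$time) || any(!is.finite(df$time)) || any(df$time <= 0))
    validation_error("survival time must be finite and > 0")
  if (!all(df$event %in% c(0, 1)))
    validation_error("event indicator must be 0 (censored) or 1 (event)")
  if (!all(df$endpoint %in% ENDPOINTS))
    validation_error("endpoint must be one of: ", paste(ENDPOINTS, collapse = ", "))
  df <- df[, need]
  df$event <- as.integer(df$event)
  class(df) <- c("survival_records", "data.frame")
  df
}

#' Read a clinical TSV into survival records
#'
#' Header and columns `sample_id`, `time`, `event`, `endpoint`; row order is
#' preserved.
#'
#' @param path File to read.
#' @return A [survival_records()] data frame.
#' @export
read_clinical_tsv <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  survival_records(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write survival records as TSV
#' @param records A [survival_records()] data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_clinical_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a sample annotation table
#'
#' Per-sample metadata driving atlas filtering and contrasts: `sample_id`,
#' `tissue_name`, `sample_class` (`adult`/`embryo`), `embryonic_stage`
#' (`E6.5`..`E10.5` or `none`), and the exclusion flags `is_cell_line`,
#' `is_stimulated`, `is_undeveloped`. A sample is of class `embryo` if and
#' only if it carries an embryonic stage.
#'
#' @param df Data frame with the columns above.
#' @return The validated data frame, classed `sample_annotation`.
#' @export
sample_annotation <- function(df) {
  need <- c("sample_id", "tissue_name", "sample_class", "embryonic_stage",
            "is_cell_line", "is_stimulated", "is_undeveloped")
  if (!all(need %in% names(df)))
    validation_error("sample annotation needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    validation_error("duplicate sample ids in annotation")
  if (!all(df$sample_class %in% c("adult", "embryo")))
    validation_error("sample_class must be 'adult' or 'embryo'")
  if (!all(df$embryonic_stage %in% c(EMBRYONIC_STAGES, "none")))
    validation_error("embryonic_stage must be one of ",
                     paste(c(EMBRYONIC_STAGES, "none"), collapse = ", "))
  staged <- df$embryonic_stage != "none"
  if (!all(staged == (df$sample_class == "embryo")))
    validation_error("sample_class 'embryo' must coincide with a non-'none' embryonic_stage")
  for (fl in c("is_cell_line", "is_stimulated", "is_undeveloped"))
    if (!is.logical(df[[fl]]) || anyNA(df[[fl]]))
      validation_error(fl, " must be TRUE/FALSE")
  df <- df[, need]
  class(df) <- c("sample_annotation", "data.frame")
  df
}

#' Read a sample annotation TSV
#' @param path File to read.
#' @return A [sample_annotation()] data frame.
#' @export
read_annotation_tsv <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (fl in c("is_cell_line", "is_stimulated", "is_undeveloped"))
    if (fl %in% names(df)) df[[fl]] <- as.logical(df[[fl]])
  sample_annotation(df)
}

#' Write a sample annotation TSV
#' @param annotation A [sample_annotation()] data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
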