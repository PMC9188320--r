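# Deidentification of OCR output: mask patient names, medical record
# numbers, and dates with placeholders. Masking never changes word count,
# order, or geometry, and the placeholders never match the downstream
# numeric-candidate pattern.

#' Mask patient name and MRN words
#'
#' Each token of the patient's name is matched case-insensitively and
#' exactly against the OCR word texts and replaced by `"[PATNAME]"`; words
#' equal to the medical record number become `"[MRN]"`. The operation fails
#' closed: a `report_id` absent from the lookup is an error.
#'
#' @param words OCR word tibble for one report.
#' @param lookup PHI lookup tibble with columns `report_id`, `name`,
#'   `mrn`.
#' @param report_id The report the words belong to.
#' @return The word tibble with masked text.
#' @export
mask_phi <- function(words, lookup, report_id) {
  row <- lookup[lookup$report_id == report_id, , drop = FALSE]
  if (nrow(row) == 0) {
    abort(paste0("report '", report_id,
                 "' is missing from the PHI lookup table (failing closed)"))
  }
  assert_that(nzchar(row$name[1]) && nzchar(row$mrn[1]),
              "PHI lookup name and MRN must be non-empty")
  name_tokens <- tolower(strsplit(row$name[1], "\\s+")[[1]])
  lowered <- tolower(words$text)
  words$text[lowered %in% name_tokens] <- "[PATNAME]"
  words$text[words$text == row$mrn[1]] <- "[MRN]"
  words
}

#' Mask date-formatted words
#'
#' Words fully matching a `d/d/yyyy`-shaped pattern (1-2 digit day and
#' month, 2 or 4 digit year) are replaced by `"[DATE]"`. The broad pattern
#' fails safe for privacy.
#'
#' @param words OCR word tibble.
#' @return The word tibble with masked text.
#' @export
mask_dates <- function(words) {
  hit <- grepl("^\\d{1,2}/\\d{1,2}/(\\d{4}|\\d{2})$", words$text)
  words$text[hit] <- "[DATE]"
  words
}

#' Deidentify a whole corpus word table
#'
#' Applies [mask_phi()] per report and [mask_dates()] to the word table of
#' a multi-report corpus.
#'
#' @param words OCR word tibble with a `report_id` column.
#' @param lookup PHI lookup tibble.
#' @return The deidentified word tibble (same row order).
#' @export
deid_corpus <- function(words, lookup) {
  out <- words %>%
    group_by(.data$report_id) %>%
    dplyr::group_modify(~ mask_phi(.x, lookup, .y$report_id)) %>%
    ungroup()
  mask_dates(out[order(match(out$report_id, unique(words$report_id)),
                       out$order_idx), , drop = FALSE])
}
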