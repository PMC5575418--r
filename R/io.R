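# Readers and writers. CSV dialect: comma-separated, UTF-8, header row
# required, empty cell = missing, decimal point. Numeric fields round-trip
# losslessly (shortest round-trip representation on write).

items_cols <- function() {
  readr::cols(patient_id = readr::col_character(),
              item_id = readr::col_character(),
              response = readr::col_double())
}

check_problems <- function(df, path) {
  probs <- readr::problems(df)
  if (nrow(probs)) {
    stop_parse(paste0(
      "Malformed rows in ", path, ": ",
      paste(sprintf("line %s (%s)", probs$row, probs$expected),
            collapse = "; ")
    ))
  }
  df
}

#' Read item-level responses
#'
#' Long format: columns `patient_id`, `item_id`, `response` (empty cell =
#' missing). An empty file yields an empty record list with a warning.
#'
#' @param path CSV file.
#' @return A tibble suitable for [score_responses()].
#' @export
read_items <- function(path) {
  df <- suppressWarnings(readr::read_csv(path, col_types = items_cols(),
                        na = c("", "NA"), progress = FALSE))
  check_problems(df, path)
  missing_cols <- setdiff(c("patient_id", "item_id", "response"), names(df))
  if (length(missing_cols)) {
    stop_parse(paste0(path, " lacks column(s): ",
                      paste(missing_cols, collapse = ", ")))
  }
  if (!nrow(df)) warn(paste0(path, " contains no response rows."))
  dup <- df %>% count(.data$patient_id, .data$item_id) %>% filter(.data$n > 1)
  if (nrow(dup)) {
    stop_parse(paste0("Duplicate response rows in ", path, " for patient ",
                      dup$patient_id[1], ", item ", dup$item_id[1], "."))
  }
  df
}

#' Read wide-format item responses
#'
#' One row per patient, one column per item id, plus a `patient_id`
#' column; pivoted to the long format used by [score_responses()].
#'
#' @param path CSV file.
#' @return A long tibble: `patient_id`, `item_id`, `response`.
#' @export
read_items_wide <- function(path) {
  df <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    .default = readr::col_double()
  ), na = c("", "NA"), progress = FALSE))
  check_problems(df, path)
  if (!"patient_id" %in% names(df)) {
    stop_parse(paste0(path, " lacks a patient_id column."))
  }
  df %>%
    tidyr::pivot_longer(-"patient_id", names_to = "item_id",
                        values_to = "response")
}

#' @rdname read_items
#' @param items Long tibble to write.
#' @export
write_items <- function(items, path) {
  readr::write_csv(items, path, na = "")
  invisible(path)
}

#' Read a demographics table
#'
#' Columns `patient_id`, `sex` (`male`/`female`), `age` (years).
#'
#' @param path CSV file.
#' @return A tibble.
#' @export
read_demographics <- function(path) {
  df <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    sex = readr::col_character(),
    age = readr::col_double()
  ), na = c("", "NA"), progress = FALSE))
  check_problems(df, path)
  missing_cols <- setdiff(c("patient_id", "sex", "age"), names(df))
  if (length(missing_cols)) {
    stop_parse(paste0(path, " lacks column(s): ",
                      paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(df$sex), c("male", "female", NA))
  if (length(bad)) {
    stop_parse(paste0("Unknown sex value(s) in ", path, ": ",
                      paste(bad, collapse = ", ")))
  }
  df
}

#' @rdname read_demographics
#' @param demographics Tibble to write.
#' @export
write_demographics <- function(demographics, path) {
  readr::write_csv(demographics, path, na = "")
  invisible(path)
}

#' Read / write a norm table
#'
#' CSV columns: `comparator`, `scale_id`, `sex`, `age_lo`, `age_hi`
#' (`Inf` for the open-ended band), `mean`, `sd`, `n`. Validated on read
#' (duplicate (comparator, scale, sex, band) keys are a parse error
#' naming the key); numeric fields round-trip exactly.
#'
#' @param path CSV file.
#' @param scales Optional scale registry for range checks.
#' @return A validated norm tibble.
#' @export
read_norms <- function(path, scales = NULL) {
  df <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    comparator = readr::col_character(),
    scale_id = readr::col_character(),
    sex = readr::col_character(),
    age_lo = readr::col_double(),
    age_hi = readr::col_double(),
    mean = readr::col_double(),
    sd = readr::col_double(),
    n = readr::col_integer()
  ), na = c("", "NA"), progress = FALSE))
  check_problems(df, path)
  validate_norms(df, scales)
  df
}

#' @rdname read_norms
#' @param norms Norm tibble to write.
#' @export
write_norms <- function(norms, path) {
  validate_norms(norms)
  readr::write_csv(norms, path, na = "")
  invisible(path)
}

#' Read / write feedback selections as JSON
#'
#' An array of objects with fields `patient_id`, `wants_feedback`,
#' `topics`, `comparators`.
#'
#' @param path JSON file.
#' @return A tibble with list-columns `topics` and `comparators`.
#' @export
read_selections <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  tibble(
    patient_id = vapply(raw, function(x) x$patient_id, character(1)),
    wants_feedback = vapply(raw, function(x) isTRUE(x$wants_feedback),
                            logical(1)),
    topics = lapply(raw, function(x) as.character(unlist(x$topics))),
    comparators = lapply(raw, function(x) as.character(unlist(x$comparators)))
  )
}

#' @rdname read_selections
#' @param selections Tibble (as from [simulate_cohort()]) to write.
#' @export
write_selections <- function(selections, path) {
  out <- lapply(seq_len(nrow(selections)), function(i) {
    list(patient_id = selections$patient_id[i],
         wants_feedback = selections$wants_feedback[i],
         topics = as.list(selections$topics[[i]]),
         comparators = as.list(selections$comparators[[i]]))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Convert a selections row to a feedback_selection
#'
#' @param selections Selections tibble.
#' @param patient_id Which patient.
#' @return A [feedback_selection()].
#' @export
as_feedback_selection <- function(selections, patient_id) {
  row <- selections[selections$patient_id == patient_id, ]
  if (nrow(row) != 1) {
    stop_config(paste0("No selection row for patient ", patient_id, "."))
  }
  if (!row$wants_feedback) {
    return(feedback_selection(patient_id, wants_feedback = FALSE))
  }
  feedback_selection(patient_id, TRUE,
                     topics = row$topics[[1]],
                     comparators = row$comparators[[1]])
}
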