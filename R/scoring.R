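# Scoring: item responses -> scale scores.
#
# EORTC scales use the published two-step procedure: raw score = mean of
# answered items (scored if at least half the items are answered), then a
# linear transform to 0-100. HADS subscales are summed to 0-21, prorating
# when exactly one of the 7 items is missing.

#' Raw score of one scale for one respondent
#'
#' The mean of the answered item responses, provided the scale's
#' completeness rule passes: for EORTC scales at least half of the items
#' answered (the "half rule"); for HADS at most one of the 7 items
#' missing. Otherwise `NA`.
#'
#' @param responses Named numeric vector of item responses (`NA` =
#'   missing). Must contain an entry (possibly `NA`) for every item of the
#'   scale.
#' @param scale A one-row scale registry tibble (see [default_scales()]).
#' @param min_prop_answered Completeness threshold for EORTC scales as a
#'   proportion of items; default 0.5.
#' @param hads_max_missing Maximum missing items tolerated on a HADS
#'   subscale; default 1.
#'
#' @return The raw score (mean of answered responses) or `NA`.
#' @export
#' @examples
#' sc <- default_scales()[default_scales()$scale_id == "fatigue", ]
#' raw_score(c(c30_q10 = 2, c30_q12 = 3, c30_q18 = NA), sc)
raw_score <- function(responses, scale, min_prop_answered = 0.5,
                      hads_max_missing = 1L) {
  items <- scale$items[[1]]
  missing_ids <- setdiff(items$item_id, names(responses))
  if (length(missing_ids)) {
    stop_config(paste0(
      "Responses lack entries for item(s) of scale ", scale$scale_id, ": ",
      paste(missing_ids, collapse = ", ")
    ))
  }
  vals <- as.numeric(responses[items$item_id])
  check_item_range(vals, items, scale$scale_id)
  n_total <- nrow(items)
  n_answered <- sum(!is.na(vals))
  ok <- if (scale$transform == "hads_sum") {
    (n_total - n_answered) <= hads_max_missing
  } else {
    n_answered >= min_prop_answered * n_total
  }
  if (!ok || n_answered == 0) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

check_item_range <- function(vals, items, scale_id, patient_id = NULL) {
  bad <- which(!is.na(vals) &
                 (vals < items$response_min | vals > items$response_max |
                    vals != round(vals)))
  if (length(bad)) {
    who <- if (is.null(patient_id)) "" else paste0("patient ", patient_id, ", ")
    stop_domain(paste0(
      "Response out of range (", who, "item ", items$item_id[bad[1]],
      ", scale ", scale_id, "): got ", vals[bad[1]], ", allowed ",
      items$response_min[bad[1]], "-", items$response_max[bad[1]], "."
    ))
  }
  invisible(vals)
}

#' Linear transform of an EORTC raw score to the 0-100 scale
#'
#' Functioning scales: `S = (1 - (raw - min) / range) * 100`, so the
#' favorable extreme scores 100. Symptom scales and the global scale:
#' `S = ((raw - min) / range) * 100` (for the global scale the item range
#' is 6, items being coded 1-7). All transformed scores lie in \[0, 100\].
#'
#' @param raw Raw score (mean of item responses); vectorized.
#' @param scale A one-row scale registry tibble with an EORTC transform.
#' @return Transformed score(s) in \[0, 100\].
#' @export
#' @examples
#' pf <- default_scales()[1, ]
#' transform_score(1, pf)   # 100
#' transform_score(2.5, pf) # 50
transform_score <- function(raw, scale) {
  if (scale$transform == "hads_sum") {
    stop_config("transform_score() applies to EORTC scales; HADS subscales are summed.")
  }
  items <- scale$items[[1]]
  lo <- items$response_min[1]
  hi <- items$response_max[1]
  rng <- hi - lo
  out_of_range <- !is.na(raw) & (raw < lo | raw > hi)
  if (any(out_of_range)) {
    stop_domain(paste0(
      "Raw score ", raw[out_of_range][1], " outside item range [",
      lo, ", ", hi, "] for scale ", scale$scale_id, "."
    ))
  }
  prop <- (raw - lo) / rng
  if (scale$transform == "eortc_functioning") {
    (1 - prop) * 100
  } else {
    prop * 100
  }
}

#' Score a HADS subscale
#'
#' Sum of the 7 item responses (0-3 each), giving 0-21; higher scores mean
#' more anxiety or depressive symptoms. If exactly one item is missing the
#' sum is prorated (`sum * 7 / 6`); with more than one missing the score
#' is `NA`.
#'
#' @inheritParams raw_score
#' @param patient_id Optional id used in the returned row.
#' @return A one-row tibble: `patient_id`, `scale_id`, `value`,
#'   `n_items_total`, `n_items_answered`.
#' @export
score_hads <- function(responses, scale, patient_id = NA_character_,
                       hads_max_missing = 1L) {
  if (scale$instrument != "HADS") {
    stop_config("score_hads() expects a HADS subscale definition.")
  }
  m <- raw_score(responses, scale, hads_max_missing = hads_max_missing)
  items <- scale$items[[1]]
  vals <- as.numeric(responses[items$item_id])
  tibble(
    patient_id = patient_id,
    scale_id = scale$scale_id,
    value = if (is.na(m)) NA_real_ else m * nrow(items),
    n_items_total = nrow(items),
    n_items_answered = sum(!is.na(vals))
  )
}

score_one <- function(responses, scale, patient_id = NA_character_,
                      min_prop_answered = 0.5, hads_max_missing = 1L) {
  if (scale$transform == "hads_sum") {
    return(score_hads(responses, scale, patient_id,
                      hads_max_missing = hads_max_missing))
  }
  m <- raw_score(responses, scale, min_prop_answered = min_prop_answered)
  items <- scale$items[[1]]
  vals <- as.numeric(responses[items$item_id])
  tibble(
    patient_id = patient_id,
    scale_id = scale$scale_id,
    value = if (is.na(m)) NA_real_ else transform_score(m, scale),
    n_items_total = nrow(items),
    n_items_answered = sum(!is.na(vals))
  )
}

#' Score all scales for a cohort of item-level responses
#'
#' The main scoring entry point. Takes long-format item responses (one row
#' per patient per item) and returns one scored row per patient per scale,
#' applying the EORTC half rule, the 0-100 linear transform, and HADS
#' summation with single-item proration. Items absent from the data are
#' treated as missing; transformed values are kept at full floating
#' precision (round only at report time).
#'
#' @param items A data frame with columns `patient_id`, `item_id`,
#'   `response` (`NA` = missing).
#' @param scales Scale registry; defaults to [default_scales()].
#' @param min_prop_answered,hads_max_missing Completeness rules, see
#'   [raw_score()].
#' @param warn_unknown_items Warn about response rows whose `item_id`
#'   belongs to no scale in the registry (they are ignored). Default `TRUE`.
#'
#' @return A tibble: `patient_id`, `scale_id`, `value`, `n_items_total`,
#'   `n_items_answered`, one row per patient x scale.
#' @export
#' @examples
#' items <- tibble::tibble(
#'   patient_id = "P1",
#'   item_id = c("c30_q20", "c30_q25"),
#'   response = c(1, 2)
#' )
#' score_responses(items)
score_responses <- function(items, scales = default_scales(),
                            min_prop_answered = 0.5, hads_max_missing = 1L,
                            warn_unknown_items = TRUE) {
  validate_scales(scales)
  required <- c("patient_id", "item_id", "response")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols)) {
    stop_parse(paste0("Item data lacks column(s): ",
                      paste(missing_cols, collapse = ", ")))
  }
  if (!nrow(scales)) {
    return(tibble(patient_id = character(), scale_id = character(),
                  value = double(), n_items_total = integer(),
                  n_items_answered = integer()))
  }
  reg <- item_registry(scales)
  unknown <- setdiff(unique(items$item_id), reg$item_id)
  if (length(unknown) && warn_unknown_items) {
    warn(paste0("Ignoring ", length(unknown),
                " item id(s) not in the scale registry: ",
                paste(head(unknown, 5), collapse = ", "),
                if (length(unknown) > 5) ", ..." else ""))
  }
  dup <- items %>%
    count(.data$patient_id, .data$item_id) %>%
    filter(.data$n > 1)
  if (nrow(dup)) {
    stop_parse(paste0("Duplicate response rows for patient ",
                      dup$patient_id[1], ", item ", dup$item_id[1], "."))
  }

  joined <- items %>%
    inner_join(reg, by = "item_id")
  # range validation with patient + item named
  bad <- joined %>%
    filter(!is.na(.data$response) &
             (.data$response < .data$response_min |
                .data$response > .data$response_max |
                .data$response != round(.data$response)))
  if (nrow(bad)) {
    stop_domain(paste0(
      "Response out of range (patient ", bad$patient_id[1], ", item ",
      bad$item_id[1], ", scale ", bad$scale_id[1], "): got ",
      bad$response[1], ", allowed ", bad$response_min[1], "-",
      bad$response_max[1], "."
    ))
  }

  patients <- unique(items$patient_id)
  if (!length(patients) || !nrow(scales)) {
    return(tibble(patient_id = character(), scale_id = character(),
                  value = double(), n_items_total = integer(),
                  n_items_answered = integer()))
  }

  per <- joined %>%
    group_by(.data$patient_id, .data$scale_id) %>%
    summarise(
      n_items_answered = sum(!is.na(.data$response)),
      raw = mean(.data$response, na.rm = TRUE),
      .groups = "drop"
    )

  meta <- scales %>%
    mutate(n_items_total = vapply(.data$items, nrow, integer(1))) %>%
    select("scale_id", "transform", "n_items_total", "items")

  full <- tidyr::expand_grid(patient_id = patients,
                             scale_id = scales$scale_id) %>%
    left_join(per, by = c("patient_id", "scale_id")) %>%
    left_join(meta, by = "scale_id") %>%
    mutate(n_items_answered = ifelse(is.na(.data$n_items_answered), 0L,
                                     .data$n_items_answered))

  full$value <- NA_real_
  for (sid in scales$scale_id) {
    sc <- scale_row(scales, sid)
    idx <- which(full$scale_id == sid)
    n_ans <- full$n_items_answered[idx]
    raw <- full$raw[idx]
    n_tot <- sc$items[[1]] %>% nrow()
    if (sc$transform == "hads_sum") {
      ok <- (n_tot - n_ans) <= hads_max_missing & n_ans > 0
      full$value[idx] <- ifelse(ok, raw * n_tot, NA_real_)
    } else {
      ok <- n_ans >= min_prop_answered * n_tot & n_ans > 0
      val <- rep(NA_real_, length(idx))
      val[ok] <- transform_score(raw[ok], sc)
      full$value[idx] <- val
    }
  }

  full %>%
    transmute(
      patient_id = .data$patient_id,
      scale_id = .data$scale_id,
      value = .data$value,
      n_items_total = as.integer(.data$n_items_total),
      n_items_answered = as.integer(.data$n_items_answered)
    ) %>%
    arrange(match(.data$patient_id, patients),
            match(.data$scale_id, scales$scale_id))
}

#' Score a single respondent from a named response vector
#'
#' Convenience wrapper around [score_responses()] for one patient held as
#' a named vector, mirroring the per-record scoring functions.
#'
#' @param responses Named numeric vector (`NA` = missing).
#' @param scales Scale registry.
#' @param patient_id Id placed in the output.
#' @inheritParams score_responses
#' @return A tibble with one row per scale.
#' @export
score_record <- function(responses, scales = default_scales(),
                         patient_id = "patient",
                         min_prop_answered = 0.5, hads_max_missing = 1L) {
  validate_scales(scales)
  all_ids <- unlist(lapply(scales$items, function(x) x$item_id))
  absent <- setdiff(all_ids, names(responses))
  responses <- c(responses, setNames(rep(NA_real_, length(absent)), absent))
  bind_rows(lapply(seq_len(nrow(scales)), function(i) {
    score_one(responses, scales[i, ], patient_id,
              min_prop_answered = min_prop_answered,
              hads_max_missing = hads_max_missing)
  }))
}
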