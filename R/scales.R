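# Instrument registry: the EORTC QLQ-C30 scales fed back to patients, the
# added single-item tingling symptom, and the two HADS subscales.

#' Define a questionnaire scale
#'
#' Constructs one row of the scale registry used throughout the package.
#' Most users will start from [default_scales()] and add rows for further
#' scales; the registry format is deliberately open.
#'
#' @param scale_id Identifier, e.g. `"physical_functioning"`.
#' @param instrument `"EORTC"` or `"HADS"`.
#' @param item_ids Character vector of item identifiers.
#' @param response_min,response_max Integer response coding shared by all
#'   items of the scale. EORTC symptom/functioning items are coded 1–4 and
#'   the two global items 1–7 (the published scoring convention under which
#'   the linear transform attains exactly 0 and 100); HADS items 0–3.
#' @param polarity `"higher_is_better"` (functioning, global quality of
#'   life) or `"higher_is_worse"` (symptoms, HADS).
#' @param transform One of `"eortc_functioning"`, `"eortc_symptom"`,
#'   `"eortc_global"`, `"hads_sum"`.
#'
#' @return A one-row tibble with an `items` list-column.
#' @export
#' @examples
#' scale_definition("pain", "EORTC", c("c30_q09", "c30_q19"),
#'   1, 4, "higher_is_worse", "eortc_symptom")
scale_definition <- function(scale_id, instrument, item_ids,
                             response_min, response_max,
                             polarity, transform) {
  instrument <- match.arg(instrument, c("EORTC", "HADS"))
  polarity <- match.arg(polarity, c("higher_is_better", "higher_is_worse"))
  transform <- match.arg(
    transform,
    c("eortc_functioning", "eortc_symptom", "eortc_global", "hads_sum")
  )
  if (!(response_min < response_max)) {
    stop_config("`response_min` must be strictly below `response_max`.")
  }
  score_range <- if (transform == "hads_sum") c(0, 21) else c(0, 100)
  tibble(
    scale_id = scale_id,
    instrument = instrument,
    polarity = polarity,
    transform = transform,
    score_min = score_range[1],
    score_max = score_range[2],
    items = list(tibble(
      item_id = item_ids,
      response_min = as.integer(response_min),
      response_max = as.integer(response_max)
    ))
  )
}

#' Scales shipped with the package
#'
#' The scale registry covering the feedback topics: five EORTC QLQ-C30
#' scales (physical, emotional, cognitive and social functioning, global
#' health status/QoL), the fatigue symptom scale, a single added item on
#' tingling in hands or feet (a prevalent symptom among patients with
#' lymphoma, scored like any EORTC symptom item), and the two 7-item HADS
#' subscales for anxiety and depressive symptoms.
#'
#' EORTC items use the published 1–4 coding (1–7 for the two global items);
#' questionnaires rendered with 0-anchored verbal labels should be recoded
#' before scoring, or the registry edited to carry the alternative coding.
#' HADS items are coded 0–3 and subscales are scored by summation to 0–21.
#'
#' @return A tibble with one row per scale; see [scale_definition()].
#' @export
#' @examples
#' default_scales()
default_scales <- function() {
  bind_rows(
    scale_definition("physical_functioning", "EORTC",
      paste0("c30_q0", 1:5), 1, 4, "higher_is_better", "eortc_functioning"),
    scale_definition("emotional_functioning", "EORTC",
      paste0("c30_q", 21:24), 1, 4, "higher_is_better", "eortc_functioning"),
    scale_definition("cognitive_functioning", "EORTC",
      c("c30_q20", "c30_q25"), 1, 4, "higher_is_better", "eortc_functioning"),
    scale_definition("social_functioning", "EORTC",
      c("c30_q26", "c30_q27"), 1, 4, "higher_is_better", "eortc_functioning"),
    scale_definition("global_qol", "EORTC",
      c("c30_q29", "c30_q30"), 1, 7, "higher_is_better", "eortc_global"),
    scale_definition("fatigue", "EORTC",
      c("c30_q10", "c30_q12", "c30_q18"), 1, 4, "higher_is_worse",
      "eortc_symptom"),
    scale_definition("tingling", "EORTC",
      "lym_tingling", 1, 4, "higher_is_worse", "eortc_symptom"),
    scale_definition("hads_anxiety", "HADS",
      sprintf("hads_q%02d", seq(1, 13, 2)), 0, 3, "higher_is_worse",
      "hads_sum"),
    scale_definition("hads_depression", "HADS",
      sprintf("hads_q%02d", seq(2, 14, 2)), 0, 3, "higher_is_worse",
      "hads_sum")
  )
}

#' Validate a scale registry
#'
#' Checks the structural invariants the rest of the package relies on:
#' item coding ranges are proper intervals, functioning/global scales are
#' `higher_is_better` and symptom/HADS scales `higher_is_worse`, HADS
#' subscales have exactly 7 items, and no item id belongs to two scales.
#'
#' @param scales A scale registry tibble.
#' @return `scales`, invisibly, if valid; otherwise an error.
#' @export
validate_scales <- function(scales) {
  required <- c("scale_id", "instrument", "polarity", "transform",
                "score_min", "score_max", "items")
  missing_cols <- setdiff(required, names(scales))
  if (length(missing_cols)) {
    stop_config(paste0("Scale registry lacks column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(scales$scale_id)) {
    stop_config("Duplicate scale_id in registry.")
  }
  for (i in seq_len(nrow(scales))) {
    it <- scales$items[[i]]
    id <- scales$scale_id[i]
    if (any(it$response_min >= it$response_max)) {
      stop_config(paste0("Scale ", id, ": response_min must be < response_max."))
    }
    if (length(unique(it$response_min)) != 1 ||
        length(unique(it$response_max)) != 1) {
      stop_config(paste0("Scale ", id, ": items must share one response coding."))
    }
    if (scales$transform[i] %in% c("eortc_functioning") &&
        scales$polarity[i] != "higher_is_better") {
      stop_config(paste0("Scale ", id, ": functioning scales are higher_is_better."))
    }
    if (scales$transform[i] == "eortc_symptom" &&
        scales$polarity[i] != "higher_is_worse") {
      stop_config(paste0("Scale ", id, ": symptom scales are higher_is_worse."))
    }
    if (scales$transform[i] == "hads_sum") {
      if (nrow(it) != 7) {
        stop_config(paste0("Scale ", id, ": HADS subscales have exactly 7 items."))
      }
      if (scales$polarity[i] != "higher_is_worse") {
        stop_config(paste0("Scale ", id, ": HADS subscales are higher_is_worse."))
      }
    }
  }
  all_items <- unlist(lapply(scales$items, function(x) x$item_id))
  if (anyDuplicated(all_items)) {
    stop_config(paste0("Item id assigned to more than one scale: ",
                       paste(unique(all_items[duplicated(all_items)]),
                             collapse = ", ")))
  }
  invisible(scales)
}

# Long item registry: one row per item with its scale's metadata attached.
item_registry <- function(scales) {
  scales %>%
    select("scale_id", "instrument", "polarity", "transform",
           "score_min", "score_max", "items") %>%
    tidyr::unnest("items")
}

scale_row <- function(scales, scale_id) {
  row <- scales[scales$scale_id == scale_id, ]
  if (nrow(row) != 1) {
    stop_config(paste0("Unknown scale_id: ", scale_id))
  }
  row
}
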