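# Clinically-relevant-difference thresholds: the amber band half-width d
# (minimal medium clinically relevant difference) used for traffic-light
# boundaries, and size-class bounds for labelling mean differences.

#' Default clinically-relevant-difference thresholds (demonstration)
#'
#' Per-scale size-class lower bounds for labelling an absolute mean
#' difference as trivial / small / medium / large (below the first bound:
#' no clinically relevant difference), plus `d_medium`, the minimal
#' *medium* clinically relevant difference that sets the half-width of the
#' amber band in traffic-light classification.
#'
#' The original system took these values from evidence-based
#' interpretation guidelines for the EORTC QLQ-C30, which publish
#' per-scale (not universal) thresholds; the exact numbers are not
#' reprinted here. The defaults below are demonstration values chosen to
#' be consistent with the published interpretation guidance and are fully
#' editable — supply your own table (or [read_thresholds()] a YAML file)
#' for production use.
#'
#' @return A tibble: `scale_id`, `d_medium`, `b_trivial`, `b_small`,
#'   `b_medium`, `b_large` (lower bounds of each size class, score units).
#' @export
#' @examples
#' default_thresholds()
default_thresholds <- function() {
  tribble(
    ~scale_id,               ~b_trivial, ~b_small, ~b_medium, ~b_large,
    "physical_functioning",  4,   5,   14,  22,
    "emotional_functioning", 3,   7,   15,  24,
    "cognitive_functioning", 3,   6,   9,   17,
    "social_functioning",    3,   5,   11,  18,
    "global_qol",            2,   4,   10,  15,
    "fatigue",               5,   6,   14,  23,
    "tingling",              2,   5,   10,  15,
    "hads_anxiety",          1,   1.5, 2.5, 4,
    "hads_depression",       1,   1.5, 2.5, 4
  ) %>%
    mutate(d_medium = .data$b_medium, .after = "scale_id")
}

#' Validate a threshold table
#'
#' @param thresholds Tibble as returned by [default_thresholds()].
#' @return `thresholds`, invisibly.
#' @export
validate_thresholds <- function(thresholds) {
  required <- c("scale_id", "d_medium",
                "b_trivial", "b_small", "b_medium", "b_large")
  missing_cols <- setdiff(required, names(thresholds))
  if (length(missing_cols)) {
    stop_parse(paste0("Threshold table lacks column(s): ",
                      paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(thresholds$scale_id)) {
    stop_parse("Duplicate scale_id in threshold table.")
  }
  if (any(thresholds$d_medium <= 0)) {
    stop_parse("d_medium must be positive.")
  }
  bounds <- as.matrix(thresholds[, c("b_trivial", "b_small",
                                     "b_medium", "b_large")])
  if (any(apply(bounds, 1, function(x) is.unsorted(x, strictly = TRUE)))) {
    stop_parse("Size-class bounds must be strictly increasing per scale.")
  }
  invisible(thresholds)
}

#' Amber-band half-width for a scale
#'
#' @param scale_id Scale identifier.
#' @param thresholds Threshold table.
#' @return The scale's `d_medium` (score units).
#' @export
d_for_scale <- function(scale_id, thresholds = default_thresholds()) {
  row <- thresholds[thresholds$scale_id == scale_id, ]
  if (nrow(row) != 1) {
    stop_config(paste0("No clinically-relevant-difference threshold configured for scale ",
                       scale_id, "."))
  }
  row$d_medium
}

#' Label the clinical relevance of a mean difference
#'
#' Maps the absolute value of a score difference through the scale's
#' ordered size-class bounds to one of `"no"`, `"trivial"`, `"small"`,
#' `"medium"`, `"large"`. Symmetric in the sign of the difference.
#'
#' @param difference Numeric vector of differences (score units).
#' @param scale_id Scale id (length 1 or same length as `difference`).
#' @param thresholds Threshold table; see [default_thresholds()].
#' @return Character vector of labels.
#' @export
#' @examples
#' clinical_relevance_label(c(-12.1, 0.7), "cognitive_functioning")
clinical_relevance_label <- function(difference, scale_id,
                                     thresholds = default_thresholds()) {
  validate_thresholds(thresholds)
  if (length(scale_id) == 1) scale_id <- rep(scale_id, length(difference))
  if (length(scale_id) != length(difference)) {
    stop_config("`scale_id` must be length 1 or match `difference`.")
  }
  labels <- c("no", "trivial", "small", "medium", "large")
  vapply(seq_along(difference), function(i) {
    row <- thresholds[thresholds$scale_id == scale_id[i], ]
    if (nrow(row) != 1) {
      stop_config(paste0("No size-class bounds configured for scale ",
                         scale_id[i], "."))
    }
    if (is.na(difference[i])) return(NA_character_)
    bounds <- c(row$b_trivial, row$b_small, row$b_medium, row$b_large)
    labels[findInterval(abs(difference[i]), bounds) + 1]
  }, character(1))
}

#' Read / write threshold tables as YAML
#'
#' The on-disk format is a mapping from scale id to `d_medium` and
#' `class_bounds` (the four ascending size-class lower bounds).
#'
#' @param path File path.
#' @return `read_thresholds()`: a validated threshold tibble.
#' @export
read_thresholds <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- bind_rows(lapply(names(raw), function(sid) {
    entry <- raw[[sid]]
    cb <- as.numeric(entry$class_bounds)
    if (length(cb) != 4) {
      stop_parse(paste0("Scale ", sid, ": class_bounds must have 4 values."))
    }
    tibble(scale_id = sid,
           d_medium = as.numeric(entry$d_medium),
           b_trivial = cb[1], b_small = cb[2],
           b_medium = cb[3], b_large = cb[4])
  }))
  validate_thresholds(out)
  out
}

#' @rdname read_thresholds
#' @param thresholds Threshold tibble to serialize.
#' @export
write_thresholds <- function(thresholds, path) {
  validate_thresholds(thresholds)
  out <- lapply(seq_len(nrow(thresholds)), function(i) {
    list(d_medium = thresholds$d_medium[i],
         class_bounds = c(thresholds$b_trivial[i], thresholds$b_small[i],
                          thresholds$b_medium[i], thresholds$b_large[i]))
  })
  names(out) <- thresholds$scale_id
  yaml::write_yaml(out, path)
  invisible(path)
}
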