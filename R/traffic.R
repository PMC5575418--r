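# Traffic-light classification of a score against a comparator norm, or
# against the published HADS severity cutoffs.
#
# Rule: a score differing from the matched reference mean by less than the
# minimal medium clinically relevant difference d is "average" (amber); a
# difference of d or more is above average (green) or below average (red),
# with green/red sides determined by scale polarity. Scores exactly at
# mean +/- d take the extreme colour ("as much as or more than").

new_traffic_light <- function(color, boundaries, patient_value, comparator,
                              scale_id, polarity, score_range,
                              gp_advice = FALSE, note = NULL) {
  structure(
    list(color = color, boundaries = boundaries,
         patient_value = patient_value, comparator = comparator,
         scale_id = scale_id, polarity = polarity,
         score_range = score_range, gp_advice = gp_advice, note = note),
    class = "traffic_light"
  )
}

#' Classify a score against a reference mean
#'
#' @param score Patient's scale score.
#' @param norm_mean Reference mean for the matched (comparator, sex, age
#'   band) cell.
#' @param d Amber half-width: the minimal medium clinically relevant
#'   difference for the scale (score units, > 0).
#' @param polarity `"higher_is_better"` or `"higher_is_worse"`; decides
#'   which side of the mean is green.
#' @param score_range Numeric length-2, the scale's score range
#'   (default 0-100).
#' @param comparator,scale_id Optional metadata carried into the result.
#' @return A `traffic_light` object: `color`, `boundaries` (a tibble of
#'   `(lo, hi, color)` segments tiling the score range; an extreme segment
#'   that would fall entirely outside the range is dropped),
#'   `patient_value`, `gp_advice` (filled by [gp_advice_flag()]).
#' @export
#' @examples
#' classify_score(62, norm_mean = 74, d = 10)                 # red
#' classify_score(30, 17, 5, polarity = "higher_is_worse")    # red
classify_score <- function(score, norm_mean, d,
                           polarity = c("higher_is_better", "higher_is_worse"),
                           score_range = c(0, 100),
                           comparator = NA_character_,
                           scale_id = NA_character_) {
  polarity <- match.arg(polarity)
  if (!is.numeric(d) || length(d) != 1 || is.na(d) || d <= 0) {
    stop_domain("`d` (clinically relevant difference) must be a positive number.")
  }
  lo <- score_range[1]; hi <- score_range[2]
  if (is.na(score) || score < lo || score > hi) {
    stop_domain(paste0("Score ", score, " outside the scale range [",
                       lo, ", ", hi, "]."))
  }
  diff <- score - norm_mean
  color <- if (abs(diff) < d) {
    "amber"
  } else if ((diff >= d) == (polarity == "higher_is_better")) {
    "green"
  } else {
    "red"
  }
  below_color <- if (polarity == "higher_is_better") "red" else "green"
  above_color <- if (polarity == "higher_is_better") "green" else "red"
  amber_lo <- max(lo, norm_mean - d)
  amber_hi <- min(hi, norm_mean + d)
  segs <- tibble(
    lo = c(lo, amber_lo, amber_hi),
    hi = c(amber_lo, amber_hi, hi),
    color = c(below_color, "amber", above_color)
  )
  # extreme segments lying entirely outside the range are dropped; a
  # degenerate single-point segment is kept when the boundary coincides
  # exactly with the range edge (a score there takes the extreme colour)
  keep <- (segs$lo < segs$hi) |
    (segs$color == below_color & norm_mean - d == lo) |
    (segs$color == above_color & norm_mean + d == hi)
  segs <- segs[keep, ]
  new_traffic_light(color, segs, score,
                    comparator = comparator, scale_id = scale_id,
                    polarity = polarity, score_range = score_range)
}

#' Classify a HADS subscale score by absolute severity cutoffs
#'
#' HADS anxiety and depression scores are interpreted on absolute bands
#' regardless of comparator: 0-7 no or mild symptoms (green), 8-10
#' moderate (amber), 11 or more severe (red). Chart segment edges are
#' drawn halfway between the integer cutoffs.
#'
#' @param score Integer score in 0-21.
#' @param scale_id Metadata carried into the result.
#' @return A `traffic_light` object (comparator `NA`: absolute bands).
#' @export
#' @examples
#' classify_hads(7)$color   # "green"
#' classify_hads(11)$color  # "red"
classify_hads <- function(score, scale_id = NA_character_) {
  if (is.na(score) || score < 0 || score > 21) {
    stop_domain(paste0("HADS score must lie in [0, 21]; got ", score, "."))
  }
  color <- if (score <= 7) "green" else if (score <= 10) "amber" else "red"
  segs <- tibble(
    lo = c(0, 7.5, 10.5),
    hi = c(7.5, 10.5, 21),
    color = c("green", "amber", "red")
  )
  new_traffic_light(color, segs, score,
                    comparator = NA_character_, scale_id = scale_id,
                    polarity = "higher_is_worse", score_range = c(0, 21))
}

#' Own-score (uncoloured) chart result
#'
#' For patients who only want to see their own scores, the chart carries a
#' single neutral segment and the dotted score line, no classification.
#'
#' @param score Patient's score.
#' @param score_range Scale score range.
#' @param scale_id Metadata.
#' @return A `traffic_light` object with `color = NA`.
#' @export
own_score_result <- function(score, score_range = c(0, 100),
                             scale_id = NA_character_) {
  if (is.na(score) || score < score_range[1] || score > score_range[2]) {
    stop_domain("Score outside the scale range.")
  }
  segs <- tibble(lo = score_range[1], hi = score_range[2], color = "own")
  new_traffic_light(NA_character_, segs, score,
                    comparator = "own_only", scale_id = scale_id,
                    polarity = NA_character_, score_range = score_range)
}

#' General-practitioner advice flag
#'
#' Patients with a *symptom* score in the red part of the bar chart are
#' advised to contact their general practitioner. Under the default
#' policy the advice applies to symptom scales and HADS subscales
#' (`polarity == "higher_is_worse"`); setting `include_functioning = TRUE`
#' extends it to red functioning scores as well.
#'
#' @param result A `traffic_light` object.
#' @param scale One-row scale registry tibble for the scored scale.
#' @param policy A [gp_advice_policy()] list.
#' @return Logical flag.
#' @export
gp_advice_flag <- function(result, scale, policy = gp_advice_policy()) {
  if (is.na(result$color) || result$color != "red") return(FALSE)
  if (scale$polarity == "higher_is_worse") return(TRUE)
  isTRUE(policy$include_functioning)
}

#' @rdname gp_advice_flag
#' @param include_functioning Extend GP advice to red functioning scores.
#' @export
gp_advice_policy <- function(include_functioning = FALSE) {
  list(include_functioning = include_functioning)
}

#' Tabulate traffic-light colours
#'
#' Counts and percentages of green / amber / red, the tabulation used to
#' report how many patients score below, at, or above the reference
#' average.
#'
#' @param x A character vector of colours, a list of `traffic_light`
#'   objects, or a data frame with a `color` column.
#' @return A tibble: `color` (ordered green, amber, red), `n`, `pct`.
#' @export
#' @examples
#' color_counts(c("green", "red", "red"))
color_counts <- function(x) {
  if (is.data.frame(x)) {
    cols <- x$color
  } else if (is.list(x) && !is.null(x[[1]]) && inherits(x[[1]], "traffic_light")) {
    cols <- vapply(x, function(r) r$color, character(1))
  } else {
    cols <- as.character(x)
  }
  cols <- cols[!is.na(cols)]
  bad <- setdiff(unique(cols), c("green", "amber", "red"))
  if (length(bad)) {
    stop_domain(paste0("Unknown colour(s): ", paste(bad, collapse = ", ")))
  }
  lv <- factor(cols, levels = c("green", "amber", "red"))
  tab <- table(lv)
  tibble(
    color = factor(names(tab), levels = c("green", "amber", "red")),
    n = as.integer(tab),
    pct = if (length(cols)) 100 * as.integer(tab) / length(cols) else rep(0, 3)
  )
}

#' Classify every scored scale of a cohort against one comparator
#'
#' Pipeline convenience: joins scores with demographics, resolves each
#' patient's (sex, age band) norm cell for `comparator`, and classifies.
#' HADS subscales are classified on their absolute cutoffs. Rows whose
#' norm cell is unavailable (e.g. tingling versus the normative
#' population) or whose score is missing get `color = NA` and a `note`.
#'
#' @param scores Output of [score_responses()].
#' @param demographics Tibble with `patient_id`, `sex` (`"male"`/`"female"`),
#'   `age`.
#' @param comparator `"lymphoma_cohort"` or `"normative_population"`.
#' @param norms,thresholds,scales,scheme Configuration tables.
#' @param gp_policy A [gp_advice_policy()].
#' @return A tibble: patient_id, scale_id, comparator, value, norm_mean,
#'   d, color, gp_advice, note.
#' @export
classify_cohort <- function(scores, demographics, comparator,
                            norms = default_norms(),
                            thresholds = default_thresholds(),
                            scales = default_scales(),
                            scheme = age_bands(),
                            gp_policy = gp_advice_policy()) {
  validate_norms(norms, scales)
  validate_thresholds(thresholds)
  df <- scores %>%
    inner_join(demographics, by = "patient_id")
  rows <- purrr::pmap(
    list(df$patient_id, df$scale_id, df$value, df$sex, df$age),
    function(pid, sid, value, sex, age) {
      base <- tibble(patient_id = pid, scale_id = sid,
                     comparator = comparator, value = value,
                     norm_mean = NA_real_, d = NA_real_,
                     color = NA_character_, gp_advice = FALSE,
                     note = NA_character_)
      if (is.na(value)) {
        base$note <- "score not computable"
        return(base)
      }
      sc <- scale_row(scales, sid)
      res <- tryCatch({
        if (sc$transform == "hads_sum") {
          classify_hads(value, scale_id = sid)
        } else {
          cell <- lookup_norm(norms, comparator, sid, sex, age,
                              scheme = scheme)
          d <- d_for_scale(sid, thresholds)
          base$norm_mean <- cell$mean
          base$d <- d
          classify_score(value, cell$mean, d, polarity = sc$polarity,
                         score_range = c(sc$score_min, sc$score_max),
                         comparator = comparator, scale_id = sid)
        }
      }, prolight_norm_unavailable = function(e) NULL)
      if (is.null(res)) {
        base$note <- "comparison unavailable"
        return(base)
      }
      base$color <- res$color
      base$gp_advice <- gp_advice_flag(res, sc, gp_policy)
      base
    }
  )
  bind_rows(rows)
}

# S3 methods -----------------------------------------------------------

#' @export
print.traffic_light <- function(x, ...) {
  cat("<traffic_light>", x$scale_id,
      if (!is.na(x$comparator)) paste0("vs ", x$comparator) else "(absolute bands)",
      "\n")
  cat("  score:", format(x$patient_value), "->",
      if (is.na(x$color)) "(own score, no classification)" else x$color, "\n")
  seg <- x$boundaries
  cat("  bands:", paste(sprintf("[%s, %s] %s", format(seg$lo), format(seg$hi),
                                seg$color), collapse = "; "), "\n")
  if (isTRUE(x$gp_advice)) cat("  advice: contact general practitioner\n")
  invisible(x)
}

#' Tidy a traffic-light result
#'
#' @param x A `traffic_light` object.
#' @param ... Unused.
#' @return One-row tibble: scale_id, comparator, patient_value, color,
#'   gp_advice, n_segments.
#' @export
tidy.traffic_light <- function(x, ...) {
  tibble(
    scale_id = x$scale_id,
    comparator = x$comparator,
    patient_value = x$patient_value,
    color = x$color,
    gp_advice = x$gp_advice,
    n_segments = nrow(x$boundaries)
  )
}

#' Plot a traffic-light result as a horizontal bar chart
#'
#' A ggplot2 rendering of the feedback chart: coloured band segments and
#' a dotted vertical line at the patient's score.
#'
#' @param object A `traffic_light` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.traffic_light <- function(object, ...) {
  pal <- c(green = "#2E7D32", amber = "#F9A825", red = "#C62828",
           own = "#B0BEC5")
  seg <- object$boundaries
  ggplot2::ggplot(seg) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$lo, xmax = .data$hi,
                                    ymin = 0, ymax = 1,
                                    fill = .data$color),
                       color = "grey30", linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = object$patient_value,
                        linetype = "dotted", linewidth = 1,
                        color = "#4A148C") +
    ggplot2::scale_fill_manual(values = pal, guide = "none") +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "Score", y = NULL,
                  title = object$scale_id,
                  subtitle = if (!is.na(object$comparator))
                    paste("versus", object$comparator) else NULL) +
    ggplot2::theme_minimal()
}
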