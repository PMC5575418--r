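# Feedback reports: the opt-in -> topics -> comparators flow, narrative
# assembly, deterministic SVG bar charts, and the per-patient HTML
# document with its JSON sidecar.

#' Feedback topics and the scales behind them
#'
#' The nine topics a patient can select feedback on, mapped to scale ids.
#'
#' @return A tibble: `topic`, `scale_id`.
#' @export
feedback_topics <- function() {
  tribble(
    ~topic,        ~scale_id,
    "general_qol", "global_qol",
    "physical",    "physical_functioning",
    "emotional",   "emotional_functioning",
    "cognitive",   "cognitive_functioning",
    "social",      "social_functioning",
    "fatigue",     "fatigue",
    "tingling",    "tingling",
    "anxiety",     "hads_anxiety",
    "depressive",  "hads_depression"
  )
}

#' A patient's feedback selection
#'
#' Captures the questionnaire flow: whether the patient wants feedback at
#' all; if so, which topics (or `"all"`) and against which comparators —
#' own scores only, the lymphoma reference cohort, the normative
#' population, or both cohorts. When `wants_feedback` is `FALSE`, topics
#' and comparators are forced empty (no feedback is generated).
#' `"own_only"` excludes the cohort comparators.
#'
#' @param patient_id Patient identifier.
#' @param wants_feedback Logical.
#' @param topics Character vector of topics (see [feedback_topics()]) or
#'   `"all"`.
#' @param comparators Subset of `"own_only"`, `"lymphoma_cohort"`,
#'   `"normative_population"`.
#' @return A `feedback_selection` object.
#' @export
#' @examples
#' feedback_selection("P1", TRUE, "all", "lymphoma_cohort")
feedback_selection <- function(patient_id, wants_feedback = TRUE,
                               topics = "all",
                               comparators = c("lymphoma_cohort",
                                               "normative_population")) {
  if (!wants_feedback) {
    topics <- character(0)
    comparators <- character(0)
  } else {
    if (identical(topics, "all")) topics <- feedback_topics()$topic
    unknown <- setdiff(topics, feedback_topics()$topic)
    if (length(unknown)) {
      stop_config(paste0("Unknown feedback topic(s): ",
                         paste(unknown, collapse = ", ")))
    }
    bad <- setdiff(comparators,
                   c("own_only", "lymphoma_cohort", "normative_population"))
    if (length(bad)) {
      stop_config(paste0("Unknown comparator(s): ", paste(bad, collapse = ", ")))
    }
    if ("own_only" %in% comparators && length(comparators) > 1) {
      stop_config("`own_only` excludes the cohort comparators.")
    }
    if (!length(comparators)) {
      stop_config("A patient wanting feedback must select a comparator option.")
    }
  }
  structure(
    list(patient_id = patient_id, wants_feedback = wants_feedback,
         topics = topics, comparators = comparators),
    class = "feedback_selection"
  )
}

#' Narrative text registry
#'
#' Reads the packaged (or a user-supplied) YAML registry holding the
#' per-scale descriptions and contextual paragraphs, the per-colour
#' interpretation sentence templates, comparator display names, the HADS
#' severity sentences, the GP-advice callout and the
#' comparison-unavailable note. Localizable by supplying a translated
#' file.
#'
#' @param path YAML file; defaults to the packaged English registry.
#' @return A nested list.
#' @export
default_narratives <- function(path = system.file("extdata", "narratives.yaml",
                                                  package = "prolight")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop_config("Narrative registry file not found.")
  }
  yaml::read_yaml(path)
}

interpretation_sentence <- function(narratives, scale, comparator, result) {
  comp_label <- narratives$comparators[[comparator]]
  if (scale$transform == "hads_sum") {
    sent <- narratives$hads[[result$color]]
    return(glue::glue(sent, comparator_label = comp_label))
  }
  relation <- if (result$color == "amber") {
    "similar to"
  } else {
    favorable <- result$color == "green"
    higher_obs <- xor(!favorable, scale$polarity == "higher_is_better")
    if (higher_obs) "higher than" else "lower than"
  }
  tmpl <- narratives$sentences[[result$color]]
  glue::glue(tmpl, relation = relation, comparator_label = comp_label)
}

#' Build a patient's feedback report
#'
#' Drives the feedback flow: if the patient declined feedback the report
#' is not generated (no sections). Otherwise one section per selected
#' topic, each carrying the patient's score, one traffic-light result per
#' selected comparator (HADS topics are classified on their absolute
#' severity cutoffs), the assembled narrative (scale description,
#' per-comparator interpretation sentence keyed by colour, contextual
#' paragraph) and the GP-advice flag. A norm lookup that fails — e.g.
#' tingling versus the normative population — degrades that comparison to
#' the own-score chart plus an explanatory note rather than an error.
#'
#' @param scores [score_responses()] output for (at least) this patient.
#' @param demographics Tibble with `patient_id`, `sex`, `age`.
#' @param selection A [feedback_selection()].
#' @param norms,thresholds,scales,scheme Configuration tables.
#' @param narratives Narrative registry, see [default_narratives()].
#' @param gp_policy A [gp_advice_policy()].
#' @return A `feedback_report` object: `patient_id`, `generated`,
#'   `sections` (named by topic).
#' @export
build_report <- function(scores, demographics, selection,
                         norms = default_norms(),
                         thresholds = default_thresholds(),
                         scales = default_scales(),
                         scheme = age_bands(),
                         narratives = default_narratives(),
                         gp_policy = gp_advice_policy()) {
  stopifnot(inherits(selection, "feedback_selection"))
  if (!selection$wants_feedback) {
    return(structure(list(patient_id = selection$patient_id,
                          generated = FALSE, sections = list()),
                     class = "feedback_report"))
  }
  pid <- selection$patient_id
  dem <- demographics[demographics$patient_id == pid, ]
  if (nrow(dem) != 1) {
    stop_config(paste0("Demographics missing for patient ", pid, "."))
  }
  psc <- scores[scores$patient_id == pid, ]
  topic_map <- feedback_topics()
  own_only <- identical(selection$comparators, "own_only")

  sections <- lapply(selection$topics, function(topic) {
    sid <- topic_map$scale_id[topic_map$topic == topic]
    sc <- scale_row(scales, sid)
    srow <- psc[psc$scale_id == sid, ]
    value <- if (nrow(srow)) srow$value[1] else NA_real_
    reg <- narratives$scales[[sid]]
    section <- list(
      topic = topic, scale_id = sid, score = value,
      results = list(), notes = character(0),
      narrative = character(0), gp_advice = FALSE
    )
    if (is.na(value)) {
      section$notes <- narratives$not_computable
      section$narrative <- c(reg$description, narratives$not_computable)
      return(section)
    }
    narrative <- c(reg$description)
    if (own_only) {
      section$results <- list(own_only = own_score_result(
        value, c(sc$score_min, sc$score_max), scale_id = sid))
    } else {
      for (comp in selection$comparators) {
        res <- tryCatch({
          if (sc$transform == "hads_sum") {
            classify_hads(value, scale_id = sid)
          } else {
            cell <- lookup_norm(norms, comp, sid, dem$sex, dem$age,
                                scheme = scheme)
            classify_score(value, cell$mean, d_for_scale(sid, thresholds),
                           polarity = sc$polarity,
                           score_range = c(sc$score_min, sc$score_max),
                           comparator = comp, scale_id = sid)
          }
        }, prolight_norm_unavailable = function(e) NULL)
        if (is.null(res)) {
          section$results[[comp]] <- own_score_result(
            value, c(sc$score_min, sc$score_max), scale_id = sid)
          note <- glue::glue(narratives$unavailable,
                             comparator_label = narratives$comparators[[comp]])
          section$notes <- c(section$notes, note)
          narrative <- c(narrative, note)
        } else {
          res$gp_advice <- gp_advice_flag(res, sc, gp_policy)
          section$results[[comp]] <- res
          narrative <- c(narrative,
                         as.character(interpretation_sentence(
                           narratives, sc, comp, res)))
          if (res$gp_advice) section$gp_advice <- TRUE
        }
      }
    }
    if (!is.null(reg$context)) narrative <- c(narrative, reg$context)
    if (section$gp_advice) narrative <- c(narrative, narratives$gp_advice)
    section$narrative <- narrative
    section
  })
  names(sections) <- selection$topics
  structure(list(patient_id = pid, generated = TRUE, sections = sections),
            class = "feedback_report")
}

#' @export
print.feedback_report <- function(x, ...) {
  cat("<feedback_report> patient", x$patient_id, "\n")
  if (!x$generated) {
    cat("  not generated (patient declined feedback)\n")
    return(invisible(x))
  }
  for (s in x$sections) {
    cols <- vapply(s$results, function(r)
      if (is.na(r$color)) "own" else r$color, character(1))
    cat("  ", s$topic, ": score ", format(round(s$score, 1)),
        if (length(cols)) paste0(" [", paste(names(cols), cols, sep = ": ",
                                             collapse = ", "), "]"),
        if (s$gp_advice) " (GP advice)", "\n", sep = "")
  }
  invisible(x)
}

# Chart rendering -------------------------------------------------------

#' Chart styling configuration
#'
#' Traffic-light hex colours, the dotted patient-score line, and chart
#' geometry. The defaults follow the design patients preferred in the
#' preparatory survey: bar charts in traffic-light colours with a dotted
#' line marking "your score".
#'
#' @param width,height Canvas size in pixels.
#' @param colors Named colours for `green`, `amber`, `red`, `own`, `line`.
#' @param margin Margin around the bar, pixels.
#' @return A list.
#' @export
chart_style <- function(width = 480, height = 110,
                        colors = c(green = "#2E7D32", amber = "#F9A825",
                                   red = "#C62828", own = "#B0BEC5",
                                   line = "#4A148C"),
                        margin = 28) {
  list(width = width, height = height, colors = colors, margin = margin)
}

fmt_num <- function(x) {
  # fixed, locale-independent numeric formatting so output is byte-stable
  s <- formatC(x, format = "f", digits = 2)
  sub("\\.?0+$", "", s)
}

#' Render a traffic-light result as an SVG bar chart
#'
#' A self-contained SVG: one rectangle per band segment (in segment
#' order), a dotted vertical line at the patient's score, and axis labels
#' at the scale limits and segment edges. Output is a plain string and is
#' byte-identical for identical input.
#'
#' @param result A `traffic_light` object.
#' @param style A [chart_style()].
#' @return A character scalar containing the SVG document.
#' @export
#' @examples
#' svg <- render_chart(classify_score(62, 74, 10))
#' substr(svg, 1, 4)
render_chart <- function(result, style = chart_style()) {
  seg <- result$boundaries
  if (nrow(seg) < 1) stop_usage("Result has no band segments.")
  rng <- result$score_range
  w <- style$width; h <- style$height; m <- style$margin
  bar_top <- 22; bar_bot <- h - 34
  xmap <- function(v) m + (v - rng[1]) / (rng[2] - rng[1]) * (w - 2 * m)
  rects <- vapply(seq_len(nrow(seg)), function(i) {
    x0 <- xmap(seg$lo[i]); x1 <- xmap(seg$hi[i])
    sprintf(
      '<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="#333333" stroke-width="0.5"/>',
      fmt_num(x0), fmt_num(bar_top), fmt_num(max(x1 - x0, 0)),
      fmt_num(bar_bot - bar_top),
      style$colors[[seg$color[i]]]
    )
  }, character(1))
  edges <- sort(unique(c(rng, seg$lo, seg$hi)))
  ticks <- vapply(edges, function(v) {
    x <- xmap(v)
    sprintf(
      '<text x="%s" y="%s" font-size="10" font-family="sans-serif" text-anchor="middle" fill="#333333">%s</text>',
      fmt_num(x), fmt_num(bar_bot + 14), fmt_num(v)
    )
  }, character(1))
  px <- xmap(result$patient_value)
  line <- sprintf(
    '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="2.5" stroke-dasharray="4,3"/>',
    fmt_num(px), fmt_num(bar_top - 8), fmt_num(px), fmt_num(bar_bot + 4),
    style$colors[["line"]]
  )
  label <- sprintf(
    '<text x="%s" y="%s" font-size="11" font-family="sans-serif" text-anchor="middle" fill="%s">your score: %s</text>',
    fmt_num(px), fmt_num(bar_top - 11), style$colors[["line"]],
    fmt_num(round(result$patient_value, 1))
  )
  paste0(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
            fmt_num(w), fmt_num(h), fmt_num(w), fmt_num(h)),
    paste(rects, collapse = ""),
    paste(ticks, collapse = ""),
    line, label,
    "</svg>"
  )
}

# HTML document ---------------------------------------------------------

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a feedback report as a self-contained HTML document
#'
#' One heading per section with the charts inlined as SVG, the narrative
#' paragraphs, any comparison-unavailable notes, and a GP-advice callout
#' where a symptom score falls in the red band.
#'
#' @param report A generated `feedback_report`.
#' @param style A [chart_style()].
#' @param title Document title; defaults to a generic heading with the
#'   patient id.
#' @return A character scalar of HTML.
#' @export
render_document <- function(report, style = chart_style(), title = NULL) {
  if (!inherits(report, "feedback_report")) {
    stop_usage("`report` must be a feedback_report.")
  }
  if (!report$generated) {
    stop_usage("Report was not generated (patient declined feedback).")
  }
  if (is.null(title)) {
    title <- paste0("Your questionnaire feedback (", report$patient_id, ")")
  }
  body <- vapply(report$sections, function(s) {
    charts <- vapply(names(s$results), function(comp) {
      paste0('<figure>', render_chart(s$results[[comp]], style),
             '<figcaption>', html_escape(comp), '</figcaption></figure>')
    }, character(1))
    paras <- paste0("<p>", html_escape(s$narrative), "</p>", collapse = "")
    callout <- if (s$gp_advice) {
      '<div class="gp-advice"><strong>Advice:</strong> your score falls in the red part; please contact your general practitioner.</div>'
    } else ""
    paste0(
      "<section><h2>", html_escape(s$topic), "</h2>",
      paste(charts, collapse = ""), paras, callout, "</section>"
    )
  }, character(1))
  paste0(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\"/><title>",
    html_escape(title), "</title><style>",
    "body{font-family:sans-serif;max-width:720px;margin:2em auto;}",
    "figure{margin:0.5em 0;}figcaption{font-size:0.8em;color:#555;}",
    ".gp-advice{border:2px solid #C62828;padding:0.6em;margin:0.8em 0;}",
    "</style></head><body><h1>", html_escape(title), "</h1>",
    paste(body, collapse = ""),
    "</body></html>"
  )
}

report_sidecar <- function(report) {
  list(
    patient_id = report$patient_id,
    generated = report$generated,
    sections = lapply(unname(report$sections), function(s) {
      list(
        topic = s$topic,
        scale_id = s$scale_id,
        score = s$score,
        gp_advice = s$gp_advice,
        notes = as.list(s$notes),
        results = lapply(s$results, function(r) {
          list(
            comparator = r$comparator,
            color = r$color,
            patient_value = r$patient_value,
            boundaries = lapply(seq_len(nrow(r$boundaries)), function(i) {
              list(lo = r$boundaries$lo[i], hi = r$boundaries$hi[i],
                   color = r$boundaries$color[i])
            }),
            gp_advice = r$gp_advice
          )
        })
      )
    })
  )
}

#' Write a feedback report to disk
#'
#' Emits one SVG file per chart (`<patient>_<topic>_<comparator>.svg`), a
#' single self-contained HTML document, and a JSON sidecar with all
#' numeric content for downstream systems. Output is deterministic for a
#' fixed report and style.
#'
#' @param report A generated `feedback_report`.
#' @param dir Output directory (created if needed).
#' @param style A [chart_style()].
#' @return Invisibly, a character vector of the written file paths.
#' @export
write_report <- function(report, dir, style = chart_style()) {
  if (!inherits(report, "feedback_report")) {
    stop_usage("`report` must be a feedback_report.")
  }
  if (!report$generated) {
    stop_usage("Report was not generated (patient declined feedback).")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in report$sections) {
    for (comp in names(s$results)) {
      p <- file.path(dir, paste0(report$patient_id, "_", s$topic, "_",
                                 comp, ".svg"))
      writeLines(render_chart(s$results[[comp]], style), p, useBytes = TRUE)
      paths <- c(paths, p)
    }
  }
  html_path <- file.path(dir, paste0(report$patient_id, ".html"))
  writeLines(render_document(report, style), html_path, useBytes = TRUE)
  json_path <- file.path(dir, paste0(report$patient_id, ".json"))
  jsonlite::write_json(report_sidecar(report), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, html_path, json_path))
}
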