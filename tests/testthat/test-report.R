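# Helpers: a deterministic one-patient fixture with known scores.
report_fixture <- function(overrides = c()) {
  responses <- favorable_responses()
  responses[names(overrides)] <- overrides
  items <- items_from_responses(responses, "P1")
  scores <- score_responses(items)
  demographics <- tibble::tibble(patient_id = "P1", sex = "female", age = 57)
  list(scores = scores, demographics = demographics)
}

test_that("declining feedback means no report is generated", {
  fx <- report_fixture()
  sel <- feedback_selection("P1", wants_feedback = FALSE)
  expect_equal(sel$topics, character(0))
  expect_equal(sel$comparators, character(0))
  rep <- build_report(fx$scores, fx$demographics, sel)
  expect_false(rep$generated)
  expect_equal(length(rep$sections), 0)
  expect_error(render_document(rep), class = "prolight_usage_error")
  expect_error(write_report(rep, withr::local_tempdir()),
               class = "prolight_usage_error")
})

test_that("selecting all topics yields nine sections with 1-2 charts each", {
  fx <- report_fixture()
  sel <- feedback_selection("P1", TRUE, "all",
                            c("lymphoma_cohort", "normative_population"))
  rep <- build_report(fx$scores, fx$demographics, sel)
  expect_true(rep$generated)
  expect_equal(length(rep$sections), 9)
  n_charts <- vapply(rep$sections, function(s) length(s$results), integer(1))
  expect_true(all(n_charts %in% 1:2))
})

test_that("selection invariants are enforced", {
  expect_error(feedback_selection("P1", TRUE, "nonsense"),
               class = "prolight_config_error")
  expect_error(feedback_selection("P1", TRUE, "all",
                                  c("own_only", "lymphoma_cohort")),
               class = "prolight_config_error")
  expect_error(feedback_selection("P1", TRUE, "all", character(0)),
               class = "prolight_config_error")
})

test_that("narratives name the comparator and agree with the colour", {
  # cognitive score 80: amber versus the lymphoma cohort (|80 - 82.4| < 9)
  # and red versus the normative population (92.5 - 80 >= 9)
  fx <- report_fixture(c(c30_q20 = 2, c30_q25 = 1))  # raw mean 1.5 -> 83.3
  # want a score of 80 exactly? 2-item scale cannot hit 80; use 83.3:
  # |83.3 - 82.4| = 0.9 -> amber vs cohort; 92.5 - 83.3 = 9.2 >= 9 -> red
  sel <- feedback_selection("P1", TRUE, "cognitive",
                            c("lymphoma_cohort", "normative_population"))
  rep <- build_report(fx$scores, fx$demographics, sel)
  sec <- rep$sections$cognitive
  expect_equal(sec$results$lymphoma_cohort$color, "amber")
  expect_equal(sec$results$normative_population$color, "red")
  text <- paste(sec$narrative, collapse = " ")
  expect_match(text, "similar to that of other people with lymphoma")
  expect_match(text, "lower than the average score of people from the general population")
})

test_that("own-only selections produce a single uncoloured chart per section", {
  fx <- report_fixture()
  sel <- feedback_selection("P1", TRUE, c("general_qol", "fatigue"),
                            "own_only")
  rep <- build_report(fx$scores, fx$demographics, sel)
  for (s in rep$sections) {
    expect_equal(length(s$results), 1)
    r <- s$results$own_only
    expect_true(is.na(r$color))
    expect_equal(nrow(r$boundaries), 1)
    expect_equal(r$boundaries$color, "own")
  }
})

test_that("an unavailable norm degrades to the own-score chart with a note", {
  fx <- report_fixture(c(lym_tingling = 3))
  sel <- feedback_selection("P1", TRUE, "tingling",
                            c("lymphoma_cohort", "normative_population"))
  rep <- build_report(fx$scores, fx$demographics, sel)
  sec <- rep$sections$tingling
  expect_equal(length(sec$results), 2)
  expect_false(is.na(sec$results$lymphoma_cohort$color))
  expect_true(is.na(sec$results$normative_population$color))
  expect_match(sec$notes, "general population")
  html <- render_document(rep)
  expect_match(html, "No reference scores are available")
})

test_that("red symptom scores carry GP advice into the document", {
  fx <- report_fixture(c(c30_q10 = 4, c30_q12 = 4, c30_q18 = 4))  # fatigue 100
  sel <- feedback_selection("P1", TRUE, "fatigue", "lymphoma_cohort")
  rep <- build_report(fx$scores, fx$demographics, sel)
  expect_true(rep$sections$fatigue$gp_advice)
  html <- render_document(rep)
  expect_match(html, "general practitioner")
  expect_match(html, "gp-advice")
})

test_that("charts render segments, the dotted score line, and are byte-stable", {
  res <- classify_score(62, 74, 10, comparator = "lymphoma_cohort",
                        scale_id = "global_qol")
  svg <- render_chart(res)
  expect_equal(lengths(regmatches(svg, gregexpr("<rect", svg))), 3)
  expect_equal(lengths(regmatches(svg, gregexpr("stroke-dasharray", svg))), 1)
  expect_identical(svg, render_chart(res))
  clipped <- classify_score(95, 90.5, 14)
  expect_equal(lengths(regmatches(render_chart(clipped),
                                  gregexpr("<rect", render_chart(clipped)))), 2)
})

test_that("one-topic reports render one section heading", {
  fx <- report_fixture()
  sel <- feedback_selection("P1", TRUE, "general_qol", "lymphoma_cohort")
  rep <- build_report(fx$scores, fx$demographics, sel)
  html <- render_document(rep)
  expect_equal(lengths(regmatches(html, gregexpr("<h2>", html))), 1)
})

test_that("written reports include SVGs, HTML, and a numeric JSON sidecar", {
  fx <- report_fixture()
  sel <- feedback_selection("P1", TRUE, c("cognitive", "anxiety"),
                            c("lymphoma_cohort", "normative_population"))
  rep <- build_report(fx$scores, fx$demographics, sel)
  dir <- withr::local_tempdir()
  paths <- write_report(rep, dir)
  expect_equal(sum(grepl("\\.svg$", paths)), 4)
  expect_equal(sum(grepl("\\.html$", paths)), 1)
  expect_equal(sum(grepl("\\.json$", paths)), 1)
  side <- jsonlite::read_json(paths[grepl("\\.json$", paths)])
  expect_equal(side$patient_id, "P1")
  expect_equal(length(side$sections), 2)
  cogn <- side$sections[[1]]
  expect_equal(cogn$scale_id, "cognitive_functioning")
  expect_equal(length(cogn$results), 2)
})

test_that("interpretation direction follows polarity", {
  # red on a symptom scale reads "higher than"; red on functioning "lower"
  fx <- report_fixture(c(c30_q10 = 4, c30_q12 = 4, c30_q18 = 4,
                         c30_q01 = 4, c30_q02 = 4, c30_q03 = 4,
                         c30_q04 = 4, c30_q05 = 4))
  sel <- feedback_selection("P1", TRUE, c("fatigue", "physical"),
                            "lymphoma_cohort")
  rep <- build_report(fx$scores, fx$demographics, sel)
  fatigue_text <- paste(rep$sections$fatigue$narrative, collapse = " ")
  physical_text <- paste(rep$sections$physical$narrative, collapse = " ")
  expect_match(fatigue_text, "higher than the average score")
  expect_match(physical_text, "lower than the average score")
})
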