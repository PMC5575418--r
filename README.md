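# prolight

Traffic-light feedback on patient-reported outcomes (PROs), for
researchers and registries that return questionnaire results to the
patients who completed them.

Patients with lymphoma (and cancer survivors generally) often ask "am I
normal?" — whether their fatigue, concentration problems or worries are
shared by people like them. `prolight` implements the full pipeline of an
automatic PRO feedback system for that question:

1. **Scoring.** EORTC QLQ-C30 scales are scored from item responses with
   the standard two-step procedure — raw score *RS* = mean of answered
   items (scored when at least half are answered), then the linear
   transform *S* = (1 − (RS − 1)/r)·100 for functioning scales and
   *S* = ((RS − 1)/r)·100 for symptom and global scales, giving 0–100.
   HADS anxiety/depression subscales are summed to 0–21, prorating a
   single missing item.
2. **Norm matching.** Each score is matched to reference statistics of
   the same sex and 10–15-year age band, from two comparators: a
   lymphoma reference cohort and a general-population normative cohort.
3. **Traffic-light classification.** With per-scale threshold *d* (the
   minimal medium clinically relevant difference): |s − m| < d is amber
   (average), a difference of at least *d* is green on the favorable
   side and red on the unfavorable side. HADS uses the published
   absolute bands 0–7 / 8–10 / ≥11 instead.
4. **Reports.** Per-patient bar charts (deterministic SVG) in traffic
   colours with a dotted "your score" line, narrative text per topic and
   comparator, GP-contact advice for red symptom scores, bundled into a
   self-contained HTML document plus a JSON sidecar.
5. **Study statistics.** Fisher / Freeman–Halton exact tests (complete
   enumeration), two-sample t tests from raw data or printed summary
   statistics, ANCOVA with age and sex covariates, and
   clinical-relevance labelling of mean differences.
6. **Synthetic cohorts.** An item-level generator with calibrated scale
   means, demographics and feedback selections, so the whole pipeline is
   testable end-to-end without any patient data.

See `vignettes/pro-feedback-methods.Rmd` for the methods in detail.

## Worked example

```r
library(prolight)
library(tibble)

items <- tribble(
  ~patient_id, ~item_id,  ~response,
  "P1",        "c30_q20", 2,    # cognitive: trouble concentrating
  "P1",        "c30_q25", 1,    # cognitive: trouble remembering
  "P1",        "c30_q10", 2, "P1", "c30_q12", 2, "P1", "c30_q18", 1,
  "P1",        "hads_q01", 2, "P1", "hads_q03", 2, "P1", "hads_q05", 1,
  "P1",        "hads_q07", 1, "P1", "hads_q09", 1, "P1", "hads_q11", 1,
  "P1",        "hads_q13", 1
)
scores <- score_responses(items)
demographics <- tibble(patient_id = "P1", sex = "female", age = 57)
report <- build_report(
  scores, demographics,
  feedback_selection("P1", TRUE, c("cognitive", "fatigue", "anxiety"),
                     c("lymphoma_cohort", "normative_population"))
)
report
#> <feedback_report> patient P1
#>   cognitive: score 83.3 [lymphoma_cohort: amber, normative_population: red]
#>   fatigue: score 22.2 [lymphoma_cohort: amber, normative_population: amber]
#>   anxiety: score 9 [lymphoma_cohort: amber, normative_population: amber]
```

The cognitive score of 83.3 sits within *d* = 9 points of the lymphoma
reference mean (82.4) — amber, "similar to that of other people with
lymphoma with your age and sex" — but more than 9 points below the
general-population mean (92.5) — red, "lower than the average score of
people from the general population". The HADS anxiety score of 9 falls
in the absolute moderate band (8–10), amber. `write_report(report, dir)`
then emits the SVG charts, the HTML document and a JSON sidecar.

Cohort-level tabulation and the accompanying statistics:

```r
sim <- simulate_cohort(cohort_spec(n = 200, seed = 1))
scored <- score_responses(sim$items)
classified <- classify_cohort(scored, sim$demographics, "lymphoma_cohort")
color_counts(dplyr::filter(classified, scale_id == "global_qol"))

fisher_exact(matrix(c(8, 1, 37, 18), 2, byrow = TRUE))
#>   method       statistic p_value    df n_tables
#> 1 fisher_exact        NA   0.260    NA       NA

t_test_summary(60.7, 13.6, 45, 63.8, 14.7, 19)   # from printed summaries
```

The packaged `default_norms()` and `default_thresholds()` are
demonstration fixtures (pooled published statistics replicated across
strata; editable threshold defaults) — production use requires your own
stratified norm table and guideline thresholds, supplied as CSV/YAML.

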