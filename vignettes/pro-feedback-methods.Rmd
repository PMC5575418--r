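---
title: "Methods: norm-referenced traffic-light feedback on patient-reported outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: norm-referenced traffic-light feedback on patient-reported outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prolight)
```

## The problem

Patients completing health-related quality-of-life (HRQoL) questionnaires
often want to know whether what they experience is "normal". prolight
implements an automatic feedback pipeline for that question, developed in
the context of lymphoma survivorship research: a patient's EORTC QLQ-C30
and HADS scale scores are compared with reference statistics from two
cohorts — other patients with lymphoma, and a general population without
cancer, both matched on sex and age band — and each comparison is shown
as a bar chart in traffic-light colours with a dotted line marking the
patient's own score, plus a narrative interpretation.

## Scoring model

**EORTC QLQ-C30.** Each scale is a small set of items coded 1–4 (the two
global health items 1–7). With raw score $RS$ = mean of the answered
items and item range $r$:

* functioning scales (higher is better):
  $S = \left(1 - \frac{RS - 1}{r}\right)\cdot 100$
* symptom scales and the global scale:
  $S = \frac{RS - 1}{r}\cdot 100$

so every transformed score lies in $[0, 100]$ and the favorable extreme
of a functioning scale maps to exactly 100. A scale is scored when at
least half of its items are answered (the "half rule", configurable via
`min_prop_answered`); the answered-item mean then stands in for the
missing items.

Questionnaire renderings sometimes label the four answer categories 0–3
("not at all" … "very much"). The registry stores explicit
`response_min`/`response_max` per item, so either coding can be
configured; the shipped default is the 1-based coding under which the
transform above attains the documented 0–100 range. Data collected with
0-based coding should be shifted or the registry edited — mixing the two
silently shifts every score by a third of the range, which is why
`score_responses()` validates every response against the registry coding.

**HADS.** Anxiety and depression are separate 7-item subscales, items
coded 0–3, scored by summation to 0–21 (higher = more symptoms). With
exactly one missing item the sum is prorated ($\text{sum}\times 7/6$,
i.e. the answered mean times 7); with more than one missing the score is
missing. Both rules are the instruments' standard conventions — the
feedback system itself does not redefine them — and both are exposed as
parameters.

Transformed values are kept at full floating precision; rounding to one
decimal happens only in rendered output.

## Reference norms and matching

Reference statistics are organised as one cell per (comparator, scale,
sex, age band): mean, SD, n. Age bands span 10–15 years from 18–30 up to
an open-ended band above 75; the default edges are 18–30, 31–45, 46–60,
61–75, >75. The published description of the original system fixes only
the first and last band, so the middle edges are configurable
(`age_bands()`). Band upper bounds are inclusive, and a fractional age
falling between two integer bands resolves downward (a cell for ages
46–60 covers $[46, 61)$).

The packaged `default_norms()` table is a *demonstration fixture*: the
published pooled means/SDs per scale for each comparator, replicated
across bands with sex `"pooled"` (sex-specific lookups fall back to the
pooled cell). The stratified cells used by the original system are
unpublished; production deployments supply their own stratified CSV via
`read_norms()`. Lookups that cannot be resolved raise a typed
`prolight_norm_unavailable` condition carrying the failed key — never a
silent default. With the packaged table that is the defined behaviour
for tingling versus the general population, for which no normative
statistics exist; a feedback report degrades that comparison to an
own-score chart with an explanatory note.

## Traffic-light classification

For a score $s$, matched reference mean $m$ and a per-scale threshold
$d$ (the minimal *medium* clinically relevant difference):

* $|s - m| < d$: **amber** — average;
* a difference of at least $d$ in the favorable direction (higher on
  functioning scales, lower on symptom scales): **green**;
* at least $d$ in the unfavorable direction: **red**.

Scores exactly at $m \pm d$ take the extreme colour ("as much as or
more than"), so the amber band is open at both ends. Chart bands are the
three intervals clipped to the score range; an extreme band lying
entirely outside the range is dropped (a boundary exactly at the range
edge keeps a degenerate band so the edge score still displays its
colour). HADS subscales are instead classified on the published absolute
severity cutoffs — 0–7 green, 8–10 amber, ≥11 red — regardless of the
selected comparator; segment edges for charting sit halfway between the
integer cutoffs. Patients whose *symptom* score (including HADS) falls
in the red band are advised to contact their general practitioner; a
configuration switch (`gp_advice_policy(include_functioning = TRUE)`)
extends the advice to functioning scales.

The per-scale $d$ values come from the published evidence-based
interpretation guidelines for the EORTC QLQ-C30, which give per-scale
(not universal) thresholds; the exact numbers used by the original
system are not reprinted anywhere we can cite as data. The shipped
`default_thresholds()` are therefore demonstration values: they were
chosen to be consistent with the size-class labels published alongside
the packaged reference statistics (every published mean difference maps
to its published label under these bounds) and with the spirit of the
guidelines, and they are fully editable via YAML. For HADS, small
absolute bounds are provided for difference labelling only.

## Feedback flow

The report generator mirrors the survey flow: patients are first asked
whether they want feedback at all (no means no report is generated — the
object carries `generated = FALSE` and zero sections); then which of
nine topics (or all); then whether to see their own scores only, or a
comparison against the lymphoma cohort, the general population, or both.
Each section carries one chart per selected comparator (one or two), an
interpretation sentence that is a pure function of (scale, comparator,
colour), a scale description, and a contextual paragraph. "Yellow" and
"amber" are one category with one registry token. Narrative strings live
in a YAML registry and are localizable.

Charts are emitted as hand-built SVG with fixed number formatting, so a
given result renders byte-identically — reports are golden-file
testable, and the whole simulate → score → report path is deterministic
under a fixed seed. `autoplot()` methods provide ggplot2 renderings for
interactive work.

## Study statistics

The toolkit around such feedback studies is included:

* `fisher_exact()` — two-sided Fisher exact test; for r×c tables the
  Freeman–Halton generalisation by complete enumeration of
  margin-constrained tables in log-probability space. Two-sidedness is
  the probability-mass ordering: the p value sums the probabilities of
  all tables no more probable than the observed one. Probability
  comparisons use a relative tolerance of $10^{-7}$ so genuinely tied
  tables (which arise whenever two row margins coincide) are never
  excluded by floating-point noise. Note that software which effectively
  excludes such ties reports a p value smaller by the tied table's mass
  — a discrepancy of one unit in the second decimal is possible on small
  tables. A configurable enumeration cap guards runtime; exceeding it is
  a typed resource error suggesting Monte-Carlo approximation.
* `t_test_summary()` / `t_test_groups()` — two-sided two-sample t test
  from summary statistics (the form needed for printed tables) or raw
  data; the raw-data entry point computes group summaries and delegates
  to the summary form, so the two agree exactly. Pooled (Student) is the
  default, Welch by flag. Two zero-variance groups with equal means
  return $t = 0, p = 1$ by convention.
* `ancova_group_effect()` — least squares of score on a two-level group
  indicator, age in years (untransformed) and sex as a 0/1 indicator;
  the group coefficient is the adjusted mean difference, with adjusted
  means evaluated at the overall covariate means. Singular designs are a
  typed error naming the collinear term.
* `clinical_relevance_label()` — maps $|\Delta|$ through per-scale
  ordered bounds to no / trivial / small / medium / large.

## Synthetic cohorts

`simulate_cohort()` generates item-level data with known structure so
the full pipeline is testable without patient data. Per patient: sex
and a truncated-normal age from the spec; per scale a latent score from
a normal truncated to the score range; item responses constructed so the
scored value is the *nearest achievable* score to the latent (the raw
item sum is rounded to the nearest integer; which items absorb the units
is randomised uniformly). Scoring the generated items therefore
reproduces the latent to within half the scale's minimal score step.

Two biases would otherwise pull the realised mean away from the target:
truncation at the scale limits (a target of 82.4 with SD 23 on a 0–100
scale loses about a fifth of its upper tail, shifting a naive truncated
mean by roughly nine points) and nearest-grid rounding on coarse scales
(a single 1–4 item has a 33.3-point step). The generator solves for the
latent location whose expected *scored* value equals the target, so
realised cohort means are unbiased for any target/SD; the realised SD
near a boundary is necessarily somewhat smaller than nominal, which is
also what bounded real-world scores exhibit.

Defaults emulate the study conditions this system was evaluated under:
58% male; age ~ N(60.7, 13.6) truncated to [18, 95]; per-scale targets
equal to the published patient means/SDs; 80% opt-in; per-topic uptake
probabilities from the published uptake table; comparator-set
probabilities own-only 2/36, lymphoma-only 11/36, both 23/36. Opt-in,
topic and comparator choices are drawn independently. A single root
seed derives one sub-seed per stream (demographics, scores,
missingness, selections), so e.g. changing the opt-in model leaves the
simulated questionnaires bit-identical.

What the generator does **not** emulate: correlations between scales
within a patient (latents are independent), item-level response styles
or local dependence, coupling between clinical covariates and outcomes
(treatment/stage exist only as labels, and `simulate_norm_microdata()`
covers covariate-coupled scores for ANCOVA testing), and informative
missingness (missingness is uniform at a configurable rate). Tests
passing on these cohorts therefore validate the scoring/classification/
reporting machinery and the statistical calibration of the tools — not
the psychometrics of real questionnaire data.

## Numerical choices and problem sizes

* Boundary scores at $m \pm d$ classify to the extreme colour; ties in
  exact-test probabilities are included (both directions of these
  conventions are stated above).
* Truncated-normal draws use inverse-CDF sampling; location calibration
  uses `uniroot` at tolerance $10^{-9}$.
* The test suite exercises the generator at n = 5000 for mean-recovery
  checks (three standard errors), 200 replicates for ANCOVA null
  calibration, and 1200–1500 margin-fixed simulated tables for exact-test
  validity — sizes chosen to keep Monte-Carlo error well below the
  tolerances being asserted while running in about a minute.
* CSV is comma-separated UTF-8 with a decimal point; empty cell =
  missing. JSON sidecars are written with full numeric precision.

## Known limitations

* The packaged norm table replicates pooled statistics across strata; it
  demonstrates the mechanics but must not be used for real feedback.
* The shipped clinically-relevant-difference values are demonstration
  defaults (see above), not the guideline tables themselves.
* Longitudinal within-patient change (tracking scores over time) is out
  of scope, as is serving the reports over the web; the package stops at
  deterministic HTML/SVG/JSON artifacts.
* HADS charts show only the absolute severity bands; whether a
  norm-based banding should be overlaid for HADS is left to the
  configuration layer (the absolute interpretation is the published
  one).
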