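# Reference norms: age bands, the packaged demonstration norm table, and
# the lookup that resolves a patient to the matching reference cell.

#' Age band scheme for norm matching
#'
#' Reference statistics are stratified by sex and by age bands of 10-15
#' years, from 18-30 up to an open-ended band above 75. The default edges
#' are 18-30, 31-45, 46-60, 61-75, >75; the middle edges are configurable
#' because different reference tables stratify differently.
#'
#' @param lower Integer vector of band lower edges (years); the first must
#'   be 18 and each subsequent edge starts the next band. The last band is
#'   open-ended.
#' @return A tibble: `band` (index), `label`, `age_lo`, `age_hi`
#'   (`Inf` for the last band).
#' @export
#' @examples
#' age_bands()
age_bands <- function(lower = c(18, 31, 46, 61, 76)) {
  lower <- as.numeric(lower)
  if (length(lower) < 2 || lower[1] != 18 || is.unsorted(lower, strictly = TRUE)) {
    stop_config("Age band lower edges must start at 18 and increase strictly.")
  }
  hi <- c(lower[-1] - 1, Inf)
  span <- hi - lower + 1
  closed <- span[is.finite(span)]
  if (any(closed < 10 | closed > 15)) {
    stop_config("Each closed age band must span 10-15 years.")
  }
  tibble(
    band = seq_along(lower),
    label = ifelse(is.finite(hi),
                   paste0(lower, "-", hi),
                   paste0(">", lower - 1)),
    age_lo = lower,
    age_hi = hi
  )
}

#' Assign ages to bands
#'
#' Returns the band index containing each age; band upper bounds are
#' inclusive (age 30 falls in 18-30), and fractional ages between two
#' integer bands resolve downward (age 30.5 also falls in 18-30).
#'
#' @param age Numeric vector of ages in years; all must be >= 18.
#' @param scheme An [age_bands()] tibble.
#' @return Integer vector of band indices.
#' @export
#' @examples
#' assign_age_band(c(22, 30, 31, 84))
assign_age_band <- function(age, scheme = age_bands()) {
  if (any(is.na(age))) stop_domain("Missing age cannot be matched to a band.")
  if (any(age < scheme$age_lo[1])) {
    stop_domain(paste0("Age below the lowest band (", scheme$age_lo[1],
                       "): ", min(age), "."))
  }
  findInterval(age, scheme$age_lo)
}

#' Published reference summary statistics (demonstration fixture)
#'
#' Pooled mean (SD) scale scores from a published Dutch population-based
#' lymphoma HRQoL study: the surveyed patients (n = 45), a lymphoma
#' reference cohort (n = 876), and an age- and sex-matched normative
#' population without cancer (n = 1852). Tingling in hands or feet has no
#' normative-population entry (`NA`). These pooled values seed the
#' packaged demonstration norm table; the original system used sex- and
#' age-stratified cells, which are not published.
#'
#' @return A tibble: `cohort`, `scale_id`, `mean`, `sd`, `n`.
#' @export
reference_stats <- function() {
  tribble(
    ~scale_id,               ~patients_mean, ~patients_sd, ~lymph_mean, ~lymph_sd, ~norm_mean, ~norm_sd,
    "physical_functioning",  83.1, 20,   79.4, 21,   90.5, 15,
    "emotional_functioning", 82.2, 21,   82.8, 21,   87.9, 17,
    "cognitive_functioning", 80.4, 22,   82.4, 23,   92.5, 14,
    "social_functioning",    85.9, 25,   84.4, 24,   93.6, 16,
    "global_qol",            73.3, 20,   74.0, 20,   77.6, 17,
    "fatigue",               24.7, 23,   28.9, 27,   17.0, 20,
    "tingling",              18.5, 28,   17.0, 29,   NA,   NA,
    "hads_anxiety",          4.0,  3.8,  4.4,  3.8,  3.6,  3.2,
    "hads_depression",       3.9,  3.8,  4.7,  3.8,  3.6,  3.2
  ) %>%
    tidyr::pivot_longer(-"scale_id",
                        names_to = c("cohort", ".value"),
                        names_sep = "_") %>%
    mutate(
      cohort = recode(.data$cohort,
                      patients = "patients",
                      lymph = "lymphoma_cohort",
                      norm = "normative_population"),
      n = case_when(
        .data$cohort == "patients" ~ 45L,
        .data$cohort == "lymphoma_cohort" ~ 876L,
        TRUE ~ 1852L
      )
    ) %>%
    filter(!is.na(.data$mean)) %>%
    select("cohort", "scale_id", "mean", "sd", "n")
}

#' Packaged demonstration norm table
#'
#' Builds a norm table from [reference_stats()]: the pooled mean/SD of
#' each scale for each comparator, replicated across all age bands with
#' sex `"pooled"` (sex-specific lookups fall back to the pooled cell). It
#' is a demonstration fixture — real deployments supply sex- and
#' age-stratified tables via [read_norms()]. Tingling has no
#' normative-population cell, so that lookup raises the typed
#' "norm unavailable" error by design.
#'
#' @param scheme An [age_bands()] scheme.
#' @return A norm tibble: `comparator`, `scale_id`, `sex`, `age_lo`,
#'   `age_hi`, `mean`, `sd`, `n`.
#' @export
#' @examples
#' default_norms()
default_norms <- function(scheme = age_bands()) {
  stats <- reference_stats() %>%
    filter(.data$cohort != "patients") %>%
    rename(comparator = "cohort")
  tidyr::expand_grid(stats, band = scheme$band) %>%
    left_join(scheme, by = "band") %>%
    transmute(
      comparator = .data$comparator,
      scale_id = .data$scale_id,
      sex = "pooled",
      age_lo = .data$age_lo,
      age_hi = .data$age_hi,
      mean = .data$mean,
      sd = .data$sd,
      n = .data$n
    ) %>%
    arrange(.data$comparator, .data$scale_id, .data$age_lo)
}

#' Validate a norm table
#'
#' Enforces the norm-table invariants: recognised comparators and sexes,
#' non-negative SD, n >= 1, at most one cell per
#' (comparator, scale, sex, age band) key, and — when the scale registry
#' is supplied — means inside the scale's score range.
#'
#' @param norms A norm tibble (see [default_norms()] for the columns).
#' @param scales Optional scale registry used to range-check means.
#' @return `norms`, invisibly.
#' @export
validate_norms <- function(norms, scales = NULL) {
  required <- c("comparator", "scale_id", "sex", "age_lo", "age_hi",
                "mean", "sd", "n")
  missing_cols <- setdiff(required, names(norms))
  if (length(missing_cols)) {
    stop_parse(paste0("Norm table lacks column(s): ",
                      paste(missing_cols, collapse = ", ")))
  }
  bad_comp <- setdiff(unique(norms$comparator),
                      c("lymphoma_cohort", "normative_population"))
  if (length(bad_comp)) {
    stop_parse(paste0("Unknown comparator(s): ",
                      paste(bad_comp, collapse = ", ")))
  }
  bad_sex <- setdiff(unique(norms$sex), c("male", "female", "pooled"))
  if (length(bad_sex)) {
    stop_parse(paste0("Unknown sex value(s): ", paste(bad_sex, collapse = ", ")))
  }
  if (any(norms$sd < 0, na.rm = TRUE)) stop_parse("Negative SD in norm table.")
  if (any(norms$n < 1, na.rm = TRUE)) stop_parse("Norm cell with n < 1.")
  dup <- norms %>%
    count(.data$comparator, .data$scale_id, .data$sex, .data$age_lo) %>%
    filter(.data$n > 1)
  if (nrow(dup)) {
    stop_parse(paste0(
      "Duplicate norm cell for key (", dup$comparator[1], ", ",
      dup$scale_id[1], ", ", dup$sex[1], ", age_lo ", dup$age_lo[1], ")."
    ))
  }
  if (!is.null(scales)) {
    rng <- scales %>% select("scale_id", "score_min", "score_max")
    chk <- norms %>% inner_join(rng, by = "scale_id")
    bad <- chk %>% filter(.data$mean < .data$score_min |
                            .data$mean > .data$score_max)
    if (nrow(bad)) {
      stop_parse(paste0("Norm mean outside score range for scale ",
                        bad$scale_id[1], ": ", bad$mean[1], "."))
    }
  }
  invisible(norms)
}

#' Look up the reference cell matching a patient
#'
#' Resolves (comparator, scale, sex, age band) to a single norm cell. If
#' no sex-specific cell exists and `fallback_pooled` is `TRUE`, the
#' `"pooled"` cell for the same key is used. When nothing matches, a typed
#' condition of class `prolight_norm_unavailable` is signalled carrying
#' the failed key — never a silent default. (With the packaged table this
#' is the defined behaviour for tingling versus the normative population.)
#'
#' @param norms Norm table.
#' @param comparator `"lymphoma_cohort"` or `"normative_population"`.
#' @param scale_id Scale identifier.
#' @param sex `"male"`, `"female"` or `"pooled"`.
#' @param age Age in years (>= 18).
#' @param scheme Age band scheme the table is resolved against.
#' @param fallback_pooled Fall back to the pooled-sex cell; default `TRUE`.
#' @return A one-row tibble (the matching cell, plus `band`).
#' @export
#' @examples
#' lookup_norm(default_norms(), "lymphoma_cohort", "cognitive_functioning",
#'             "female", 57)
lookup_norm <- function(norms, comparator, scale_id, sex, age,
                        scheme = age_bands(), fallback_pooled = TRUE) {
  comparator <- match.arg(comparator,
                          c("lymphoma_cohort", "normative_population"))
  sex <- match.arg(sex, c("male", "female", "pooled"))
  band <- assign_age_band(age, scheme)
  lo <- scheme$age_lo[band]
  # a finite band of integer ages lo-hi covers fractional ages [lo, hi + 1)
  pick <- function(s) {
    norms %>%
      filter(.data$comparator == .env$comparator,
             .data$scale_id == .env$scale_id,
             .data$sex == s,
             .data$age_lo <= .env$age,
             is.infinite(.data$age_hi) | .env$age < .data$age_hi + 1)
  }
  hit <- pick(sex)
  if (!nrow(hit) && fallback_pooled && sex != "pooled") hit <- pick("pooled")
  if (!nrow(hit)) {
    key <- list(comparator = comparator, scale_id = scale_id, sex = sex,
                age = age, band = band)
    stop_norm_unavailable(paste0(
      "No reference norm available for (", comparator, ", ", scale_id,
      ", ", sex, ", age band starting ", lo, ")."
    ), key = key)
  }
  if (nrow(hit) > 1) {
    stop_parse(paste0("Norm table resolves ", nrow(hit),
                      " cells for one key; validate_norms() it."))
  }
  hit %>% mutate(band = band)
}
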