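# Synthetic cohorts: item-level patients with controlled scale-score
# distributions, demographics, and feedback selections, plus subject-level
# microdata for ANCOVA structure tests. Everything is reproducible from a
# single root seed with per-stream derived seeds.

#' Specify a synthetic cohort
#'
#' Defaults reproduce the composition of the surveyed lymphoma cohort:
#' 58% male, age ~ normal(60.7, 13.6) truncated to \[18, 95\], per-scale
#' score targets equal to the published patient means/SDs, an 80% opt-in
#' probability for feedback, per-topic selection probabilities matching
#' the published uptake table, and comparator-set probabilities from the
#' observed counts (own scores only 2/36, lymphoma cohort only 11/36,
#' both comparators 23/36).
#'
#' @param n Number of patients.
#' @param sex_ratio Fraction male.
#' @param age_mean,age_sd,age_min,age_max Truncated-normal age
#'   distribution (years).
#' @param scale_targets Tibble `scale_id`, `mean`, `sd`: target score
#'   distribution per scale (score units, truncated to the scale range).
#' @param optin_probability Probability a patient wants feedback.
#' @param topic_probabilities Named vector of per-topic selection
#'   probabilities (see [feedback_topics()] for the topic ids).
#' @param comparator_probabilities Named vector over
#'   `own_only`, `lymphoma_only`, `normative_only`, `both`; normalised
#'   internally.
#' @param missing_rate Per-item probability of a missing response
#'   (default 0).
#' @param seed Root seed (integer) for full reproducibility; `NULL` uses
#'   the current RNG state.
#' @return A `cohort_spec` list.
#' @export
#' @examples
#' cohort_spec(n = 10, seed = 1)
cohort_spec <- function(n,
                        sex_ratio = 0.58,
                        age_mean = 60.7, age_sd = 13.6,
                        age_min = 18, age_max = 95,
                        scale_targets = default_scale_targets(),
                        optin_probability = 0.80,
                        topic_probabilities = default_topic_probabilities(),
                        comparator_probabilities = default_comparator_probabilities(),
                        missing_rate = 0,
                        seed = NULL) {
  if (n < 0 || n != round(n)) stop_domain("`n` must be a non-negative integer.")
  probs <- c(optin_probability, topic_probabilities,
             comparator_probabilities, missing_rate, sex_ratio)
  if (any(probs < 0 | probs > 1)) {
    stop_domain("All probabilities must lie in [0, 1].")
  }
  if (age_min < 18) stop_domain("`age_min` must be at least 18 (adult norms).")
  spec <- list(
    n = as.integer(n), sex_ratio = sex_ratio,
    age_mean = age_mean, age_sd = age_sd,
    age_min = age_min, age_max = age_max,
    scale_targets = scale_targets,
    optin_probability = optin_probability,
    topic_probabilities = topic_probabilities,
    comparator_probabilities =
      comparator_probabilities / sum(comparator_probabilities),
    missing_rate = missing_rate,
    seed = seed
  )
  structure(spec, class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_scale_targets <- function() {
  reference_stats() %>%
    filter(.data$cohort == "patients") %>%
    select("scale_id", "mean", "sd")
}

#' @rdname cohort_spec
#' @export
default_topic_probabilities <- function() {
  c(general_qol = 1.00, physical = 0.92, emotional = 0.89, social = 0.92,
    cognitive = 0.86, fatigue = 0.86, tingling = 0.81, anxiety = 0.83,
    depressive = 0.83)
}

#' @rdname cohort_spec
#' @export
default_comparator_probabilities <- function() {
  c(own_only = 2, lymphoma_only = 11, normative_only = 0, both = 23) / 36
}

# inverse-CDF truncated normal draw (deterministic given RNG stream)
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pa <- pnorm(lo, mean, sd)
  pb <- pnorm(hi, mean, sd)
  qnorm(runif(n, pa, pb), mean, sd)
}

# Expected scored value when a truncated-normal latent is rounded to the
# scale's achievable score grid (uniform spacing `step` over [lo, hi],
# nearest-point rounding with bin edges halfway between grid points).
expected_grid_score <- function(mu, sd, step, lo, hi) {
  grid <- seq(lo, hi, by = step)
  edges <- c(lo, grid[-1] - step / 2, hi)
  p <- pnorm(edges, mu, sd)
  z <- p[length(p)] - p[1]
  sum(grid * diff(p)) / z
}

# Location calibration. Two biases would otherwise shift the realized
# mean away from the target: truncation at the scale limits (bounded
# scores pile up near the ceiling; up to ~9 points for a mean near 100)
# and nearest-grid rounding on coarse scales (a single 1-4 item has a
# 33.3-point step). Solve for the latent location whose expected *scored*
# value equals the target.
calibrate_latent_mu <- function(target_mean, sd, step, lo, hi) {
  if (target_mean < lo || target_mean > hi) {
    stop_domain("Target mean outside the score range.")
  }
  lo_mean <- expected_grid_score(lo - 8 * sd, sd, step, lo, hi)
  hi_mean <- expected_grid_score(hi + 8 * sd, sd, step, lo, hi)
  if (target_mean <= lo_mean || target_mean >= hi_mean) {
    stop_domain(paste0("Target mean ", target_mean,
                       " is not attainable with SD ", sd,
                       " on this scale's score grid."))
  }
  f <- function(mu) expected_grid_score(mu, sd, step, lo, hi) - target_mean
  stats::uniroot(f, lower = lo - 8 * sd, upper = hi + 8 * sd,
                 tol = 1e-9)$root
}

derive_stream_seeds <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

#' Simulate an item-level cohort
#'
#' For each patient: demographics from the spec's distributions; for each
#' scale a latent score drawn from a normal truncated to the score range,
#' its location calibrated so the truncated mean equals the target mean
#' (bounded scores pile up at the ceiling, so an uncalibrated truncation
#' would bias the realized mean; the nominal SD is kept, and near a scale
#' boundary the realized SD is somewhat smaller). Item responses are then
#' constructed so the scored scale equals
#' the *nearest achievable* score to the latent value (the raw item sum
#' is rounded to the nearest integer; which items absorb the units is
#' randomized). Opt-in, topics and comparator sets are drawn
#' independently with the spec probabilities. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param scales Scale registry; targets must name scales in it.
#' @return A list of tibbles: `demographics` (patient_id, sex, age),
#'   `items` (patient_id, item_id, response), `selections` (patient_id,
#'   wants_feedback, topics and comparators list-columns).
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_spec(n = 5, seed = 42))
#' score_responses(sim$items)
simulate_cohort <- function(spec, scales = default_scales()) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_scales(scales)
  targets <- spec$scale_targets
  unknown <- setdiff(targets$scale_id, scales$scale_id)
  if (length(unknown)) {
    stop_config(paste0("Targets name unknown scale(s): ",
                       paste(unknown, collapse = ", ")))
  }
  for (i in seq_len(nrow(targets))) {
    sc <- scale_row(scales, targets$scale_id[i])
    if (targets$mean[i] < sc$score_min || targets$mean[i] > sc$score_max) {
      stop_domain(paste0("Target mean ", targets$mean[i],
                         " outside the score range of ",
                         targets$scale_id[i], "."))
    }
  }
  n <- spec$n
  if (n == 0) {
    return(list(
      demographics = tibble(patient_id = character(), sex = character(),
                            age = double()),
      items = tibble(patient_id = character(), item_id = character(),
                     response = double()),
      selections = tibble(patient_id = character(),
                          wants_feedback = logical(),
                          topics = list(), comparators = list())
    ))
  }
  ss <- derive_stream_seeds(spec$seed, 4)
  ids <- sprintf("P%05d", seq_len(n))

  # stream 1: demographics
  if (!is.null(ss)) set.seed(ss[1])
  sex <- ifelse(runif(n) < spec$sex_ratio, "male", "female")
  age <- rtrunc_norm(n, spec$age_mean, spec$age_sd, spec$age_min, spec$age_max)
  demographics <- tibble(patient_id = ids, sex = sex, age = age)

  # stream 2: latent scores -> item responses
  if (!is.null(ss)) set.seed(ss[2])
  items_out <- vector("list", nrow(targets))
  for (t in seq_len(nrow(targets))) {
    sc <- scale_row(scales, targets$scale_id[t])
    it <- sc$items[[1]]
    k <- nrow(it); lo <- it$response_min[1]; hi <- it$response_max[1]
    step <- if (sc$transform == "hads_sum") 1 else 100 / (k * (hi - lo))
    mu_star <- calibrate_latent_mu(targets$mean[t], targets$sd[t], step,
                                   sc$score_min, sc$score_max)
    latent <- rtrunc_norm(n, mu_star, targets$sd[t],
                          sc$score_min, sc$score_max)
    if (sc$transform == "hads_sum") {
      target_sum <- round(latent)
    } else {
      raw_mean <- if (sc$transform == "eortc_functioning") {
        lo + (1 - latent / 100) * (hi - lo)
      } else {
        lo + (latent / 100) * (hi - lo)
      }
      target_sum <- round(raw_mean * k)
    }
    target_sum <- pmin(pmax(target_sum, k * lo), k * hi)
    units <- target_sum - k * lo
    cap <- hi - lo
    resp <- matrix(lo, nrow = n, ncol = k)
    slot_items <- rep(seq_len(k), each = cap)
    for (p in seq_len(n)) {
      if (units[p] > 0) {
        take <- slot_items[sample.int(k * cap, units[p])]
        resp[p, ] <- lo + tabulate(take, nbins = k)
      }
    }
    items_out[[t]] <- tibble(
      patient_id = rep(ids, each = k),
      item_id = rep(it$item_id, times = n),
      response = as.double(t(resp))
    )
  }
  items <- bind_rows(items_out) %>%
    arrange(match(.data$patient_id, ids))

  # stream 3: missingness
  if (spec$missing_rate > 0) {
    if (!is.null(ss)) set.seed(ss[3])
    drop <- runif(nrow(items)) < spec$missing_rate
    items$response[drop] <- NA_real_
  }

  # stream 4: feedback selections
  if (!is.null(ss)) set.seed(ss[4])
  wants <- runif(n) < spec$optin_probability
  tp <- spec$topic_probabilities
  comp_sets <- list(
    own_only = "own_only",
    lymphoma_only = "lymphoma_cohort",
    normative_only = "normative_population",
    both = c("lymphoma_cohort", "normative_population")
  )
  cp <- spec$comparator_probabilities[names(comp_sets)]
  topics <- vector("list", n)
  comparators <- vector("list", n)
  for (p in seq_len(n)) {
    if (!wants[p]) {
      topics[[p]] <- character(0)
      comparators[[p]] <- character(0)
    } else {
      topics[[p]] <- names(tp)[runif(length(tp)) < tp]
      set_name <- sample(names(comp_sets), 1, prob = cp)
      comparators[[p]] <- comp_sets[[set_name]]
    }
  }
  selections <- tibble(patient_id = ids, wants_feedback = wants,
                       topics = topics, comparators = comparators)

  list(demographics = demographics, items = items, selections = selections)
}

#' Simulate subject-level reference microdata
#'
#' Subject-level scores from a linear generative model
#' `score = baseline + group_effect * I(group 1) + age_effect * age +
#' sex_effect * I(male) + noise`, with optionally group-specific age
#' distributions so that age confounding can be constructed on purpose.
#' Intended for ANCOVA recovery and null-calibration tests.
#'
#' @param n Length-2 vector: subjects in group 1 and group 2.
#' @param group_labels Labels for the two groups.
#' @param baseline Intercept (score units).
#' @param group_effect Adjusted difference added to group 1.
#' @param age_effect,sex_effect Linear covariate effects (per year; male
#'   vs female).
#' @param age_mean,age_sd Length-1 or length-2 (per group) age
#'   distribution parameters.
#' @param sex_ratio Fraction male, length 1 or 2.
#' @param resid_sd Residual SD of the noise.
#' @param seed Optional seed.
#' @return A tibble: subject_id, group, age, sex, score.
#' @export
#' @examples
#' simulate_norm_microdata(n = c(50, 50), group_effect = 10, seed = 7)
simulate_norm_microdata <- function(n = c(100, 100),
                                    group_labels = c("patients", "reference"),
                                    baseline = 70,
                                    group_effect = 0,
                                    age_effect = 0,
                                    sex_effect = 0,
                                    age_mean = 60.7, age_sd = 13.6,
                                    sex_ratio = 0.58,
                                    resid_sd = 20,
                                    seed = NULL) {
  if (length(n) != 2 || any(n < 0)) stop_domain("`n` must give two group sizes.")
  if (!is.null(seed)) set.seed(seed)
  age_mean <- rep_len(age_mean, 2)
  age_sd <- rep_len(age_sd, 2)
  sex_ratio <- rep_len(sex_ratio, 2)
  rows <- lapply(1:2, function(g) {
    ng <- n[g]
    tibble(
      group = rep(group_labels[g], ng),
      age = rtrunc_norm(ng, age_mean[g], age_sd[g], 18, 95),
      sex = ifelse(runif(ng) < sex_ratio[g], "male", "female")
    )
  })
  out <- bind_rows(rows)
  is_g1 <- out$group == group_labels[1]
  out %>%
    mutate(
      subject_id = sprintf("S%05d", row_number()),
      score = baseline + group_effect * as.numeric(is_g1) +
        age_effect * .data$age +
        sex_effect * as.numeric(.data$sex == "male") +
        rnorm(sum(n), 0, resid_sd)
    ) %>%
    select("subject_id", "group", "age", "sex", "score")
}
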