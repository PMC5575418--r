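# Independent oracles and fixture builders used across the suite.

# A complete, all-favorable response vector over the default battery.
favorable_responses <- function() {
  c(
    setNames(rep(1, 5), paste0("c30_q0", 1:5)),
    setNames(rep(1, 4), paste0("c30_q", 21:24)),
    c30_q20 = 1, c30_q25 = 1, c30_q26 = 1, c30_q27 = 1,
    c30_q29 = 7, c30_q30 = 7,
    c30_q10 = 1, c30_q12 = 1, c30_q18 = 1,
    lym_tingling = 1,
    setNames(rep(0, 14), sprintf("hads_q%02d", 1:14))
  )
}

# long-format items tibble from a named response vector
items_from_responses <- function(responses, patient_id = "P1") {
  tibble::tibble(
    patient_id = patient_id,
    item_id = names(responses),
    response = as.double(responses)
  )
}

# Brute-force two-sided exact test for an r x 2 table: enumerate every
# first-column vector directly and compute multivariate hypergeometric
# probabilities from products of binomial coefficients (a different
# formula and a different enumeration strategy than the implementation).
oracle_exact_rx2 <- function(x) {
  R <- rowSums(x); C1 <- sum(x[, 1]); N <- sum(x)
  grids <- lapply(R, function(r) 0:r)
  grid <- do.call(expand.grid, grids)
  grid <- grid[rowSums(grid) == C1, , drop = FALSE]
  prob <- apply(grid, 1, function(v) prod(choose(R, v)) / choose(N, C1))
  pobs <- prod(choose(R, x[, 1])) / choose(N, C1)
  sum(prob[prob <= pobs * (1 + 1e-7)])
}

# Segment-membership reference classifier: build the three intervals
# explicitly and report which one contains the score, boundary points
# belonging to the extreme colours.
oracle_classify <- function(score, mean, d, polarity) {
  below <- if (polarity == "higher_is_better") "red" else "green"
  above <- if (polarity == "higher_is_better") "green" else "red"
  if (score <= mean - d) below
  else if (score >= mean + d) above
  else "amber"
}

# Normal-equations least squares (explicit X'X solve, no lm()).
oracle_normal_equations <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
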