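# Study statistics: exact contingency-table tests (Fisher 2x2 and the
# Freeman-Halton r x c generalization by complete enumeration), two-sample
# t tests usable from raw data or printed summary statistics, and ANCOVA
# with age and sex as covariates.

#' Two-sided Fisher / Freeman-Halton exact test
#'
#' For a 2x2 table, the two-sided exact p value is the sum of
#' hypergeometric probabilities (margins fixed) of all tables no more
#' probable than the observed one. For r x c tables the Freeman-Halton
#' generalization enumerates every table with the observed margins and
#' sums the multivariate hypergeometric probabilities of those with
#' probability at most that of the observed table. Probability ties are
#' compared with a small relative tolerance so that floating-point noise
#' never excludes a genuinely tied table.
#'
#' @param x A matrix (or table) of non-negative integer counts, at least
#'   2x2, with no all-zero row or column margin.
#' @param tie_tol Relative tolerance when comparing a table's probability
#'   with the observed table's; default `1e-7`.
#' @param max_tables Enumeration guard: an upper bound on the number of
#'   candidate tables above which the test refuses to run exactly.
#' @return A tibble: `method`, `statistic` (`NA`; the test has no test
#'   statistic), `p_value`, `df` (`NA`), `n_tables` (tables enumerated;
#'   `NA` on the 2x2 fast path).
#' @export
#' @examples
#' fisher_exact(matrix(c(8, 1, 37, 18), 2, byrow = TRUE))
fisher_exact <- function(x, tie_tol = 1e-7, max_tables = 2e6) {
  x <- as.matrix(x)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    stop_domain("Counts must be non-negative integers.")
  }
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop_domain("Need at least a 2x2 table.")
  }
  storage.mode(x) <- "double"
  R <- rowSums(x); C <- colSums(x); N <- sum(x)
  if (N == 0 || any(R == 0) || any(C == 0)) {
    stop_domain("Table has an all-zero margin.")
  }

  if (nrow(x) == 2 && ncol(x) == 2) {
    p <- fisher_2x2_p(x, tie_tol)
    return(tibble(method = "fisher_exact", statistic = NA_real_,
                  p_value = p, df = NA_real_, n_tables = NA_integer_))
  }

  # guard: crude upper bound on the number of candidate tables
  free <- outer(R[-length(R)], C[-length(C)], pmin) + 1
  if (prod(free) > max_tables) {
    stop_resource(paste0(
      "Exact enumeration bound (", format(prod(free), big.mark = ","),
      " candidate tables) exceeds max_tables = ", format(max_tables),
      "; consider a Monte-Carlo approximation, e.g. ",
      "stats::fisher.test(x, simulate.p.value = TRUE)."
    ))
  }

  enum <- enumerate_margin_tables(R, C)
  # log P(table) = const - sum(lfactorial(cells)); const cancels in the
  # comparison but is needed for the probabilities themselves
  const <- sum(lfactorial(R)) + sum(lfactorial(C)) - lfactorial(N)
  logp <- const + enum$neg_lfact
  obs_logp <- const - sum(lfactorial(x))
  keep <- logp <= obs_logp + log1p(tie_tol)
  p <- min(1, sum(exp(logp[keep])))
  tibble(method = "freeman_halton_exact", statistic = NA_real_,
         p_value = p, df = NA_real_, n_tables = length(logp))
}

fisher_2x2_p <- function(x, tie_tol) {
  m <- sum(x[1, ]); n <- sum(x[2, ]); k <- sum(x[, 1])
  support <- max(0, k - n):min(k, m)
  dens <- dhyper(support, m, n, k)
  obs <- dhyper(x[1, 1], m, n, k)
  min(1, sum(dens[dens <= obs * (1 + tie_tol)]))
}

# Enumerate all r x c tables with the given margins, returning
# -sum(lfactorial(cells)) per table. Recursive row-by-row generation with
# column-feasibility pruning.
enumerate_margin_tables <- function(R, C) {
  r <- length(R); c <- length(C)
  acc <- new.env(parent = emptyenv())
  acc$vals <- numeric(1024)
  acc$n <- 0L
  push <- function(v) {
    if (acc$n == length(acc$vals)) {
      acc$vals <- c(acc$vals, numeric(length(acc$vals)))
    }
    acc$n <- acc$n + 1L
    acc$vals[acc$n] <- v
  }
  recurse <- function(row, cols_left, neg_lfact) {
    if (row == r) {
      # last row forced by remaining column margins
      if (all(cols_left >= 0) && sum(cols_left) == R[r]) {
        push(neg_lfact - sum(lfactorial(cols_left)))
      }
      return(invisible(NULL))
    }
    # enumerate compositions of R[row] over c cells, bounded by cols_left
    comp <- function(j, remaining, cells) {
      if (j == c) {
        if (remaining <= cols_left[c]) {
          recurse(row + 1, cols_left - c(cells, remaining),
                  neg_lfact - sum(lfactorial(c(cells, remaining))))
        }
        return(invisible(NULL))
      }
      for (v in 0:min(remaining, cols_left[j])) {
        comp(j + 1, remaining - v, c(cells, v))
      }
    }
    comp(1, R[row], numeric(0))
  }
  recurse(1, C, 0)
  list(neg_lfact = acc$vals[seq_len(acc$n)])
}

#' Two-sample t test from summary statistics
#'
#' Two-sided two-sample t test computed directly from per-group mean, SD
#' and n — the form needed when comparing groups from printed summary
#' rows. `variant = "pooled"` is the classical equal-variance Student
#' test; `"welch"` uses the Welch-Satterthwaite approximation. When both
#' groups have zero variance and equal means the convention `statistic =
#' 0, p = 1` applies; zero variance with unequal means is a domain error.
#'
#' @param mean1,sd1,n1 First group summary statistics (n >= 2).
#' @param mean2,sd2,n2 Second group summary statistics.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return A tibble: `method`, `estimate` (mean1 - mean2), `statistic`,
#'   `p_value`, `df`.
#' @export
#' @examples
#' t_test_summary(60.7, 13.6, 45, 63.8, 14.7, 19)
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                           variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop_domain("Each group needs n >= 2.")
  if (sd1 < 0 || sd2 < 0) stop_domain("SDs must be non-negative.")
  est <- mean1 - mean2
  if (variant == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  if (se == 0) {
    if (est == 0) {
      return(tibble(method = paste0("t_", variant), estimate = 0,
                    statistic = 0, p_value = 1,
                    df = if (variant == "pooled") n1 + n2 - 2 else NA_real_))
    }
    stop_domain("Zero variance in both groups with unequal means.")
  }
  stat <- est / se
  tibble(method = paste0("t_", variant), estimate = est, statistic = stat,
         p_value = 2 * pt(-abs(stat), df), df = df)
}

#' Two-sample t test on raw per-subject data
#'
#' Computes each group's mean/SD/n and delegates to [t_test_summary()],
#' so the raw-data and summary-statistic entry points agree exactly.
#'
#' @param data A data frame.
#' @param score,group Columns (tidy-eval) holding the numeric outcome and
#'   a two-level grouping variable. The estimate is first level minus
#'   second level (factor order, or sorted unique values).
#' @inheritParams t_test_summary
#' @return As [t_test_summary()].
#' @export
t_test_groups <- function(data, score, group,
                          variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  score <- dplyr::pull(data, {{ score }})
  grp <- dplyr::pull(data, {{ group }})
  lv <- if (is.factor(grp)) levels(droplevels(grp)) else sort(unique(grp))
  if (length(lv) != 2) stop_domain("`group` must have exactly 2 levels.")
  keep <- !is.na(score) & !is.na(grp)
  score <- score[keep]; grp <- grp[keep]
  a <- score[grp == lv[1]]; b <- score[grp == lv[2]]
  t_test_summary(mean(a), stats::sd(a), length(a),
                 mean(b), stats::sd(b), length(b), variant = variant)
}

#' ANCOVA group effect with age and sex as covariates
#'
#' Least-squares fit of `score ~ group + age + sex`, the model used to
#' compare a patient group's mean scale scores with a reference cohort
#' while adjusting for age and sex. The group effect is the adjusted mean
#' difference; adjusted means are evaluated at the overall covariate
#' means; the p value comes from the group coefficient's t statistic.
#'
#' @param data A data frame.
#' @param score,group,age,sex Columns (tidy-eval): numeric outcome, a
#'   two-level group, age in years (untransformed), and sex, coerced to a
#'   0/1 indicator (logical, 0/1 numeric, or a two-level factor/character
#'   coded by level order).
#' @return An `ancova_fit` object with elements `group_effect` (second
#'   level minus first), `p_value`, `adjusted_means`, and the underlying
#'   `lm` fit; has [tidy()], [glance()] and `print()` methods.
#' @export
#' @examples
#' d <- simulate_norm_microdata(n = c(60, 60), group_effect = 8, seed = 1)
#' ancova_group_effect(d, score, group, age, sex)
ancova_group_effect <- function(data, score, group, age, sex) {
  df <- tibble(
    score = dplyr::pull(data, {{ score }}),
    group = dplyr::pull(data, {{ group }}),
    age = dplyr::pull(data, {{ age }}),
    sex = dplyr::pull(data, {{ sex }})
  )
  df <- df[complete.cases(df), ]
  if (!is.factor(df$group)) df$group <- factor(df$group)
  df$group <- droplevels(df$group)
  if (nlevels(df$group) != 2) stop_domain("`group` must have exactly 2 levels.")
  if (min(table(df$group)) < 2) stop_domain("Need >= 2 subjects per group.")
  df$sex01 <- coerce_binary(df$sex, "sex")
  fit <- lm(score ~ group + age + sex01, data = df)
  if (fit$rank < 4) {
    aliased <- names(which(is.na(coef(fit))))
    stop_domain(paste0("Singular design; collinear term(s): ",
                       paste(aliased, collapse = ", "), "."))
  }
  cf <- summary(fit)$coefficients
  grow <- grep("^group", rownames(cf))
  effect <- cf[grow, "Estimate"]
  p <- cf[grow, "Pr(>|t|)"]
  mean_age <- mean(df$age); mean_sex <- mean(df$sex01)
  b <- coef(fit)
  base <- b[["(Intercept)"]] + b[["age"]] * mean_age + b[["sex01"]] * mean_sex
  adj <- tibble(
    group = levels(df$group),
    adjusted_mean = c(base, base + effect)
  )
  structure(
    list(fit = fit, group_effect = unname(effect), p_value = unname(p),
         adjusted_means = adj,
         covariate_means = c(age = mean_age, sex = mean_sex),
         n = nrow(df)),
    class = "ancova_fit"
  )
}

coerce_binary <- function(x, what) {
  if (is.logical(x)) return(as.numeric(x))
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) {
      stop_domain(paste0("Numeric `", what, "` must be coded 0/1."))
    }
    return(x)
  }
  f <- droplevels(factor(x))
  if (nlevels(f) > 2) stop_domain(paste0("`", what, "` must have at most 2 levels."))
  as.numeric(f) - 1
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat("<ancova_fit> score ~ group + age + sex, n =", x$n, "\n")
  cat("  adjusted group effect (", x$adjusted_means$group[2], " - ",
      x$adjusted_means$group[1], "): ",
      format(x$group_effect, digits = 4), ", p = ",
      format.pval(x$p_value, digits = 3), "\n", sep = "")
  print(x$adjusted_means)
  invisible(x)
}

#' @export
tidy.ancova_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std.error = cf[, "Std. Error"],
    statistic = cf[, "t value"],
    p.value = cf[, "Pr(>|t|)"]
  )
}

#' @export
glance.ancova_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    r.squared = s$r.squared,
    sigma = s$sigma,
    df.residual = x$fit$df.residual,
    nobs = x$n,
    group_effect = x$group_effect,
    p_value = x$p_value
  )
}
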