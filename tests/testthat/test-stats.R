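test_that("2x2 exact test matches flat tables, ties, and the generic path", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  # the fast 2x2 path equals the generic r x c enumeration restricted to 2x2
  set.seed(3)
  for (i in 1:20) {
    x <- matrix(rpois(4, 6) + 1, 2)
    p22 <- fisher_exact(x)$p_value
    enum <- prolight:::enumerate_margin_tables(rowSums(x), colSums(x))
    const <- sum(lfactorial(rowSums(x))) + sum(lfactorial(colSums(x))) -
      lfactorial(sum(x))
    logp <- const + enum$neg_lfact
    obs <- const - sum(lfactorial(x))
    p_generic <- sum(exp(logp[logp <= obs + log1p(1e-7)]))
    expect_equal(p22, min(1, p_generic), tolerance = 1e-12)
    # and the mainstream implementation agrees
    expect_equal(p22, stats::fisher.test(x)$p.value, tolerance = 1e-9)
  }
})

test_that("enumerated table probabilities sum to one", {
  margins <- list(
    list(R = c(9, 55), C = c(45, 19)),
    list(R = c(12, 12, 9, 17), C = c(36, 14)),
    list(R = c(8, 10, 7), C = c(9, 9, 7))
  )
  for (m in margins) {
    enum <- prolight:::enumerate_margin_tables(m$R, m$C)
    const <- sum(lfactorial(m$R)) + sum(lfactorial(m$C)) -
      lfactorial(sum(m$R))
    expect_equal(sum(exp(const + enum$neg_lfact)), 1, tolerance = 1e-9)
  }
})

test_that("r x c exact test equals a direct multivariate-hypergeometric oracle", {
  tables <- list(
    matrix(c(3, 4, 5, 2, 1, 6), 3, 2, byrow = TRUE),
    matrix(c(2, 2, 4, 1, 5, 3), 3, 2, byrow = TRUE),
    matrix(c(8, 4, 10, 2, 5, 4, 13, 4), 4, 2, byrow = TRUE),
    matrix(c(2, 1, 19, 8, 13, 1, 11, 9), 4, 2, byrow = TRUE)
  )
  for (x in tables) {
    got <- fisher_exact(x)
    expect_equal(got$p_value, oracle_exact_rx2(x), tolerance = 1e-12)
    expect_equal(got$p_value, stats::fisher.test(x)$p.value, tolerance = 1e-7)
  }
  # a genuinely 3-column case against the mainstream implementation
  x3 <- matrix(c(1, 3, 4, 5, 2, 2, 3, 1, 4), 3, 3, byrow = TRUE)
  expect_equal(fisher_exact(x3)$p_value, stats::fisher.test(x3)$p.value,
               tolerance = 1e-7)
})

test_that("exact test rejects malformed tables and huge enumerations", {
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)),
               class = "prolight_domain_error")
  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2)),
               class = "prolight_domain_error")
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               class = "prolight_domain_error")
  expect_error(fisher_exact(matrix(1, 1, 2)), class = "prolight_domain_error")
  big <- matrix(50, 5, 5)
  expect_error(fisher_exact(big, max_tables = 1000),
               class = "prolight_resource_error")
})

test_that("exact p values are valid under margin-fixed null simulation", {
  set.seed(101)
  n_sim <- 1500
  tabs <- stats::r2dtable(n_sim, c(14, 16), c(13, 17))
  pvals <- vapply(tabs, function(x) fisher_exact(x)$p_value, double(1))
  for (alpha in c(0.01, 0.05, 0.1)) {
    mc <- 3 * sqrt(alpha * (1 - alpha) / n_sim)
    expect_lte(mean(pvals <= alpha), alpha + mc)
  }
})

test_that("t tests agree between entry points, variants, and the reference implementation", {
  expect_equal(t_test_summary(5, 1, 10, 5, 1, 10)$p_value, 1)
  # printed-summary worked example: pooled t on age
  res <- t_test_summary(60.7, 13.6, 45, 63.8, 14.7, 19)
  expect_equal(round(res$statistic, 2), -0.81)
  expect_equal(res$df, 62)
  set.seed(5)
  for (variant in c("pooled", "welch")) {
    a <- rnorm(14, 50, 9); b <- rnorm(23, 55, 12)
    df <- tibble::tibble(score = c(a, b),
                         group = rep(c("A", "B"), c(14, 23)))
    mine <- t_test_groups(df, score, group, variant = variant)
    summ <- t_test_summary(mean(a), sd(a), 14, mean(b), sd(b), 23,
                           variant = variant)
    expect_equal(mine$p_value, summ$p_value)
    ref <- stats::t.test(a, b, var.equal = (variant == "pooled"))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
  }
  # zero-variance conventions
  z <- t_test_summary(3, 0, 5, 3, 0, 5)
  expect_equal(z$statistic, 0); expect_equal(z$p_value, 1)
  expect_error(t_test_summary(3, 0, 5, 4, 0, 5),
               class = "prolight_domain_error")
  expect_error(t_test_summary(3, 1, 1, 4, 1, 5),
               class = "prolight_domain_error")
})

test_that("ANCOVA coefficients equal a normal-equations oracle on a worked dataset", {
  d <- tibble::tibble(
    score = c(62, 75, 58, 80, 70, 66),
    group = c("patients", "patients", "patients",
              "reference", "reference", "reference"),
    age = c(55, 62, 48, 60, 51, 70),
    sex = c("male", "female", "male", "female", "male", "male")
  )
  fit <- ancova_group_effect(d, score, group, age, sex)
  X <- cbind(1, as.numeric(d$group == "reference"), d$age,
             as.numeric(factor(d$sex)) - 1)
  beta <- oracle_normal_equations(X, d$score)
  expect_equal(fit$group_effect, beta[2], tolerance = 1e-10)
  expect_equal(unname(coef(fit$fit)), unname(beta), tolerance = 1e-10)
  # adjusted means differ by exactly the group effect
  expect_equal(diff(fit$adjusted_means$adjusted_mean), fit$group_effect)
})

test_that("ANCOVA reduces to the pooled-t estimate on a perfectly balanced design", {
  set.seed(23)
  ages <- round(runif(30, 25, 80))
  sexes <- rep(c("male", "female"), 15)
  d <- tibble::tibble(
    score = rnorm(60, 70, 15),
    group = rep(c("g1", "g2"), each = 30),
    age = c(ages, ages),
    sex = c(sexes, sexes)
  )
  fit <- ancova_group_effect(d, score, group, age, sex)
  tt <- t_test_groups(d, score, group)
  # covariates are orthogonal to group, so the point estimates coincide
  expect_equal(fit$group_effect, -tt$estimate, tolerance = 1e-10)
})

test_that("ANCOVA detects singular designs and names the collinear term", {
  d <- tibble::tibble(
    score = rnorm(20), group = rep(c("a", "b"), 10),
    age = rep(50, 20), sex = rep("male", 20)
  )
  err <- expect_error(ancova_group_effect(d, score, group, age, sex),
                      class = "prolight_domain_error")
  expect_match(conditionMessage(err), "sex01|age")
})

test_that("ANCOVA tidy/glance expose broom-style summaries", {
  d <- simulate_norm_microdata(n = c(40, 40), group_effect = 5, seed = 31)
  fit <- ancova_group_effect(d, score, group, age, sex)
  td <- tidy(fit)
  expect_equal(names(td),
               c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 4)
  gl <- glance(fit)
  expect_equal(gl$nobs, 80)
  expect_equal(gl$group_effect, fit$group_effect)
})
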