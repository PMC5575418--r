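test_that("classification against a norm follows the clinically-relevant-difference rule", {
  expect_equal(classify_score(74, 74, 10)$color, "amber")
  # boundary scores take the extreme colour ("as much as or more than")
  expect_equal(classify_score(84, 74, 10)$color, "green")
  expect_equal(classify_score(64, 74, 10)$color, "red")
  # symptom polarity: 13-point unfavorable difference on fatigue
  expect_equal(classify_score(30, 17, 5, polarity = "higher_is_worse")$color,
               "red")
  expect_error(classify_score(50, 74, 0), class = "prolight_domain_error")
  expect_error(classify_score(101, 74, 10), class = "prolight_domain_error")
})

test_that("classifier agrees with the segment-membership oracle on a dense grid", {
  for (polarity in c("higher_is_better", "higher_is_worse")) {
    for (m in c(17, 50, 74, 90.5)) {
      for (d in c(5, 9, 14)) {
        for (s in seq(0, 100, by = 0.5)) {
          got <- classify_score(s, m, d, polarity = polarity)$color
          expect_identical(got, oracle_classify(s, m, d, polarity))
          if (abs(s - m) == d) expect_true(got != "amber")
        }
      }
    }
  }
})

test_that("segments tile the score range and contain the patient's score", {
  set.seed(7)
  for (i in 1:200) {
    m <- runif(1, 0, 100); d <- runif(1, 1, 30); s <- runif(1, 0, 100)
    pol <- sample(c("higher_is_better", "higher_is_worse"), 1)
    res <- classify_score(s, m, d, polarity = pol)
    seg <- res$boundaries
    expect_lte(nrow(seg), 3)
    expect_equal(seg$lo[1], 0)
    expect_equal(seg$hi[nrow(seg)], 100)
    if (nrow(seg) > 1) expect_equal(seg$lo[-1], seg$hi[-nrow(seg)])
    # the score lies in (or on the boundary of) its colour's segment
    own <- seg[seg$color == res$color, ]
    expect_true(nrow(own) == 1 && own$lo <= s && s <= own$hi)
  }
})

test_that("flipping polarity and reflecting the score swaps green and red", {
  set.seed(17)
  for (i in 1:100) {
    m <- runif(1, 20, 80); d <- runif(1, 1, 15); s <- runif(1, 0, 100)
    a <- classify_score(s, m, d, polarity = "higher_is_better")$color
    reflected <- 2 * m - s
    if (reflected >= 0 && reflected <= 100) {
      b <- classify_score(reflected, m, d, polarity = "higher_is_worse")$color
      expect_identical(a, b)
    }
  }
})

test_that("colour is monotone in the score on a higher_is_better scale", {
  ranks <- c(red = 1, amber = 2, green = 3)
  cols <- vapply(seq(0, 100, by = 0.25),
                 function(s) classify_score(s, 60, 12)$color, character(1))
  expect_true(all(diff(ranks[cols]) >= 0))
})

test_that("extreme segments clipped away by the scale range are dropped", {
  res <- classify_score(95, 90.5, 14)   # mean + d > 100
  expect_equal(nrow(res$boundaries), 2)
  expect_false("green" %in% res$boundaries$color)
  expect_equal(res$color, "amber")
  # but a boundary exactly at the range edge keeps its degenerate segment
  res2 <- classify_score(100, 90, 10)
  expect_equal(res2$color, "green")
  expect_true("green" %in% res2$boundaries$color)
})

test_that("HADS severity bands partition the integer score range", {
  cols <- vapply(0:21, function(s) classify_hads(s)$color, character(1))
  expect_equal(unname(cols[1:8]), rep("green", 8))    # 0-7
  expect_equal(unname(cols[9:11]), rep("amber", 3))   # 8-10
  expect_equal(unname(cols[12:22]), rep("red", 11))   # >= 11
  expect_equal(min(which(cols == "amber")) - 1, 8)
  expect_equal(min(which(cols == "red")) - 1, 11)
  expect_error(classify_hads(22), class = "prolight_domain_error")
  seg <- classify_hads(0)$boundaries
  expect_equal(seg$lo[1], 0); expect_equal(seg$hi[3], 21)
  expect_equal(seg$lo[-1], seg$hi[-3])
})

test_that("GP advice triggers on red symptom scores only, unless extended", {
  scales <- default_scales()
  fa <- scales[scales$scale_id == "fatigue", ]
  pf <- scales[scales$scale_id == "physical_functioning", ]
  anx <- scales[scales$scale_id == "hads_anxiety", ]
  red_fa <- classify_score(60, 17, 5, polarity = "higher_is_worse")
  expect_true(gp_advice_flag(red_fa, fa))
  red_pf <- classify_score(40, 79.4, 14)
  expect_equal(red_pf$color, "red")
  expect_false(gp_advice_flag(red_pf, pf))
  expect_true(gp_advice_flag(red_pf, pf,
                             gp_advice_policy(include_functioning = TRUE)))
  amber_anx <- classify_hads(9)
  expect_false(gp_advice_flag(amber_anx, anx))
})

test_that("colour tabulation matches counts and the normal-tail oracle", {
  empty <- color_counts(character(0))
  expect_equal(empty$n, c(0L, 0L, 0L))
  cc <- color_counts(c("green", "red", "red"))
  expect_equal(cc$n[cc$color == "green"], 1L)
  expect_equal(cc$n[cc$color == "amber"], 0L)
  expect_equal(cc$n[cc$color == "red"], 2L)
  expect_equal(sum(cc$pct), 100)
  # scores drawn from the norm distribution with d = 0.5 SD: each extreme
  # colour has the closed-form tail mass beyond half an SD
  set.seed(42)
  n <- 4000; m <- 50; sdev <- 12
  scores <- pmin(pmax(rnorm(n, m, sdev), 0), 100)
  cols <- vapply(scores, function(s) classify_score(s, m, 0.5 * sdev)$color,
                 character(1))
  tail_mass <- pnorm(-0.5)   # ~0.3085
  mc <- 3 * sqrt(tail_mass * (1 - tail_mass) / n)
  cc2 <- color_counts(cols)
  expect_lt(abs(cc2$n[cc2$color == "red"] / n - tail_mass), mc)
  expect_lt(abs(cc2$n[cc2$color == "green"] / n - tail_mass), mc)
})

test_that("cohort classification joins norms and flags unavailable cells", {
  sim <- simulate_cohort(cohort_spec(n = 12, seed = 9))
  scores <- score_responses(sim$items)
  out <- classify_cohort(scores, sim$demographics, "normative_population")
  expect_equal(nrow(out), 12 * 9)
  ting <- out[out$scale_id == "tingling", ]
  expect_true(all(is.na(ting$color)))
  expect_true(all(ting$note == "comparison unavailable"))
  rest <- out[out$scale_id != "tingling" & !is.na(out$value), ]
  expect_true(all(rest$color %in% c("green", "amber", "red")))
  # HADS rows classify on absolute cutoffs: colour matches classify_hads
  hads <- out[out$scale_id == "hads_anxiety", ]
  expect_identical(hads$color,
                   vapply(hads$value, function(v) classify_hads(v)$color,
                          character(1)))
})

test_that("traffic-light results tidy and plot", {
  res <- classify_score(62, 74, 10, comparator = "lymphoma_cohort",
                        scale_id = "global_qol")
  td <- tidy(res)
  expect_equal(td$color, "red")
  expect_equal(td$n_segments, 3L)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
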