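test_that("pooled summaries reconstruct the whole-population mean and SD", {
  # TVL and BMI group summaries pool to the printed totals at 1 decimal
  tvl <- pooled_mean_sd(list(group_summary(9, 8.6, 1.5),
                             group_summary(6, 8.2, 0.8)))
  expect_equal(round(tvl$mean, 1), 8.4)
  bmi <- pooled_mean_sd(list(group_summary(9, 27.8, 3.8),
                             group_summary(6, 23.9, 3.2)))
  expect_equal(round(bmi$mean, 1), 26.2)
  # pooling two identical groups is idempotent
  g <- group_summary(7, 5.5, 1.1)
  pool <- pooled_mean_sd(list(g, g))
  expect_equal(pool$mean, 5.5)
  expect_equal(pool$sd, sqrt(12 * 1.1^2 / 13))  # within-group SS only
  # oracle: pooling summaries of raw halves equals summarising all raw data
  set.seed(61)
  x1 <- rnorm(9, 8, 2); x2 <- rnorm(6, 7, 1)
  pool2 <- pooled_mean_sd(list(summarize_group(x1), summarize_group(x2)))
  expect_equal(pool2$mean, mean(c(x1, x2)), tolerance = 1e-12)
  expect_equal(pool2$sd, sd(c(x1, x2)), tolerance = 1e-12)
})

test_that("the independent-samples t-test works from raw data or summaries", {
  expect_equal(t_test_independent(group_summary(5, 3, 1),
                                  group_summary(5, 3, 1))$t, 0)
  expect_equal(t_test_independent(group_summary(5, 3, 1),
                                  group_summary(5, 3, 1))$p, 1)
  # BMI summaries: p in the band the rounded summaries allow
  p_bmi <- t_test_independent(group_summary(9, 27.8, 3.8),
                              group_summary(6, 23.9, 3.2))$p
  expect_gt(p_bmi, 0.04)
  expect_lt(p_bmi, 0.07)
  # raw input and its summaries give the identical statistic
  set.seed(62)
  x1 <- rnorm(9); x2 <- rnorm(6)
  t_raw <- t_test_independent(x1, x2)
  t_sum <- t_test_independent(summarize_group(x1), summarize_group(x2))
  expect_equal(t_raw$t, t_sum$t, tolerance = 1e-10)
  # cross-check against the standard implementation, pooled and Welch
  ref <- t.test(x1, x2, var.equal = TRUE)
  expect_equal(t_raw$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(t_raw$p, ref$p.value, tolerance = 1e-12)
  refw <- t.test(x1, x2)
  tw <- t_test_independent(x1, x2, var_equal = FALSE)
  expect_equal(tw$p, refw$p.value, tolerance = 1e-12)
  # symmetry under group exchange
  expect_equal(t_test_independent(x2, x1)$p, t_raw$p, tolerance = 1e-12)
})

test_that("the exact Mann-Whitney test enumerates all rank splits", {
  # midrank convention for a complete tie
  r <- mann_whitney_u(1, 1)
  expect_equal(r$U, 0.5)
  expect_equal(r$p, 1)
  # fully separated groups: U = 0, p = 2 / choose(6, 3)
  r2 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$U, 0)
  expect_equal(r2$p, 0.1)
  # identical groups are never significant
  expect_equal(mann_whitney_u(c(2, 4, 6), c(2, 4, 6))$p, 1)
  # tie-free small samples agree with the standard exact implementation
  set.seed(63)
  for (i in 1:5) {
    x1 <- sample(1:100, 6); x2 <- sample(101:200, 5) - 100.5
    ref <- wilcox.test(x1, x2, exact = TRUE)
    mine <- mann_whitney_u(x1, x2)
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1), "empty")
})

test_that("the exact contingency test reproduces known p-values", {
  # POP-Q stage-3 split between groups
  expect_equal(round(exact_contingency_test(matrix(c(3, 5, 6, 1), 2))$p, 3),
               0.119)
  # hand enumeration: 3 margin-fixed tables, observed is one of two extremes
  expect_equal(exact_contingency_test(matrix(c(2, 0, 0, 2), 2))$p, 1 / 3,
               tolerance = 1e-12)
  # zero margins are degenerate
  expect_equal(exact_contingency_test(matrix(c(0, 0, 3, 2), 2))$p, 1)
})

test_that("the exact test is invariant to transposition and row swaps", {
  tab <- matrix(c(3, 5, 6, 1), 2)
  p <- exact_contingency_test(tab)$p
  expect_equal(exact_contingency_test(t(tab))$p, p, tolerance = 1e-12)
  expect_equal(exact_contingency_test(tab[2:1, ])$p, p, tolerance = 1e-12)
})

test_that("the generic enumerator matches the hypergeometric 2x2 path and fisher.test", {
  tabs <- list(matrix(c(3, 5, 6, 1), 2), matrix(c(2, 2, 3, 4), 2),
               matrix(c(1, 7, 5, 2), 2))
  for (tab in tabs) {
    p_hyper <- exact_contingency_test(tab)$p
    p_generic <- pessaryfit:::.exact_rc_p(tab)
    expect_equal(p_generic, p_hyper, tolerance = 1e-12)
    expect_equal(p_hyper, fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  # 2 x 3 (avulsion-shaped) tables against the standard implementation
  tab3 <- matrix(c(4, 3, 1, 1, 4, 2), 2)
  expect_equal(exact_contingency_test(tab3)$p, fisher.test(tab3)$p.value,
               tolerance = 1e-9)
})

test_that("baseline_table chooses the right test per characteristic", {
  coh <- generate_cohort(9, 6, seed = 71)
  tab <- baseline_table(coh)
  expect_true(all(tab$p > 0 & tab$p <= 1))
  expect_equal(tab$test[tab$characteristic == "Parity"], "Mann-Whitney U")
  expect_equal(tab$test[tab$characteristic == "BMI (kg/m2)"], "t-test")
  expect_equal(tab$test[tab$characteristic == "POP-Q stage 3+"],
               "exact test")
  expect_equal(nrow(tab), 9)
  expect_error(baseline_table(tiny_cohort()), "baseline")
})
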