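test_that("the trichotomous rule maps the closed middle zone to unknown", {
  expect_equal(classify_response(c(0.5, -0.3, 0.1, -0.1, 0, 0.1000001)),
               c("fitting", "non_fitting", "unknown", "unknown", "unknown",
                 "fitting"))
  expect_error(classify_response(NaN), "non-finite")
  # configurable half-width
  expect_equal(classify_response(0.3, halfwidth = 0.5), "unknown")
})

test_that("top-k selection takes the head of the ranking", {
  d <- random_design_cont(10, 6, seed = 21)
  vip <- vip_scores(fit_pls(d, 2))
  expect_identical(select_top_k(vip, 2), vip$ranking[1:2])
  expect_identical(select_top_k(vip, 6), vip$ranking)
  expect_error(select_top_k(vip, 0), "k must lie")
  expect_error(select_top_k(vip, 7), "k must lie")
})

test_that("leave-one-out produces one prediction per participant", {
  coh <- generate_cohort(9, 6, seed = 13)
  keys <- default_effect_profile()$informative_keys
  rep <- leave_one_out_cv(coh, keys)
  expect_equal(rep$tallies$n_total, 15)
  expect_identical(sort(rep$predictions$predicted_participant),
                   sort(coh$participant_id))
  expect_true(all(is.na(rep$predictions$co_held_out_participant)))
  t <- rep$tallies
  expect_equal(t$n_correct + t$n_incorrect + t$n_unknown, t$n_total)
  expect_equal(rep$accuracy_fraction, t$n_correct / t$n_total)
})

test_that("leave-two-out count identities hold for several cohort sizes", {
  for (sizes in list(c(3, 2), c(5, 5), c(9, 6))) {
    n <- sum(sizes)
    coh <- generate_cohort(sizes[1], sizes[2], seed = n)
    keys <- default_effect_profile()$informative_keys
    rep <- leave_two_out_cv(coh, keys, A = 2)
    expect_equal(rep$tallies$n_total, n * (n - 1))
    per <- table(rep$predictions$predicted_participant)
    expect_true(all(per == n - 1))
    expect_equal(sum(!is.na(rep$heatmap)), n * (n - 1))
    expect_true(all(is.na(diag(rep$heatmap))))
    t <- rep$tallies
    expect_equal(t$n_correct + t$n_incorrect + t$n_unknown, t$n_total)
  }
})

test_that("heatmap cell (i, j) is the call for i with j co-held-out", {
  coh <- generate_cohort(4, 3, seed = 17)
  keys <- default_effect_profile()$informative_keys
  rep <- leave_two_out_cv(coh, keys, A = 2)
  code <- c(fitting = 1, non_fitting = -1, unknown = 0)
  for (r in sample(nrow(rep$predictions), 10)) {
    pr <- rep$predictions[r, ]
    expect_equal(rep$heatmap[pr$predicted_participant,
                             pr$co_held_out_participant],
                 unname(code[pr$call]))
  }
})

test_that("strong separation yields near-perfect held-out accuracy", {
  prof <- default_effect_profile(standardized_effect = 3, missing_rate = 0)
  for (s in 1:10) {
    coh <- generate_cohort(50, 50, prof, seed = 700 + s)
    rep <- leave_one_out_cv(coh, prof$informative_keys, A = 2)
    expect_gte(rep$accuracy_fraction, 0.9)
  }
})

test_that("global-mode leave-one-out matches a naive fold-loop oracle bit for bit", {
  coh <- generate_cohort(5, 4, default_effect_profile(missing_rate = 0.05),
                         seed = 23)
  keys <- colnames(coh$measurements)  # k = p
  A <- 2
  rep <- leave_one_out_cv(coh, keys, A = A)
  # oracle: normalize/impute once, then loop folds by hand
  d <- build_design_matrix(coh)
  yhat <- vapply(seq_len(9), function(i) {
    f <- fit_pls(list(X = d$X[-i, , drop = FALSE], y = d$y[-i],
                      column_keys = keys), min(A, 7))
    predict(f, d$X[i, , drop = FALSE])
  }, numeric(1))
  expect_identical(rep$predictions$continuous_response, yhat)
  expect_identical(rep$predictions$call, classify_response(yhat))
})

test_that("relabelling participants permutes the heatmap but not the tallies", {
  coh <- generate_cohort(4, 3, seed = 29)
  keys <- default_effect_profile()$informative_keys
  rep1 <- leave_two_out_cv(coh, keys, A = 2)
  perm <- c(3, 1, 2, 4, 7, 5, 6)
  coh2 <- cohort_table(coh$participant_id[perm], coh$outcome[perm],
                       coh$measurements[perm, ], coh$baseline[perm, ])
  rep2 <- leave_two_out_cv(coh2, keys, A = 2)
  expect_identical(rep2$tallies, rep1$tallies)
  ids <- coh$participant_id
  expect_equal(rep2$heatmap[ids, ids], rep1$heatmap[ids, ids],
               tolerance = 1e-12)
})

test_that("the accuracy sweep covers the full k x scheme grid", {
  coh <- generate_cohort(5, 4, seed = 37)
  vip <- vip_scores(fit_pls(build_design_matrix(coh), 2))
  sw <- accuracy_sweep(coh, vip, k_range = 1:10, A = 2)
  expect_length(sw$reports, 20)
  expect_equal(nrow(sw$accuracy), 20)
  expect_named(sw$best_k, c("leave_one_out", "leave_two_out"))
  expect_true(all(sw$best_k %in% 1:10))
  # every report satisfies the partition identity
  for (r in sw$reports) {
    t <- r$tallies
    expect_equal(t$n_correct + t$n_incorrect + t$n_unknown, t$n_total)
  }
})

test_that("fold-wise normalization and nested selection run and stay valid", {
  coh <- generate_cohort(6, 5, default_effect_profile(missing_rate = 0.05),
                         seed = 41)
  keys <- default_effect_profile()$informative_keys
  rep_f <- leave_one_out_cv(coh, keys, A = 2,
                            config = list(normalization_mode = "fold"))
  expect_equal(rep_f$tallies$n_total, 11)
  rep_n <- leave_one_out_cv(coh, keys, A = 2,
                            config = list(selection_mode = "nested"))
  expect_equal(rep_n$tallies$n_total, 11)
  t <- rep_n$tallies
  expect_equal(t$n_correct + t$n_incorrect + t$n_unknown, t$n_total)
})

test_that("folds that cannot support a fit follow the degenerate-fold policy", {
  coh <- tiny_cohort(2, 3)
  # the pair holding out both fitting participants leaves one class behind:
  # by default those predictions are undecidable, hence unknown
  rep <- leave_two_out_cv(coh, colnames(coh$measurements), A = 1)
  expect_equal(rep$tallies$n_total, 20)
  deg <- is.na(rep$predictions$continuous_response)
  expect_equal(sum(deg), 2)
  expect_true(all(rep$predictions$call[deg] == "unknown"))
  t <- rep$tallies
  expect_equal(t$n_correct + t$n_incorrect + t$n_unknown, t$n_total)
  # the strict policy aborts instead
  expect_error(leave_two_out_cv(coh, colnames(coh$measurements), A = 1,
                                config = list(degenerate_fold = "error")),
               "single class")
})
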