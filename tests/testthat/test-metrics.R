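test_that("concordance matches the all-pairs oracle exactly, ties counted half", {
  expect_equal(concordance_index(c(0.2, 0.8), c(0, 1)), 1.0)
  expect_equal(concordance_index(c(0.5, 0.5), c(0, 1)), 0.5)
  set.seed(14)
  for (rep in 1:100) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))  # both classes guaranteed
    pred <- round(runif(n), sample(1:3, 1))  # coarse rounding induces ties
    expect_identical(concordance_index(pred, y), cindex_bruteforce(pred, y))
  }
  expect_error(concordance_index(c(0.1, 0.2), c(1, 1)), "single class")
})

test_that("IPA is the scaled Brier improvement over the prevalence model", {
  y <- c(0, 0, 1, 1)
  # hand computation: 1 - (4 * 0.01) / (4 * 0.25) = 96%
  expect_equal(ipa(c(0.1, 0.1, 0.9, 0.9), y), 96)
  # null model scores 0, perfect predictions score 100
  expect_equal(ipa(rep(0.5, 4), y), 0)
  expect_equal(ipa(y, y), 100)
  # invariant to sample reordering
  set.seed(3)
  yy <- rbinom(40, 1, 0.3); pp <- runif(40)
  o <- sample(40)
  expect_equal(ipa(pp, yy), ipa(pp[o], yy[o]))
  expect_error(ipa(runif(5), rep(1, 5)), "prevalence")
})

test_that("net benefit equals brute-force counting and its closed forms", {
  # worked counting example: n = 10, t = 0.10, TP = 2, FP = 3
  pred <- c(0.9, 0.8, 0.5, 0.4, 0.3, 0.05, 0.04, 0.03, 0.02, 0.01)
  y    <- c(1,   1,   0,   0,   0,   1,    0,    0,    0,    0)
  expect_equal(net_benefit(pred, y, 0.10), 0.2 - (0.1 / 0.9) * 0.3)
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(5:60, 1)
    y2 <- rbinom(n, 1, 0.3)
    p2 <- runif(n)
    t <- runif(1, 0.02, 0.3)
    expect_equal(net_benefit(p2, y2, t), net_benefit_bruteforce(p2, y2, t))
  }
  # treat-none: threshold above every prediction
  expect_equal(net_benefit(pred, y, 0.95), 0)
  # treat-all closed form: prevalence - odds * (1 - prevalence)
  t <- 0.07
  expect_equal(net_benefit(rep(1, 10), y, t),
               mean(y) - t / (1 - t) * (1 - mean(y)))
  # net benefit never exceeds prevalence
  set.seed(22)
  for (rep in 1:20) {
    y3 <- c(0, 1, rbinom(30, 1, 0.2)); p3 <- runif(32)
    expect_lte(net_benefit(p3, y3, runif(1, 0.03, 0.5)), mean(y3))
  }
})

test_that("decision curve covers the 3-10% grid with the PSA >= 3 comparator", {
  cohort <- generate_biopsy_cohort(cohort_config(n = 3616L, seed = 1L))
  m <- fit_cspca_model(cohort)
  pred <- predict_cspca_risk(m, cohort)
  y <- as.integer(cohort$outcome == "cspca")
  dc <- decision_curve(pred, y, cohort$psa)
  expect_equal(dc$threshold, seq(0.03, 0.10, by = 0.005))
  expect_true(all(dc$nb_none == 0))
  # the fitted model should dominate the blanket PSA strategy on its cohort
  expect_true(all(dc$nb_model >= dc$nb_default))
  # the model biopsies fewer men than the blanket strategy at 5%
  at5 <- dc[abs(dc$threshold - 0.05) < 1e-9, ]
  expect_gt(at5$biopsies_avoided_per_1000, 0)
  # when every PSA is above the cutoff the default strategy is treat-all
  dc2 <- decision_curve(pred, y, rep(5, length(y)))
  expect_equal(dc2$nb_default, dc2$nb_all)
})

test_that("optimism is zero for the intercept-only model", {
  cohort <- generate_biopsy_cohort(cohort_config(n = 400L, seed = 9L))
  rep0 <- bootstrap_optimism(cohort, character(0), n_boot = 50L, seed = 2L)
  expect_equal(rep0$c_index_apparent, 0.5)
  expect_equal(rep0$c_index_optimism, 0)
  expect_equal(rep0$c_index_corrected, 0.5)
})

test_that("an overfit noise model shows positive optimism", {
  # 100 men, balanced outcome, predictors carry no signal after shuffling
  set.seed(10)
  cohort <- generate_biopsy_cohort(cohort_config(n = 100L, seed = 10L,
                                                 prevalence = c(0.5, 0, 0.5)))
  cohort$outcome <- sample(cohort$outcome)
  rep1 <- bootstrap_optimism(
    cohort, c("age", "psa", "free_psa_pct", "ipss", "pv_estimate_cc"),
    n_boot = 100L, seed = 3L)
  expect_gt(rep1$c_index_optimism, 0)
  expect_lt(rep1$c_index_corrected, rep1$c_index_apparent)
})

test_that("too many degenerate resamples abort the bootstrap", {
  # a single positive case vanishes from ~36% of resamples
  cohort <- generate_biopsy_cohort(cohort_config(n = 30L, seed = 15L,
                                                 prevalence = c(1, 0, 0)))
  # plant the one case mid-distribution so the apparent fit itself is fine
  cohort$outcome[which.min(abs(cohort$age - stats::median(cohort$age)))] <- "cspca"
  expect_error(bootstrap_optimism(cohort, "age", n_boot = 50L, seed = 1L),
               "more than 10%")
})

test_that("seeded bootstrap runs are bit-reproducible", {
  cohort <- generate_biopsy_cohort(cohort_config(n = 500L, seed = 6L))
  a <- bootstrap_optimism(cohort, n_boot = 60L, seed = 123L)
  b <- bootstrap_optimism(cohort, n_boot = 60L, seed = 123L)
  expect_identical(a, b)
  expect_identical(a$c_index_corrected, a$c_index_apparent - a$c_index_optimism)
})

test_that("corrected concordance approximates held-out discrimination", {
  train <- generate_biopsy_cohort(cohort_config(n = 2500L, seed = 30L))
  test <- generate_biopsy_cohort(cohort_config(n = 8000L, seed = 31L))
  rep2 <- bootstrap_optimism(train, n_boot = 200L, seed = 4L)
  m <- fit_cspca_model(train)
  c_holdout <- concordance_index(predict_cspca_risk(m, test),
                                 as.integer(test$outcome == "cspca"))
  expect_lt(abs(rep2$c_index_corrected - c_holdout), 0.02)
})

test_that("concordance agrees with the survival package's estimate", {
  set.seed(77)
  y <- rbinom(300, 1, 0.2)
  pred <- runif(300) + 0.3 * y
  ext <- survival::concordance(y ~ pred)$concordance
  expect_equal(concordance_index(pred, y), ext, tolerance = 1e-12)
})
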