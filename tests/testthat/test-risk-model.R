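make_model <- function(beta = c(age = 0, psa = 0, free_psa_pct = 0),
                       intercept = 0,
                       centering = list(psa = 2.0, free_psa_pct = log2(0.2))) {
  m <- fit_cspca_model(generate_biopsy_cohort(cohort_config(n = 400L, seed = 3L)))
  m$coefficients <- as.list(beta[m$predictor_set])
  m$intercept <- intercept
  m$centering <- centering[intersect(names(centering), m$predictor_set)]
  m
}

test_that("log2-centred transforms hit hand-computed values", {
  m <- make_model()
  p <- patient_profile(age = 65, psa = 4.0, free_psa_pct = 0.2)
  x <- transform_predictors(p, m)
  expect_named(x, c("age", "psa", "free_psa_pct"))
  # PSA at the centering reference maps to 0
  expect_equal(unname(x["psa"]), log2(4.0) - 2.0)
  expect_equal(unname(x["psa"]), 0)
  # median significant-cancer PSA: log2(7.8) - 2 ~ 0.9635
  p2 <- patient_profile(age = 65, psa = 7.8, free_psa_pct = 0.2)
  expect_equal(unname(transform_predictors(p2, m)["psa"]), 0.9635,
               tolerance = 1e-4)
  # empty centering gives raw log2 values
  m0 <- make_model(centering = list())
  expect_equal(unname(transform_predictors(p, m0)["psa"]), log2(4.0))
})

test_that("missing or out-of-domain predictors give named errors", {
  m <- make_model()
  p <- patient_profile(age = 65, psa = 4, free_psa_pct = 0.2)
  p$free_psa_pct <- NULL
  expect_error(transform_predictors(p, m), "predictor unavailable: free_psa_pct")
  p2 <- patient_profile(age = 65, psa = 4, free_psa_pct = 0.2)
  p2$psa <- -1
  expect_error(transform_predictors(p2, m), "psa must be positive")
  expect_error(patient_profile(age = 65, psa = 0, free_psa_pct = 0.2),
               "psa must be a positive")
  expect_error(patient_profile(age = 65, psa = 4, free_psa_pct = 1.7),
               "ratio in \\(0, 1\\]")
})

test_that("null-signal cohorts give near-zero slopes and chance discrimination", {
  set.seed(8)
  cohort <- generate_biopsy_cohort(cohort_config(n = 2000L, seed = 8L))
  cohort$outcome <- sample(cohort$outcome)  # break the association
  m <- fit_cspca_model(cohort)
  # slopes within sampling noise of zero (bounds ~4 standard errors)
  expect_lt(abs(m$coefficients$age), 0.05)
  expect_lt(abs(m$coefficients$psa), 0.4)
  expect_lt(abs(m$coefficients$free_psa_pct), 0.5)
  # and the model discriminates no better than chance
  cidx <- concordance_index(predict_cspca_risk(m, cohort),
                            as.integer(cohort$outcome == "cspca"))
  expect_lt(abs(cidx - 0.5), 0.08)  # apparent c is mildly optimism-inflated
  # intercept-only fit encodes exactly the prevalence
  m0 <- fit_cspca_model(cohort, character(0))
  expect_equal(stats::plogis(m0$intercept), mean(cohort$outcome == "cspca"),
               tolerance = 1e-6)
})

test_that("known logistic coefficients are recovered at full cohort size", {
  beta <- c(age = 0.06, psa = 1.0, free_psa_pct = -1.4)
  intercept <- -7.0
  cohort <- generate_logistic_cohort(3616L, beta, intercept, seed = 17L)
  m <- fit_cspca_model(cohort, names(beta))
  # refit with the generator's own centering for comparability of slopes
  fit <- stats::glm(I(outcome == "cspca") ~ I(age) + I(log2(psa) - log2(4.5)) +
                      I(log2(free_psa_pct) - log2(0.20)),
                    family = binomial(), data = cohort)
  se <- sqrt(diag(vcov(fit)))[-1]
  expect_lt(abs(m$coefficients$age - beta["age"]) / se[1], 3)
  expect_lt(abs(m$coefficients$psa - beta["psa"]) / se[2], 3)
  expect_lt(abs(m$coefficients$free_psa_pct - beta["free_psa_pct"]) / se[3], 3)
})

test_that("mean predicted risk equals observed prevalence (score equation)", {
  cohort <- generate_biopsy_cohort(cohort_config(n = 3616L, seed = 1L))
  m <- fit_cspca_model(cohort)
  pred <- predict_cspca_risk(m, cohort)
  expect_equal(mean(pred), mean(cohort$outcome == "cspca"), tolerance = 1e-6)
  # default synthetic cohort encodes roughly the 9% significant-cancer rate
  expect_lt(abs(mean(pred) - 0.09), 0.015)
  expect_true(all(pred > 0 & pred < 1))
})

test_that("prediction is the inverse-logit of the linear predictor", {
  m <- make_model()
  p <- patient_profile(age = 65, psa = 4.0, free_psa_pct = 0.17)
  # all-zero model
  expect_equal(predict_cspca_risk(m, p), 0.5)
  # prevalence-only model
  m2 <- make_model(intercept = stats::qlogis(0.09))
  expect_equal(predict_cspca_risk(m2, p), 0.09)
  # fixed printed coefficients vs independent hand evaluation of expit(b.x)
  m3 <- make_model(beta = c(age = 0.05, psa = 1.1, free_psa_pct = -1.5),
                   intercept = -6.2)
  lp <- -6.2 + 0.05 * 65 + 1.1 * (log2(4.0) - 2.0) +
    (-1.5) * (log2(0.17) - log2(0.2))
  expect_equal(predict_cspca_risk(m3, p), 1 / (1 + exp(-lp)))
})

test_that("risk is strictly increasing in PSA when its coefficient is positive", {
  cohort <- generate_biopsy_cohort(cohort_config(n = 3616L, seed = 1L))
  m <- fit_cspca_model(cohort)
  expect_gt(m$coefficients$psa, 0)
  psa_grid <- seq(1, 30, by = 0.5)
  risks <- vapply(psa_grid, function(s) {
    predict_cspca_risk(m, patient_profile(age = 65, psa = s, free_psa_pct = 0.17))
  }, numeric(1))
  expect_true(all(diff(risks) > 0))
})

test_that("refitting is deterministic and collapse order does not matter", {
  cohort <- generate_biopsy_cohort(cohort_config(n = 1000L, seed = 4L))
  m1 <- fit_cspca_model(cohort)
  m2 <- fit_cspca_model(cohort)
  expect_identical(m1$coefficients, m2$coefficients)
  # pre-collapsing indolent into the negative class changes nothing
  pre <- cohort
  pre$outcome[pre$outcome == "indolent_pca"] <- "no_pca"
  m3 <- fit_cspca_model(pre)
  expect_equal(unlist(m1$coefficients), unlist(m3$coefficients))
  expect_equal(m1$intercept, m3$intercept)
})

test_that("perfect separation is reported with the offending predictor", {
  cohort <- generate_biopsy_cohort(cohort_config(n = 300L, seed = 5L))
  cohort$psa <- ifelse(cohort$outcome == "cspca", 50 + cohort$psa, cohort$psa)
  expect_error(fit_cspca_model(cohort), "separation")
  single <- cohort
  single$outcome <- "no_pca"
  expect_error(fit_cspca_model(single), "both significant-cancer and negative")
})
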