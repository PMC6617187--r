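test_that("weibull mean matches closed form and quadrature across parameters", {
  # exponential special case
  expect_equal(weibull_mean(weibull_survival(1, 10)), 10.0)
  # Gamma-function value, checked against numerical integration
  expect_equal(weibull_mean(weibull_survival(2, 10)), 10 * gamma(1.5))
  expect_equal(weibull_mean(weibull_survival(2, 10)),
               weibull_mean_quadrature(2, 10), tolerance = 1e-8)
  for (k in c(0.5, 0.8, 1.4, 2.5, 5)) {
    for (lam in c(1, 8, 20, 50)) {
      expect_equal(weibull_mean(weibull_survival(k, lam)),
                   weibull_mean_quadrature(k, lam),
                   tolerance = 1e-6, label = sprintf("k=%g lambda=%g", k, lam))
    }
  }
})

test_that("restricted mean is below the unrestricted mean and equals quadrature", {
  w <- weibull_survival(1.4, 13.5)
  rm25 <- weibull_mean(w, restrict_years = 25)
  expect_lt(rm25, weibull_mean(w))
  expect_equal(rm25, stats::integrate(function(t) surv_prob(w, t), 0, 25)$value,
               tolerance = 1e-6)
})

test_that("fitting survival points inverts exact Weibull tabulations", {
  w <- weibull_survival(1.4, 13.5)
  fit <- fit_weibull_to_points(tabulate_survival(w, 1:20))
  expect_equal(fit$shape, 1.4, tolerance = 1e-9)
  expect_equal(fit$scale, 13.5, tolerance = 1e-9)
  # exponential input recovers slope 1
  fit_e <- fit_weibull_to_points(tabulate_survival(weibull_survival(1, 12), 1:15))
  expect_equal(fit_e$shape, 1, tolerance = 1e-9)
  # round trip through refit_weibull is the identity on Weibull input
  fit_r <- refit_weibull(function(t) surv_prob(w, t), times = 2:14)
  expect_equal(fit_r$shape, w$shape, tolerance = 1e-9)
})

test_that("fitting tolerates modest multiplicative noise in the points", {
  set.seed(42)
  w <- weibull_survival(1.4, 13.5)
  errs <- replicate(40, {
    pts <- tabulate_survival(w, seq(2, 14, length.out = 8))
    pts$survival <- pmin(pts$survival * exp(rnorm(8, 0, 0.01)), 0.999)
    pts$survival <- cummin(pts$survival)  # restore monotonicity if noise broke it
    abs(fit_weibull_to_points(pts)$shape - 1.4)
  })
  # 1% noise typically perturbs the recovered shape by well under 0.1
  expect_lt(median(errs), 0.1)
  expect_lt(max(errs), 0.3)
})

test_that("degenerate survival points are rejected with informative errors", {
  expect_error(fit_weibull_to_points(data.frame(t_years = 1, survival = 0.9)),
               "at least 2")
  expect_error(fit_weibull_to_points(data.frame(t_years = c(1, 2),
                                                survival = c(1, 0.5))),
               "strictly in")
  expect_error(fit_weibull_to_points(data.frame(t_years = c(1, 2),
                                                survival = c(0.5, 0.9))),
               "nonincreasing")
})

test_that("Gleason mixture is the weighted survival average with correct bounds", {
  c57 <- weibull_survival(1, 15)
  c810 <- weibull_survival(1, 5)
  gw <- gleason_weights(source = c(`5-7` = 0.75, `8-10` = 0.25),
                        target = c(`5-7` = 0.5, `8-10` = 0.5))
  mix <- gleason_mixture_adjust(list(`5-7` = c57, `8-10` = c810), gw)
  # hand value at t = 5 for equal weights on exponentials 15 and 5
  expect_equal(mix(5), (exp(-1) + exp(-1 / 3)) / 2)
  # pointwise between the component curves
  tt <- seq(0.5, 30, by = 0.5)
  expect_true(all(mix(tt) <= surv_prob(c57, tt) + 1e-12))
  expect_true(all(mix(tt) >= surv_prob(c810, tt) - 1e-12))
  # mixture mean lies between the component means (convexity)
  m <- weibull_mean_quadrature_fn(mix)
  expect_gt(m, weibull_mean(c810))
  expect_lt(m, weibull_mean(c57))
  # all weight on one band returns that band exactly
  gw1 <- gleason_weights(source = c(`5-7` = 0.75, `8-10` = 0.25),
                         target = c(`5-7` = 1, `8-10` = 0))
  mix1 <- gleason_mixture_adjust(list(`5-7` = c57, `8-10` = c810), gw1)
  expect_equal(mix1(tt), surv_prob(c57, tt))
})

test_that("Gleason weights validate band coverage and sums", {
  expect_error(gleason_weights(c(`5-7` = 0.6, `8-10` = 0.5),
                               c(`5-7` = 0.5, `8-10` = 0.5)), "sum to 1")
  expect_error(gleason_weights(c(`5-7` = 0.5, `8-10` = 0.5),
                               c(a = 0.5, b = 0.5)), "same Gleason bands")
  c1 <- weibull_survival(1, 10)
  gw <- gleason_weights(c(`5-7` = 0.5, `8-10` = 0.5),
                        c(`5-7` = 0.5, `8-10` = 0.5))
  expect_error(gleason_mixture_adjust(list(x = c1, y = c1), gw), "do not match")
})

test_that("screening-era adjustment acts on the cancer-specific hazard only", {
  # exponential components: other-cause 0.02, cancer 0.05
  other <- weibull_survival(1, 1 / 0.02)
  overall <- weibull_survival(1, 1 / 0.07)
  adj <- psa_era_adjust(overall, other, rel_effect = 0.79)
  tt <- c(1, 5, 10, 20)
  expect_equal(adj(tt), exp(-(0.02 + 0.79 * 0.05) * tt), tolerance = 1e-12)
  # rel_effect = 1 leaves the curve unchanged
  id <- psa_era_adjust(overall, other, rel_effect = 1)
  expect_equal(id(tt), surv_prob(overall, tt))
  # adjusted survival dominates the original whenever the effect is < 1
  expect_true(all(adj(tt) >= surv_prob(overall, tt)))
  # decomposition failure (other-cause below overall) is a data error
  expect_error(psa_era_adjust(other, overall), "must be >=")
})

test_that("relative-mortality application is a proportional-hazards rescaling", {
  # exponential closed form
  w <- weibull_survival(1, 20)
  expect_equal(apply_relative_mortality(w, 1.6)$scale, 12.5)
  # identity at ratio 1, power identity S' = S^ratio, multiplicativity
  w2 <- weibull_survival(1.4, 13)
  expect_equal(apply_relative_mortality(w2, 1), w2)
  tt <- seq(0.5, 40, by = 0.5)
  expect_equal(surv_prob(apply_relative_mortality(w2, 1.6), tt),
               surv_prob(w2, tt)^1.6, tolerance = 1e-12)
  ab <- apply_relative_mortality(apply_relative_mortality(w2, 1.3), 1.2)
  expect_equal(ab$scale, apply_relative_mortality(w2, 1.3 * 1.2)$scale,
               tolerance = 1e-12)
  expect_lt(weibull_mean(apply_relative_mortality(w2, 1.6)), weibull_mean(w2))
})
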