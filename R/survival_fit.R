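#' @importFrom survival survreg Surv
NULL

charlson_levels <- c("0", "1", "2+")

# normalise the comorbidity column to the three-level factor used everywhere
as_charlson <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("2", "3", "4", "5")] <- "2+"
  bad <- !is.na(x) & !(x %in% charlson_levels)
  if (any(bad)) {
    stop("invalid Charlson category: ", paste(unique(x[bad]), collapse = ", "),
         " (expected 0, 1 or 2+)")
  }
  factor(x, levels = charlson_levels)
}

check_survival_cohort <- function(cohort) {
  need <- c("age", "charlson", "follow_up_months", "status")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("survival cohort lacks columns: ", paste(miss, collapse = ", "))
  if (any(cohort$follow_up_months < 0, na.rm = TRUE)) stop("follow-up must be nonnegative")
  st <- trimws(as.character(cohort$status))
  if (!all(st %in% c("dead", "alive"))) stop("status must be 'dead' or 'alive'")
  cohort$status <- st
  cohort$charlson <- as_charlson(cohort$charlson)
  cohort
}

#' Weibull accelerated-failure-time model for survival without significant cancer
#'
#' Fits a censored-maximum-likelihood Weibull regression of overall
#' survival on age and Charlson comorbidity (accelerated-failure-time
#' parameterisation: log scale linear in covariates, common shape), via
#' [survival::survreg()]. Age is centred at 65 so the intercept is the log
#' scale of a 65-year-old with Charlson 0. Follow-up is supplied in months
#' and converted to years internally.
#'
#' @param cohort data frame with columns `age` (years), `charlson`
#'   (`"0"`, `"1"`, `"2+"`), `follow_up_months` (>= 0) and `status`
#'   (`"dead"`/`"alive"`). Rows with zero follow-up are dropped (they carry
#'   no information for a continuous-time likelihood).
#' @return An object of class `weibull_le_model`: `shape`, `coefficients`
#'   (`intercept`, `age` per year from 65, `charlson1`, `charlson2plus`),
#'   standard errors, `n`, `n_deaths` and the underlying `survreg` fit.
#' @seealso [predict_le_curve()] to obtain the per-profile curve.
#' @export
fit_weibull_regression <- function(cohort) {
  cohort <- check_survival_cohort(cohort)
  keep <- cohort$follow_up_months > 0
  cohort <- cohort[keep, , drop = FALSE]
  dead <- cohort$status == "dead"
  if (!any(dead)) stop("no deaths in cohort: Weibull scale is not identifiable")
  years <- cohort$follow_up_months / 12
  age_c <- cohort$age - 65
  ch <- cohort$charlson
  fit <- survival::survreg(
    survival::Surv(years, dead) ~ age_c + ch,
    dist = "weibull", control = survival::survreg.control(maxiter = 100))
  if (is.null(fit$coefficients) || any(!is.finite(fit$coefficients))) {
    stop("Weibull regression failed to converge (", fit$iter, " iterations)")
  }
  cf <- fit$coefficients
  se <- sqrt(diag(fit$var))[seq_along(cf)]
  out <- list(
    shape = 1 / fit$scale,
    coefficients = c(intercept = unname(cf[["(Intercept)"]]),
                     age = unname(cf[["age_c"]]),
                     charlson1 = unname(cf[["ch1"]]),
                     charlson2plus = unname(cf[["ch2+"]])),
    se = c(intercept = unname(se[1L]), age = unname(se[2L]),
           charlson1 = unname(se[3L]), charlson2plus = unname(se[4L])),
    n = nrow(cohort), n_deaths = sum(dead), fit = fit)
  class(out) <- "weibull_le_model"
  out
}

#' @export
print.weibull_le_model <- function(x, ...) {
  cat(sprintf("Weibull AFT life-expectancy model (n = %d, deaths = %d)\n",
              x$n, x$n_deaths))
  cat(sprintf("  shape %.3f; log-scale: %.3f %+.4f*(age-65) %+.3f*[Ch1] %+.3f*[Ch2+]\n",
              x$shape, x$coefficients["intercept"], x$coefficients["age"],
              x$coefficients["charlson1"], x$coefficients["charlson2plus"]))
  invisible(x)
}

#' Survival curve implied by a fitted life-expectancy model for one profile
#'
#' @param model a `weibull_le_model` from [fit_weibull_regression()], or
#'   the equivalent coefficient list loaded from JSON.
#' @param age age in years.
#' @param charlson Charlson category `"0"`, `"1"` or `"2+"`.
#' @return A [weibull_survival()] object.
#' @export
predict_le_curve <- function(model, age, charlson) {
  cf <- model$coefficients
  charlson <- as.character(as_charlson(charlson))
  lp <- cf[["intercept"]] + cf[["age"]] * (age - 65) +
    (charlson == "1") * cf[["charlson1"]] +
    (charlson == "2+") * cf[["charlson2plus"]]
  weibull_survival(shape = model$shape, scale = exp(lp))
}

#' Expected deaths under a life table along observed follow-up
#'
#' Accumulates the life-table hazard along each man's follow-up, advancing
#' attained age annually and pro-rating the fractional final year. The
#' result is the number of deaths the reference population would have
#' experienced over the cohort's person-time.
#'
#' @param age_at_entry vector of entry ages (years).
#' @param follow_up_years vector of follow-up durations (years, >= 0).
#' @param life_table data frame with columns `age` (contiguous integers)
#'   and `hazard` (annual mortality rate, > 0).
#' @return Vector of expected deaths (cumulative hazards), one per person.
#' @export
expected_deaths_lifetable <- function(age_at_entry, follow_up_years, life_table) {
  stopifnot(length(age_at_entry) == length(follow_up_years),
            all(follow_up_years >= 0))
  lt_age <- life_table$age
  if (any(diff(lt_age) != 1L)) stop("life-table ages must be contiguous")
  if (any(life_table$hazard <= 0)) stop("life-table hazards must be positive")
  haz <- life_table$hazard
  get_h <- function(a) {
    i <- pmin(pmax(floor(a) - lt_age[1L] + 1L, 1L), length(haz))
    if (any(floor(a) > lt_age[length(lt_age)]) || any(floor(a) < lt_age[1L])) {
      stop("life table does not cover ages ",
           paste(range(floor(a)), collapse = "-"))
    }
    haz[i]
  }
  vapply(seq_along(age_at_entry), function(i) {
    fu <- follow_up_years[i]
    if (fu == 0) return(0)
    full <- floor(fu)
    ages <- age_at_entry[i] + seq_len(full) - 1
    e <- if (full > 0) sum(get_h(ages)) else 0
    frac <- fu - full
    if (frac > 0) e <- e + frac * get_h(age_at_entry[i] + full)
    e
  }, numeric(1))
}

#' Healthy-screenee relative mortality against a life table
#'
#' Screening-trial participants are on average healthier than the
#' population a life table describes. The correction is estimated by a
#' Poisson regression of observed deaths with the log of life-table
#' expected deaths as offset, adjusted for age (centred at the cohort
#' mean) and Charlson category. The returned ratio is
#' reference-population over cohort mortality at the adjustment reference
#' (mean age, Charlson 0): a value of 1.6 means the general population
#' dies at 1.6 times the cohort's rate, and [apply_relative_mortality()]
#' with that ratio generalises a cohort-fitted curve to the population.
#'
#' @param cohort survival cohort data frame (see
#'   [fit_weibull_regression()] for the schema).
#' @param life_table life-table data frame (`age`, `hazard`).
#' @return An object of class `relative_mortality`: `ratio`
#'   (reference/cohort), `smr` (observed/expected, unadjusted), `observed`,
#'   `expected` and the Poisson `fit`.
#' @export
fit_relative_mortality <- function(cohort, life_table) {
  cohort <- check_survival_cohort(cohort)
  fu_years <- cohort$follow_up_months / 12
  expected <- expected_deaths_lifetable(cohort$age, fu_years, life_table)
  keep <- expected > 0
  if (!any(keep)) stop("expected deaths are zero for every subject; check the life table")
  d <- data.frame(dead = as.integer(cohort$status == "dead"),
                  age_c = cohort$age - mean(cohort$age),
                  charlson = cohort$charlson,
                  loge = log(expected))[keep, , drop = FALSE]
  fit <- stats::glm(dead ~ age_c + charlson + offset(loge),
                    family = stats::poisson(), data = d)
  smr_adj <- exp(unname(stats::coef(fit)[["(Intercept)"]]))
  out <- list(ratio = 1 / smr_adj,
              smr = sum(d$dead) / sum(exp(d$loge)),
              observed = sum(d$dead), expected = sum(exp(d$loge)),
              fit = fit)
  class(out) <- "relative_mortality"
  out
}

#' @export
print.relative_mortality <- function(x, ...) {
  cat(sprintf(paste0("Relative mortality (reference / cohort): %.3f\n",
                     "  observed deaths %d, life-table expected %.1f (SMR %.3f)\n"),
              x$ratio, x$observed, x$expected, 1 / x$ratio))
  invisible(x)
}

#' Impute missing Charlson categories by predictive mean matching
#'
#' Single-pass predictive mean matching: the numeric Charlson score
#' (0, 1, 2) is regressed on age and vital status among complete records;
#' each record with a missing value receives the observed category of a
#' donor drawn uniformly from the `k` complete records with the nearest
#' predicted mean. Imputed values therefore always lie in the observed
#' support. The draw uses the current RNG state; set a seed for
#' reproducibility.
#'
#' @param cohort survival cohort data frame; `charlson` may contain `NA`.
#' @param k donor-pool size (default 5).
#' @return The cohort with `charlson` completed.
#' @export
impute_charlson <- function(cohort, k = 5L) {
  need <- c("age", "status", "charlson")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  ch_chr <- trimws(as.character(cohort$charlson))
  ch_chr[ch_chr %in% c("", "NA")] <- NA
  is_miss <- is.na(ch_chr)
  if (!any(is_miss)) return(cohort)
  if (all(is_miss)) stop("all Charlson values are missing; nothing to match on")
  complete <- which(!is_miss)
  if (length(complete) < 10L) stop("need at least 10 complete records for matching")
  score <- c("0" = 0, "1" = 1, "2+" = 2)[ch_chr]
  dead <- as.integer(trimws(as.character(cohort$status)) == "dead")
  X <- cbind(1, cohort$age, dead)
  fit <- stats::lm.fit(X[complete, , drop = FALSE], score[complete])
  pred <- as.numeric(X %*% fit$coefficients)
  kk <- min(k, length(complete))
  donors <- vapply(which(is_miss), function(i) {
    d <- abs(pred[complete] - pred[i])
    pool <- complete[order(d)[seq_len(kk)]]
    pool[sample.int(kk, 1L)]
  }, integer(1))
  ch_chr[is_miss] <- ch_chr[donors]
  cohort$charlson <- ch_chr
  cohort
}
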