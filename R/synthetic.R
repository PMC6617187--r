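age_band_levels <- c("55-59", "60-64", "65-69", "70-74", "75+")

#' Age band of the survival strata
#'
#' @param age age in years.
#' @return One of `"55-59"`, `"60-64"`, `"65-69"`, `"70-74"`, `"75+"`.
#' @export
age_band <- function(age) {
  stopifnot(is.numeric(age), all(age >= 0))
  cut(age, breaks = c(-Inf, 59, 64, 69, 74, Inf), labels = age_band_levels,
      right = TRUE)
}

# log-normal sigma implied by a printed median and IQR
sigma_from_iqr <- function(q25, q75) log(q75 / q25) / (2 * stats::qnorm(0.75))

#' Configuration of the synthetic biopsy-cohort generator
#'
#' The defaults reproduce the marginal structure of a first-screening-round
#' sextant-biopsy cohort: outcome prevalences 75% no cancer, 16% indolent
#' (ISUP 1), 9% clinically significant (ISUP >= 2); per-outcome log-normal
#' PSA with medians 4.0 / 5.1 / 7.8 ng/mL and spreads matched to the
#' printed interquartile ranges; %freePSA medians 0.22 / 0.17 / 0.12; ages
#' centred at 66 / 67 / 68 years (truncated to 55-75); abnormal-DRE rates
#' 31% / 41% / 66%. The prostate-volume category probabilities, family
#' history and IPSS spreads are likewise per outcome; the Charlson mix
#' (60/25/15%) is drawn independently of outcome.
#'
#' @param n cohort size (default 3616).
#' @param seed integer seed.
#' @param prevalence outcome prevalences, in the order no cancer /
#'   indolent / significant, summing to 1.
#' @return An object of class `cohort_config` (a list of sampling
#'   parameters, overridable element-wise).
#' @export
cohort_config <- function(n = 3616L, seed = 1L,
                          prevalence = c(no_pca = 0.75, indolent_pca = 0.16,
                                         cspca = 0.09)) {
  if (length(prevalence) != 3L || any(prevalence < 0) ||
      abs(sum(prevalence) - 1) > 1e-9) {
    stop("prevalence must be three nonnegative proportions summing to 1")
  }
  names(prevalence) <- outcome_levels
  structure(list(
    n = as.integer(n), seed = as.integer(seed), prevalence = prevalence,
    psa_median = c(no_pca = 4.0, indolent_pca = 5.1, cspca = 7.8),
    psa_sigma = c(no_pca = sigma_from_iqr(2.5, 5.7),
                  indolent_pca = sigma_from_iqr(3.7, 7.4),
                  cspca = sigma_from_iqr(4.8, 16.0)),
    fpsa_median = c(no_pca = 0.22, indolent_pca = 0.17, cspca = 0.12),
    fpsa_sigma = c(no_pca = sigma_from_iqr(0.17, 0.28),
                   indolent_pca = sigma_from_iqr(0.12, 0.24),
                   cspca = sigma_from_iqr(0.08, 0.17)),
    age_mean = c(no_pca = 66, indolent_pca = 67, cspca = 68),
    age_sd = c(no_pca = (70 - 60) / (2 * stats::qnorm(0.75)),
               indolent_pca = (70 - 61) / (2 * stats::qnorm(0.75)),
               cspca = (71 - 64) / (2 * stats::qnorm(0.75))),
    age_range = c(55, 75),
    dre_rate = c(no_pca = 0.31, indolent_pca = 0.41, cspca = 0.66),
    # volume category over {25, 40, 60} cc; cancers sit in smaller glands
    pv_probs = list(no_pca = c(0.25, 0.45, 0.30),
                    indolent_pca = c(0.35, 0.45, 0.20),
                    cspca = c(0.35, 0.45, 0.20)),
    fh_rate = c(no_pca = 0.08, indolent_pca = 0.11, cspca = 0.10),
    ipss_median = c(no_pca = 5, indolent_pca = 4, cspca = 4),
    ipss_sigma = c(no_pca = sigma_from_iqr(2, 11),
                   indolent_pca = sigma_from_iqr(1, 9),
                   cspca = sigma_from_iqr(1, 10)),
    charlson_probs = c(`0` = 0.60, `1` = 0.25, `2+` = 0.15)),
    class = "cohort_config")
}

rlnorm_med <- function(n, median, sigma) {
  stats::rlnorm(n, meanlog = log(median), sdlog = sigma)
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lo | x > hi
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lo | x > hi
  }
  x
}

#' Generate a synthetic biopsy cohort
#'
#' Draws the outcome by prevalence and every covariate from its
#' outcome-conditional distribution (see [cohort_config()]). The induced
#' outcome-covariate association is what a logistic risk model exploits;
#' the generator makes no structural (causal) claim. Deterministic under
#' the config seed.
#'
#' @param config a [cohort_config()].
#' @return Data frame with columns `age`, `psa`, `free_psa_pct`,
#'   `dre_abnormal`, `pv_estimate_cc`, `family_history`, `ipss`,
#'   `charlson`, `outcome`.
#' @export
generate_biopsy_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n
  outcome <- sample(outcome_levels, n, replace = TRUE, prob = config$prevalence)
  age <- psa <- fpsa <- ipss <- numeric(n)
  dre <- fh <- logical(n)
  pv <- integer(n)
  for (g in outcome_levels) {
    i <- which(outcome == g)
    if (!length(i)) next
    m <- length(i)
    age[i] <- round(rtruncnorm(m, config$age_mean[[g]], config$age_sd[[g]],
                               config$age_range[1L], config$age_range[2L]))
    psa[i] <- round(rlnorm_med(m, config$psa_median[[g]], config$psa_sigma[[g]]), 2)
    fpsa[i] <- round(pmin(rlnorm_med(m, config$fpsa_median[[g]],
                                     config$fpsa_sigma[[g]]), 0.99), 3)
    dre[i] <- stats::runif(m) < config$dre_rate[[g]]
    pv[i] <- sample(c(25L, 40L, 60L), m, replace = TRUE, prob = config$pv_probs[[g]])
    fh[i] <- stats::runif(m) < config$fh_rate[[g]]
    ipss[i] <- pmin(round(rlnorm_med(m, config$ipss_median[[g]],
                                     config$ipss_sigma[[g]])), 35)
  }
  charlson <- sample(names(config$charlson_probs), n, replace = TRUE,
                     prob = config$charlson_probs)
  data.frame(age = age, psa = pmax(psa, 0.1), free_psa_pct = pmax(fpsa, 0.01),
             dre_abnormal = dre, pv_estimate_cc = pv, family_history = fh,
             ipss = ipss, charlson = charlson, outcome = outcome,
             stringsAsFactors = FALSE)
}

#' Generate a biopsy cohort with a known logistic outcome mechanism
#'
#' Covariates are drawn from the pooled marginal mixture of
#' [generate_biopsy_cohort()]; the significant-cancer indicator is then
#' drawn from a Bernoulli whose logit is linear in the transformed
#' predictors with user-supplied coefficients. Used for parameter-recovery
#' checks of the fitting path (the fitted model should recover `beta`
#' within sampling error).
#'
#' @param n cohort size.
#' @param beta named coefficients on the model (log2-centred) scale;
#'   names from `age`, `psa`, `free_psa_pct`, `dre_abnormal`,
#'   `pv_estimate_cc`, `family_history`, `ipss`.
#' @param intercept intercept on the logit scale.
#' @param centering named centering constants for the log2 predictors
#'   (defaults: log2 of the pooled medians).
#' @param seed integer seed.
#' @return Biopsy-cohort data frame; indolent cases are not generated
#'   (negatives are labelled `no_pca`). Attribute `"linear_predictor"`
#'   carries the true logits.
#' @export
generate_logistic_cohort <- function(n, beta, intercept,
                                     centering = c(psa = log2(4.5),
                                                   free_psa_pct = log2(0.20),
                                                   pv_estimate_cc = log2(40)),
                                     seed = 1L) {
  stopifnot(all(names(beta) %in% known_predictors))
  cfg <- cohort_config(n = n, seed = seed)
  cov <- generate_biopsy_cohort(cfg)
  lp <- rep(intercept, n)
  for (nm in names(beta)) {
    v <- cov[[nm]]
    x <- if (nm %in% log2_predictors) {
      log2(v) - centering[[nm]]
    } else if (nm %in% binary_predictors) as.numeric(v) else as.numeric(v)
    lp <- lp + beta[[nm]] * x
  }
  y <- stats::runif(n) < stats::plogis(lp)
  cov$outcome <- ifelse(y, "cspca", "no_pca")
  attr(cov, "linear_predictor") <- lp
  cov
}

#' Generate a synthetic survival cohort
#'
#' Event times are Weibull in an accelerated-failure-time structure: log
#' scale = `intercept` + `beta_age` (age - 65) + Charlson effects, common
#' `shape`; censoring is administrative, uniform over `censor_months`
#' (a single value gives a fixed horizon). The defaults (shape 1.6,
#' intercept 3.4357, age effect -0.035/y, Charlson effects -0.20 / -0.45,
#' ages uniform 55-75, censoring 168-240 months) are calibrated so the
#' default cohort shows a 10-year overall survival near 81%, about 38%
#' deaths, and a median follow-up near 15 years — the margins of the
#' screening cohort the life-expectancy model emulates.
#'
#' @param n cohort size (default 19247, the post-exclusion size of that
#'   cohort).
#' @param seed integer seed.
#' @param shape Weibull shape.
#' @param intercept,beta_age,beta_charlson1,beta_charlson2 log-scale
#'   (years) regression coefficients.
#' @param censor_months censoring window in months, `c(low, high)` or a
#'   single horizon.
#' @param charlson_probs Charlson category mix.
#' @return Data frame with columns `age`, `charlson`, `follow_up_months`,
#'   `status`.
#' @export
generate_survival_cohort <- function(n = 19247L, seed = 1L, shape = 1.6,
                                     intercept = 3.4357, beta_age = -0.035,
                                     beta_charlson1 = -0.20,
                                     beta_charlson2 = -0.45,
                                     censor_months = c(168, 240),
                                     charlson_probs = c(`0` = 0.60, `1` = 0.25,
                                                        `2+` = 0.15)) {
  stopifnot(n >= 1L, shape > 0, all(censor_months >= 0))
  if (length(censor_months) == 1L) censor_months <- rep(censor_months, 2L)
  set.seed(as.integer(seed))
  age <- stats::runif(n, 55, 75)
  charlson <- sample(names(charlson_probs), n, replace = TRUE,
                     prob = charlson_probs)
  lp <- intercept + beta_age * (age - 65) +
    beta_charlson1 * (charlson == "1") + beta_charlson2 * (charlson == "2+")
  event_y <- stats::rweibull(n, shape = shape, scale = exp(lp))
  censor_y <- stats::runif(n, censor_months[1L], censor_months[2L]) / 12
  fu <- pmin(event_y, censor_y)
  data.frame(age = round(age, 1),
             charlson = charlson,
             follow_up_months = round(fu * 12, 1),
             status = ifelse(event_y <= censor_y, "dead", "alive"),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic (Gompertz) life table
#'
#' Annual mortality hazards \eqn{h(a) = \alpha e^{\beta a}}, a standard
#' description of adult all-cause mortality, as a stand-in for a national
#' life table. The default level is set so the table describes a general
#' population about 1.6 times as mortal as the default synthetic
#' screening cohort — the healthy-screenee contrast the correction
#' machinery is meant to estimate.
#'
#' @param ages integer ages covered (default 50-104).
#' @param alpha Gompertz level (default 4.85e-5).
#' @param beta Gompertz slope per year of age (default 0.09).
#' @return Data frame with columns `age`, `hazard`; hazards strictly
#'   increase with age.
#' @export
generate_life_table <- function(ages = 50:104, alpha = 4.85e-5, beta = 0.09) {
  stopifnot(alpha > 0, beta > 0, all(diff(ages) == 1L))
  data.frame(age = as.integer(ages), hazard = alpha * exp(beta * ages))
}

default_le_targets <- function() {
  # untreated-significant-cancer life expectancy (years) by age band and
  # Charlson; the Charlson-0 column for ages 65-69/70-74/75+ carries the
  # published 12.3 / 10.9 / 9.7; other cells are plausible synthetic
  # extensions (monotone in age and comorbidity)
  m <- rbind(`55-59` = c(14.6, 12.8, 10.5),
             `60-64` = c(13.5, 11.9, 9.7),
             `65-69` = c(12.3, 10.8, 8.9),
             `70-74` = c(10.9, 9.6, 7.8),
             `75+`   = c(9.7, 8.5, 7.0))
  colnames(m) <- charlson_levels
  m
}

#' Tabulated survival-curve points for the untreated-cancer strata
#'
#' Produces exact Weibull tabulations (annual, years 1-20) for each
#' age-band by Charlson stratum, with common shape and per-stratum scale
#' chosen so the curve's mean equals the stratum's life-expectancy
#' target. Refitting the points recovers shape and mean exactly, so the
#' set doubles as a round-trip fixture for the curve-fitting path.
#'
#' @param shape common Weibull shape (default 1.4, the reference shape of
#'   the untreated-cancer curves).
#' @param le_targets matrix of target life expectancies (rows: age bands
#'   55-59 ... 75+; columns: Charlson 0 / 1 / 2+). The default embeds the
#'   published 12.3 / 10.9 / 9.7 years for Charlson 0 at ages 65-69,
#'   70-74 and 75+.
#' @param times tabulation times in years.
#' @return Data frame with columns `age_band`, `charlson`, `t_years`,
#'   `survival`.
#' @export
generate_survival_points <- function(shape = 1.4,
                                     le_targets = default_le_targets(),
                                     times = 1:20) {
  stopifnot(shape > 0, all(le_targets > 0), all(times > 0))
  rows <- list()
  for (ab in rownames(le_targets)) {
    for (ch in colnames(le_targets)) {
      w <- weibull_from_mean(le_targets[ab, ch], shape)
      rows[[paste(ab, ch)]] <- data.frame(
        age_band = ab, charlson = ch,
        t_years = times, survival = surv_prob(w, times),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exclusion filter for the survival cohort
#'
#' Applies, with auditable counts, the entry filters of the
#' life-expectancy cohort: men with significant cancer detected at the
#' first round and men with other life-threatening malignancies are
#' excluded (skin cancer is not an exclusion). The flags must be supplied
#' as logical columns `cspca_round1` and `lethal_malignancy`; absent
#' flags are treated as all-`FALSE`.
#'
#' @param cohort survival cohort data frame, optionally carrying the flag
#'   columns.
#' @return The filtered cohort; attribute `"exclusions"` holds the counts
#'   removed per criterion.
#' @export
filter_survival_cohort <- function(cohort) {
  f1 <- if (is.null(cohort$cspca_round1)) rep(FALSE, nrow(cohort)) else
    as.logical(cohort$cspca_round1)
  f2 <- if (is.null(cohort$lethal_malignancy)) rep(FALSE, nrow(cohort)) else
    as.logical(cohort$lethal_malignancy)
  keep <- !(f1 | f2)
  out <- cohort[keep, setdiff(names(cohort),
                              c("cspca_round1", "lethal_malignancy")),
                drop = FALSE]
  attr(out, "exclusions") <- c(cspca_round1 = sum(f1),
                               lethal_malignancy = sum(f2 & !f1))
  out
}
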