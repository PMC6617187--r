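#' Untreated-cancer survival curve for a profile from a life-expectancy model
#'
#' Looks up the stratum (age band, Charlson) scale in the model's
#' untreated-cancer table.
#'
#' @param le_model an `le_model` (see [read_le_model()]).
#' @param age age in years.
#' @param charlson Charlson category.
#' @return A [weibull_survival()] object.
#' @export
cspca_curve <- function(le_model, age, charlson) {
  st <- le_model$cspca$strata
  ab <- as.character(age_band(age))
  ch <- as.character(as_charlson(charlson))
  i <- which(st$age_band == ab & st$charlson == ch)
  if (length(i) != 1L) {
    stop("no untreated-cancer stratum for age band ", ab, ", Charlson ", ch)
  }
  weibull_survival(shape = le_model$cspca$shape, scale = st$scale[i])
}

#' Life expectancy without significant cancer for a profile
#'
#' Evaluates the without-cancer Weibull regression at the profile's age
#' and Charlson category and applies the healthy-screenee
#' relative-mortality correction stored in the model, so the estimate
#' refers to the general population rather than the screening cohort.
#'
#' @inheritParams cspca_curve
#' @return A [weibull_survival()] object.
#' @export
no_cspca_curve <- function(le_model, age, charlson) {
  m <- list(shape = le_model$no_cspca$shape,
            coefficients = as.list(le_model$no_cspca$coefficients))
  w <- predict_le_curve(m, age, charlson)
  ratio <- le_model$no_cspca$relative_mortality
  if (!is.null(ratio) && is.finite(ratio)) w <- apply_relative_mortality(w, ratio)
  w
}

#' Full triage assessment for one man
#'
#' Runs the whole pipeline: predicted risk of clinically significant
#' cancer on a current biopsy, life expectancy without significant cancer
#' (healthy-screenee corrected), life expectancy with untreated and with
#' treated significant cancer (trial hazard ratio under proportional
#' hazards), absolute treatment benefit, and the threshold-band referral
#' advice.
#'
#' @param profile a [patient_profile()].
#' @param risk_model a `cspca_risk_model` (default: the shipped reference
#'   model).
#' @param le_model an `le_model` (default: the shipped reference model).
#' @param effect a [treatment_effect()] (default: the PIVOT estimate).
#' @param thresholds a [decision_thresholds()] object.
#' @return A `triage_report` (see [render_report()]).
#' @examples
#' \donttest{
#' p <- patient_profile(age = 65, psa = 4.0, free_psa_pct = 0.17, charlson = "0")
#' triage(p)
#' }
#' @export
triage <- function(profile,
                   risk_model = reference_risk_model(),
                   le_model = reference_le_model(),
                   effect = trial_effects("PIVOT"),
                   thresholds = decision_thresholds()) {
  stopifnot(inherits(profile, "patient_profile"))
  risk <- predict_cspca_risk(risk_model, profile)
  w_without <- no_cspca_curve(le_model, profile$age, profile$charlson)
  w_cspca <- cspca_curve(le_model, profile$age, profile$charlson)
  gain <- le_gain(w_cspca, effect)
  advice <- decide_referral(risk = risk,
                            le_without_cspca = weibull_mean(w_without),
                            le_untreated_cspca = gain$le_untreated,
                            gain = gain$gain_years,
                            thresholds = thresholds)
  render_report(profile, risk,
                le_without = weibull_mean(w_without),
                le_untreated = gain$le_untreated,
                le_treated = gain$le_treated,
                gain_years = gain$gain_years,
                advice = advice)
}
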