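#' Consensus threshold bands for the referral decision
#'
#' The three bands against which a man's numbers are judged: risk of
#' clinically significant cancer on a current biopsy (5-10%), life
#' expectancy (10-15 years) and absolute treatment benefit (1-2 years).
#' Below the lower limit a criterion argues against referral, above the
#' upper limit for it; inside the band the decision is shared with the
#' patient.
#'
#' @param risk risk band as `c(low, high)` probabilities (default
#'   `c(0.05, 0.10)`).
#' @param le life-expectancy band in years (default `c(10, 15)`).
#' @param gain treatment-benefit band in years (default `c(1, 2)`).
#' @return An object of class `decision_thresholds`.
#' @export
decision_thresholds <- function(risk = c(0.05, 0.10), le = c(10, 15),
                                gain = c(1, 2)) {
  chk <- function(b, what) {
    if (!is.numeric(b) || length(b) != 2L || b[1L] > b[2L]) {
      stop(what, " band must be numeric c(low, high) with low <= high")
    }
  }
  chk(risk, "risk"); chk(le, "le"); chk(gain, "gain")
  structure(list(risk = risk, le = le, gain = gain),
            class = "decision_thresholds")
}

#' Classify one value against a band
#'
#' @param value the measured quantity.
#' @param band numeric `c(low, high)`.
#' @return `"below"` (value < low), `"within"` (low <= value <= high) or
#'   `"above"` (value > high).
#' @export
classify_criterion <- function(value, band) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value),
            is.numeric(band), length(band) == 2L, band[1L] <= band[2L])
  if (value < band[1L]) "below" else if (value > band[2L]) "above" else "within"
}

#' Referral recommendation from risk, life expectancy and treatment benefit
#'
#' Applies the consensus bands to the three quantities and combines them
#' into one of three recommendations. The rules, in order:
#'
#' 1. all three below their bands — no referral;
#' 2. risk below its band (and benefit not clearly above) — no referral:
#'    a man unlikely to harbour significant cancer is not biopsied on life
#'    expectancy alone;
#' 3. both treatment benefit and life expectancy below their bands — no
#'    referral, regardless of risk: the potential benefit from detection
#'    is too small;
#' 4. treatment benefit above its band (with risk at least in band) —
#'    refer; risk and benefit lead the decision even when life expectancy
#'    falls below 10 years, in which case `override_applied` is set;
#' 5. risk above its band (with some expected benefit) — refer;
#' 6. no criterion below its band and at least one at or beyond its band
#'    midpoint — refer (the consensus-band reading: when everything is
#'    favourable and something is clearly so, referral is advised);
#' 7. otherwise — shared decision: the patient's preferences dictate.
#'
#' The life-expectancy criterion is judged on life expectancy *without*
#' significant cancer (the man's competing-risk horizon); the untreated
#' disease-specific life expectancy is carried along for reporting only.
#'
#' @param risk probability of significant cancer on biopsy, in (0, 1).
#' @param le_without_cspca life expectancy without significant cancer,
#'   years.
#' @param le_untreated_cspca life expectancy with untreated significant
#'   cancer, years (reported, not thresholded).
#' @param gain absolute treatment benefit, years.
#' @param thresholds a [decision_thresholds()] object.
#' @return An object of class `referral_advice`: `overall`
#'   (`"no_referral"`, `"shared_decision"`, `"refer"`), `per_criterion`
#'   (named classification of risk/le/gain), `override_applied`,
#'   `narrative`.
#' @export
decide_referral <- function(risk, le_without_cspca, le_untreated_cspca, gain,
                            thresholds = decision_thresholds()) {
  stopifnot(inherits(thresholds, "decision_thresholds"),
            is.finite(risk), risk > 0, risk < 1,
            is.finite(le_without_cspca), is.finite(le_untreated_cspca),
            is.finite(gain))
  cls <- c(risk = classify_criterion(risk, thresholds$risk),
           le = classify_criterion(le_without_cspca, thresholds$le),
           gain = classify_criterion(gain, thresholds$gain))
  mid <- function(b) mean(b)
  at_mid <- c(risk >= mid(thresholds$risk),
              le_without_cspca >= mid(thresholds$le),
              gain >= mid(thresholds$gain))
  override <- FALSE
  if (all(cls == "below")) {
    overall <- "no_referral"
  } else if (cls[["risk"]] == "below" && cls[["gain"]] != "above") {
    overall <- "no_referral"
  } else if (cls[["gain"]] == "below" && cls[["le"]] == "below") {
    overall <- "no_referral"
  } else if (cls[["gain"]] == "above" && cls[["risk"]] != "below") {
    overall <- "refer"
    override <- cls[["le"]] == "below"
  } else if (cls[["risk"]] == "above" && cls[["gain"]] != "below") {
    overall <- "refer"
    override <- cls[["le"]] == "below"
  } else if (!any(cls == "below") && any(at_mid)) {
    overall <- "refer"
  } else {
    overall <- "shared_decision"
  }
  narrative <- switch(overall,
    no_referral = paste0(
      "No referral advised: the expected benefit from detecting and ",
      "treating significant prostate cancer is low for this man."),
    shared_decision = paste0(
      "Within the consensus bands: discuss the trade-off between the ",
      "risk of significant cancer and the expected benefit; the ",
      "patient's preferences should dictate."),
    refer = paste0(
      "Referral to a urologist for further assessment is advised",
      if (override) paste0(
        " (risk and treatment benefit lead the decision despite a life ",
        "expectancy below ", thresholds$le[1L], " years)") else "", "."))
  structure(list(overall = overall, per_criterion = cls,
                 override_applied = override, narrative = narrative),
            class = "referral_advice")
}

#' @export
print.referral_advice <- function(x, ...) {
  cat(sprintf("Advice: %s%s\n", x$overall,
              if (x$override_applied) " (override applied)" else ""))
  cat(sprintf("  risk: %s, life expectancy: %s, treatment benefit: %s\n",
              x$per_criterion[["risk"]], x$per_criterion[["le"]],
              x$per_criterion[["gain"]]))
  cat(" ", x$narrative, "\n")
  invisible(x)
}

#' Render the patient-facing triage report
#'
#' Assembles the five quantities the tool communicates — risk of
#' significant cancer on a current biopsy, life expectancy with and
#' without untreated significant cancer, life expectancy after treatment,
#' and the absolute treatment benefit — together with the referral
#' advice. Display rounding follows the convention of the printed report:
#' risk to whole percent, life expectancies to one decimal year, benefit
#' to whole months; the underlying JSON keeps full precision so the
#' report round-trips.
#'
#' @param profile the [patient_profile()].
#' @param risk probability of significant cancer on biopsy.
#' @param le_without years of life expectancy without significant cancer.
#' @param le_untreated years with untreated significant cancer.
#' @param le_treated years with treated significant cancer.
#' @param gain_years absolute treatment benefit in years.
#' @param advice a [referral_advice()][decide_referral()] object.
#' @return An object of class `triage_report` (a list); `format()` and
#'   `print()` give the human-readable card, [report_to_json()] the
#'   machine form.
#' @export
render_report <- function(profile, risk, le_without, le_untreated,
                          le_treated, gain_years, advice) {
  stopifnot(inherits(advice, "referral_advice"))
  structure(list(
    patient = list(age = profile$age, psa = profile$psa,
                   free_psa_pct = profile$free_psa_pct,
                   charlson = profile$charlson),
    risk_cspca = risk,
    le_without_cspca_years = le_without,
    le_untreated_cspca_years = le_untreated,
    le_treated_cspca_years = le_treated,
    gain_years = gain_years,
    gain_months = round_months(gain_years),
    advice = advice$overall,
    per_criterion = as.list(advice$per_criterion),
    override_applied = advice$override_applied,
    narrative = advice$narrative), class = "triage_report")
}

#' @export
format.triage_report <- function(x, ...) {
  gain_line <- if (x$gain_years == 0) {
    "Treatment benefit:                 no expected survival benefit"
  } else {
    sprintf("Treatment benefit:                 %d months", x$gain_months)
  }
  paste(c(
    sprintf("Patient: age %g y, PSA %.1f ng/mL, %%freePSA %.0f%%, Charlson %s",
            x$patient$age, x$patient$psa, 100 * x$patient$free_psa_pct,
            x$patient$charlson),
    sprintf("Risk of csPCa on current biopsy:   %d%%", round(100 * x$risk_cspca)),
    sprintf("Life expectancy without csPCa:     %.1f years", x$le_without_cspca_years),
    sprintf("Life expectancy, untreated csPCa:  %.1f years", x$le_untreated_cspca_years),
    sprintf("Life expectancy, treated csPCa:    %.1f years", x$le_treated_cspca_years),
    gain_line,
    sprintf("Advice: %s", x$advice),
    x$narrative), collapse = "\n")
}

#' @export
print.triage_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Serialise / parse a triage report as JSON
#'
#' Numeric fields are stored at full precision so that
#' `parse_report(report_to_json(x))` reproduces them exactly.
#'
#' @param report a `triage_report`.
#' @return `report_to_json()`: a JSON string; `parse_report()`: the
#'   `triage_report` list.
#' @export
report_to_json <- function(report) {
  stopifnot(inherits(report, "triage_report"))
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                   pretty = TRUE)
}

#' @rdname report_to_json
#' @param json JSON string produced by [report_to_json()].
#' @export
parse_report <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  x$per_criterion <- as.list(x$per_criterion)
  for (f in c("risk_cspca", "le_without_cspca_years", "le_untreated_cspca_years",
              "le_treated_cspca_years", "gain_years", "gain_months")) {
    x[[f]] <- as.numeric(x[[f]])  # whole numbers parse as integer otherwise
  }
  class(x) <- "triage_report"
  x
}
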