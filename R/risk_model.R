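outcome_levels <- c("no_pca", "indolent_pca", "cspca")

# predictors entered on the log2 scale and centred at the training mean
log2_predictors <- c("psa", "free_psa_pct", "pv_estimate_cc")
binary_predictors <- c("dre_abnormal", "family_history")
known_predictors <- c("age", log2_predictors, binary_predictors, "ipss")

#' Patient profile for biopsy-referral triage
#'
#' Bundles the covariates a general practitioner has at hand. PSA and free
#' PSA are serum measurements; `free_psa_pct` is the free/total ratio on
#' the (0, 1] scale (enter 17% as 0.17). The prostate-volume estimate is a
#' rough three-level category a digital rectal examination supports
#' (25, 40 or 60 cc).
#'
#' @param age age in years.
#' @param psa total PSA in ng/mL (> 0).
#' @param free_psa_pct free-to-total PSA ratio in (0, 1].
#' @param charlson Charlson comorbidity category `"0"`, `"1"` or `"2+"`
#'   (numeric 0/1/2 accepted).
#' @param dre_abnormal optional logical: abnormal digital rectal exam.
#' @param pv_estimate_cc optional prostate-volume category: 25, 40 or 60.
#' @param family_history optional logical: first-degree family history.
#' @param ipss optional International Prostate Symptom Score, integer 0-35.
#' @return An object of class `patient_profile`.
#' @examples
#' patient_profile(age = 65, psa = 4.0, free_psa_pct = 0.17, charlson = "0")
#' @export
patient_profile <- function(age, psa, free_psa_pct, charlson = "0",
                            dre_abnormal = NULL, pv_estimate_cc = NULL,
                            family_history = NULL, ipss = NULL) {
  stopifnot(is.numeric(age), length(age) == 1L, age > 0)
  if (!is.numeric(psa) || length(psa) != 1L || !is.finite(psa) || psa <= 0) {
    stop("psa must be a positive number (ng/mL)")
  }
  if (!is.numeric(free_psa_pct) || length(free_psa_pct) != 1L ||
      free_psa_pct <= 0 || free_psa_pct > 1) {
    stop("free_psa_pct must be a ratio in (0, 1]; enter 17% as 0.17")
  }
  if (!is.null(pv_estimate_cc) && !pv_estimate_cc %in% c(25, 40, 60)) {
    stop("pv_estimate_cc must be one of 25, 40, 60 (cc)")
  }
  if (!is.null(ipss) && (ipss < 0 || ipss > 35)) stop("ipss must lie in 0-35")
  structure(list(
    age = age, psa = psa, free_psa_pct = free_psa_pct,
    charlson = as.character(as_charlson(charlson)),
    dre_abnormal = if (is.null(dre_abnormal)) NULL else isTRUE(as.logical(dre_abnormal)),
    pv_estimate_cc = pv_estimate_cc,
    family_history = if (is.null(family_history)) NULL else isTRUE(as.logical(family_history)),
    ipss = ipss), class = "patient_profile")
}

#' @export
print.patient_profile <- function(x, ...) {
  cat(sprintf("Patient: age %g y, PSA %.1f ng/mL, %%freePSA %.0f%%, Charlson %s\n",
              x$age, x$psa, 100 * x$free_psa_pct, x$charlson))
  invisible(x)
}

# one transformed value for one predictor of one profile-like list
transform_one <- function(profile, name, centering) {
  v <- profile[[name]]
  if (is.null(v) || length(v) == 0L || is.na(v)) {
    stop("predictor unavailable: ", name, call. = FALSE)
  }
  if (name %in% log2_predictors) {
    if (!is.numeric(v) || v <= 0) stop(name, " must be positive for the log2 transform")
    ctr <- if (!is.null(centering) && name %in% names(centering)) centering[[name]] else 0
    return(log2(v) - ctr)
  }
  if (name %in% binary_predictors) return(as.numeric(as.logical(v)))
  as.numeric(v)
}

#' Transform raw predictors into model scale
#'
#' Applies the model's predictor coding: PSA, %freePSA and the
#' prostate-volume category are taken to the log2 scale and the model's
#' centering constant (the training-cohort mean of the log2 value) is
#' subtracted; binary predictors are coded 0/1; age and IPSS enter
#' untransformed.
#'
#' @param profile a [patient_profile()] (or a named list with the needed
#'   fields).
#' @param model a fitted `cspca_risk_model` (its `predictor_set` and
#'   `centering` define the coding).
#' @return Named numeric vector, one element per model predictor, in model
#'   order.
#' @export
transform_predictors <- function(profile, model) {
  stopifnot(inherits(model, "cspca_risk_model"))
  out <- vapply(model$predictor_set, function(nm) {
    transform_one(profile, nm, model$centering)
  }, numeric(1))
  names(out) <- model$predictor_set
  out
}

new_risk_model <- function(predictor_set, coefficients, intercept, centering,
                           fit_metadata = list()) {
  stopifnot(setequal(names(coefficients), predictor_set))
  structure(list(predictor_set = predictor_set,
                 coefficients = coefficients[predictor_set],
                 intercept = intercept,
                 centering = centering,
                 fit_metadata = fit_metadata),
            class = "cspca_risk_model")
}

#' @export
print.cspca_risk_model <- function(x, ...) {
  cat("Logistic csPCa risk model\n")
  cat("  predictors:", paste(x$predictor_set, collapse = ", "), "\n")
  cat(sprintf("  intercept: %.4f\n", x$intercept))
  for (nm in x$predictor_set) {
    cat(sprintf("  %-15s %+0.4f%s\n", nm, x$coefficients[[nm]],
                if (nm %in% names(x$centering))
                  sprintf("   (log2, centred at %.4f)", x$centering[[nm]]) else ""))
  }
  invisible(x)
}

check_biopsy_cohort <- function(cohort) {
  need <- c("age", "psa", "free_psa_pct", "outcome")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("biopsy cohort lacks columns: ", paste(miss, collapse = ", "))
  out <- trimws(as.character(cohort$outcome))
  bad <- !(out %in% outcome_levels)
  if (any(bad)) {
    stop("unknown outcome label(s): ", paste(unique(out[bad]), collapse = ", "),
         " at row(s) ", paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  if (any(cohort$psa <= 0, na.rm = TRUE)) {
    stop("nonpositive PSA at row(s) ",
         paste(utils::head(which(cohort$psa <= 0), 5L), collapse = ", "))
  }
  if (any(cohort$free_psa_pct <= 0 | cohort$free_psa_pct > 1, na.rm = TRUE)) {
    stop("free_psa_pct must lie in (0, 1]")
  }
  cohort$outcome <- out
  cohort
}

# design matrix on the model scale for a cohort data frame
build_design <- function(cohort, predictor_set, centering) {
  X <- matrix(NA_real_, nrow(cohort), length(predictor_set),
              dimnames = list(NULL, predictor_set))
  for (nm in predictor_set) {
    v <- cohort[[nm]]
    if (is.null(v)) stop("predictor unavailable: ", nm, call. = FALSE)
    if (anyNA(v)) stop("predictor unavailable: ", nm, " (missing values)", call. = FALSE)
    X[, nm] <- if (nm %in% log2_predictors) {
      if (any(v <= 0)) stop(nm, " must be positive for the log2 transform")
      ctr <- if (nm %in% names(centering)) centering[[nm]] else 0
      log2(v) - ctr
    } else if (nm %in% binary_predictors) {
      as.numeric(as.logical(v))
    } else {
      as.numeric(v)
    }
  }
  X
}

#' Fit the logistic risk model for clinically significant cancer on biopsy
#'
#' Maximum-likelihood logistic regression of clinically significant
#' prostate cancer (ISUP grade >= 2) versus everything else (no cancer and
#' indolent, ISUP 1, cancers collapsed to the negative class). PSA,
#' %freePSA and the prostate-volume category enter as log2 values centred
#' at their training-cohort means; the centering constants are stored in
#' the model so prediction needs no cohort.
#'
#' @param cohort biopsy-cohort data frame with an `outcome` column
#'   (`"no_pca"`, `"indolent_pca"`, `"cspca"`) and the predictor columns.
#' @param predictor_set character vector of predictors; default is the
#'   basic age + PSA + %freePSA model. An empty set fits the
#'   intercept-only (prevalence) model.
#' @return A `cspca_risk_model` object.
#' @export
fit_cspca_model <- function(cohort,
                            predictor_set = c("age", "psa", "free_psa_pct")) {
  stopifnot(all(predictor_set %in% known_predictors))
  predictor_set <- as.character(predictor_set)
  cohort <- check_biopsy_cohort(cohort)
  y <- as.integer(cohort$outcome == "cspca")
  if (length(unique(y)) < 2L) {
    stop("cohort must contain both significant-cancer and negative outcomes")
  }
  centering <- list()
  for (nm in intersect(predictor_set, log2_predictors)) {
    v <- cohort[[nm]]
    if (is.null(v) || anyNA(v)) stop("predictor unavailable: ", nm, call. = FALSE)
    centering[[nm]] <- mean(log2(v))
  }
  X <- build_design(cohort, predictor_set, centering)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                   family = stats::binomial(),
                   control = stats::glm.control(maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) {
    stop("logistic fit did not converge after ", fit$iter, " iterations")
  }
  cf <- fit$coefficients
  if (length(cf) > 1L && (sep_warn || any(abs(cf[-1L]) > 15))) {
    worst <- names(which.max(abs(cf[-1L])))
    stop("(quasi-)perfect separation detected; predictor most implicated: ", worst)
  }
  new_risk_model(
    predictor_set = predictor_set,
    coefficients = as.list(cf[-1L]),
    intercept = unname(cf[1L]),
    centering = centering,
    fit_metadata = list(n = nrow(cohort), n_cspca = sum(y),
                        date = format(Sys.Date())))
}

#' Predicted probability of clinically significant cancer on biopsy
#'
#' @param model a `cspca_risk_model`.
#' @param profile a [patient_profile()] (or named list) for a single man,
#'   or a biopsy-cohort data frame for vectorised prediction.
#' @return Probability (or vector of probabilities), strictly inside
#'   (0, 1).
#' @export
predict_cspca_risk <- function(model, profile) {
  stopifnot(inherits(model, "cspca_risk_model"))
  beta <- unlist(model$coefficients[model$predictor_set])
  if (length(model$predictor_set) == 0L) {
    n <- if (is.data.frame(profile)) nrow(profile) else 1L
    return(stats::plogis(rep(model$intercept, n)))
  }
  if (is.data.frame(profile)) {
    X <- build_design(profile, model$predictor_set, model$centering)
    lp <- model$intercept + drop(X %*% beta)
  } else {
    x <- transform_predictors(profile, model)
    lp <- model$intercept + sum(beta * x)
  }
  stats::plogis(lp)
}
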