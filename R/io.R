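#' Read a biopsy cohort from CSV
#'
#' Expects the columns `age, psa, free_psa_pct, dre_abnormal,
#' pv_estimate_cc, family_history, ipss, charlson, outcome` (optional
#' covariates may be empty). Outcome labels are trimmed of surrounding
#' whitespace before validation; malformed rows are reported by row
#' number.
#'
#' @param path CSV file path.
#' @return Validated biopsy-cohort data frame (possibly empty).
#' @export
read_biopsy_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "psa", "free_psa_pct", "outcome")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("header lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(d) == 0L) return(d)
  d$outcome <- trimws(as.character(d$outcome))
  for (nm in c("dre_abnormal", "family_history")) {
    if (nm %in% names(d) && !is.logical(d[[nm]])) d[[nm]] <- as.logical(d[[nm]])
  }
  check_biopsy_cohort(d)
}

#' Write a biopsy cohort to CSV
#' @param cohort biopsy-cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_biopsy_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a survival cohort from CSV
#'
#' Expects columns `age, charlson, follow_up_months, status` (status
#' `dead`/`alive`).
#'
#' @param path CSV file path.
#' @return Validated survival-cohort data frame.
#' @export
read_survival_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(charlson = "character"))
  if (nrow(d) == 0L) return(d)
  d$status <- trimws(as.character(d$status))
  check_survival_cohort(d)
}

#' Write a survival cohort to CSV
#' @param cohort survival-cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a life table from CSV
#' @param path CSV with columns `age`, `hazard`.
#' @return Validated life-table data frame.
#' @export
read_life_table_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path)
  if (!all(c("age", "hazard") %in% names(d))) {
    stop("life table must have columns age, hazard")
  }
  if (any(d$hazard <= 0)) stop("life-table hazards must be positive")
  if (any(diff(d$age) != 1L)) stop("life-table ages must be contiguous")
  d
}

#' Read tabulated survival-curve points from CSV
#' @param path CSV with columns `age_band`, `charlson`, `t_years`,
#'   `survival` (an optional `gleason_band` column is carried through).
#' @return Validated points data frame.
#' @export
read_survival_points_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(charlson = "character"))
  if (!all(c("age_band", "charlson", "t_years", "survival") %in% names(d))) {
    stop("survival points must have columns age_band, charlson, t_years, survival")
  }
  if (any(d$survival <= 0 | d$survival >= 1)) {
    stop("survival proportions must lie strictly in (0, 1)")
  }
  d
}

#' Save / load a fitted risk model as JSON
#'
#' The JSON mirrors the model object: `predictor_set`, `coefficients`,
#' `intercept`, `centering`, `fit_metadata`.
#'
#' @param model a `cspca_risk_model`.
#' @param path JSON file path.
#' @return `write_risk_model()`: `path`, invisibly; `read_risk_model()`:
#'   the model.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "cspca_risk_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$predictor_set)) x$predictor_set <- character(0)
  new_risk_model(predictor_set = as.character(x$predictor_set),
                 coefficients = as.list(x$coefficients),
                 intercept = x$intercept,
                 centering = as.list(x$centering),
                 fit_metadata = as.list(x$fit_metadata))
}

#' Save / load the combined life-expectancy model as JSON
#'
#' The life-expectancy model couples (a) the Weibull
#' accelerated-failure-time model for survival without significant cancer
#' — shape, coefficients and the healthy-screenee relative-mortality
#' ratio already estimated — and (b) the per-stratum untreated-cancer
#' curves: a common shape and one scale per age band and Charlson
#' category.
#'
#' @param model a list with elements `no_cspca` (`shape`, `coefficients`,
#'   `relative_mortality`) and `cspca` (`shape`, `strata` data frame with
#'   `age_band`, `charlson`, `scale`), class `le_model`.
#' @param path JSON file path.
#' @return `write_le_model()`: `path`, invisibly; `read_le_model()`: the
#'   model list.
#' @export
write_le_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_le_model
#' @export
read_le_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("no_cspca", "cspca")) {
    if (is.null(x[[nm]])) stop("life-expectancy model JSON lacks '", nm, "'")
  }
  x$no_cspca$coefficients <- unlist(x$no_cspca$coefficients)
  x$cspca$strata <- as.data.frame(x$cspca$strata)
  class(x) <- "le_model"
  x
}

#' Read decision thresholds from JSON
#' @param path JSON with fields `risk`, `le`, `gain`, each `[low, high]`.
#' @return A [decision_thresholds()] object.
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  decision_thresholds(risk = x$risk, le = x$le, gain = x$gain)
}

#' Write a decision curve to CSV
#' @param curve data frame from [decision_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_decision_curve_csv <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reference models shipped with the package
#'
#' `reference_risk_model()` loads the versioned risk model fitted on the
#' seeded default synthetic biopsy cohort; `reference_le_model()` loads
#' the matching life-expectancy model (fitted on the seeded synthetic
#' survival cohort and life table, with the untreated-cancer strata at
#' the reference shape 1.4); `reference_thresholds()` loads the consensus
#' bands. These make the command-line tool usable out of the box and are
#' synthetic-data fits, not published coefficients.
#'
#' @return The corresponding model object.
#' @export
reference_risk_model <- function() {
  read_risk_model(system.file("extdata", "reference_model.json",
                              package = "pcatriage", mustWork = TRUE))
}

#' @rdname reference_risk_model
#' @export
reference_le_model <- function() {
  read_le_model(system.file("extdata", "reference_le_model.json",
                            package = "pcatriage", mustWork = TRUE))
}

#' @rdname reference_risk_model
#' @export
reference_thresholds <- function() {
  read_thresholds(system.file("extdata", "thresholds.json",
                              package = "pcatriage", mustWork = TRUE))
}
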