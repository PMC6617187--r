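#' Concordance index for a binary outcome
#'
#' Probability that a randomly chosen case receives a higher prediction
#' than a randomly chosen control, with prediction ties counted one half.
#' Computed from mid-ranks (Mann-Whitney identity), which is exactly the
#' all-pairs count.
#'
#' @param predictions numeric vector of risk predictions.
#' @param outcomes binary vector (0/1 or logical), same length.
#' @return Concordance in [0, 1].
#' @export
concordance_index <- function(predictions, outcomes) {
  outcomes <- as.integer(outcomes)
  stopifnot(length(predictions) == length(outcomes),
            all(outcomes %in% c(0L, 1L)))
  n1 <- sum(outcomes == 1L)
  n0 <- sum(outcomes == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("concordance undefined: outcomes contain a single class")
  }
  r <- rank(predictions)  # mid-ranks handle ties as 1/2
  (sum(r[outcomes == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Index of Prediction Accuracy
#'
#' Scaled Brier score: \eqn{IPA = (1 - Brier_{model}/Brier_{null}) \times
#' 100}, where the null model predicts the observed prevalence for
#' everyone. Unlike the concordance index it is sensitive to calibration
#' as well as discrimination; 0% means no better than prevalence, 100%
#' means perfect.
#'
#' @inheritParams concordance_index
#' @return IPA in percent.
#' @export
ipa <- function(predictions, outcomes) {
  outcomes <- as.integer(outcomes)
  stopifnot(length(predictions) == length(outcomes),
            all(outcomes %in% c(0L, 1L)))
  p0 <- mean(outcomes)
  if (p0 == 0 || p0 == 1) stop("IPA undefined: outcome prevalence is 0 or 1")
  brier_model <- mean((predictions - outcomes)^2)
  brier_null <- mean((p0 - outcomes)^2)
  (1 - brier_model / brier_null) * 100
}

#' Net benefit of a risk-based biopsy policy at one threshold
#'
#' Counts a biopsy as advised when the prediction is at or above the
#' threshold, and weighs unnecessary biopsies by the threshold odds:
#' \eqn{NB = TP/n - \frac{t}{1-t} FP/n}. The threshold probability encodes
#' how many unnecessary biopsies a patient would accept to find one
#' significant cancer.
#'
#' @inheritParams concordance_index
#' @param threshold probability threshold strictly inside (0, 1).
#' @return Net benefit (true positives per person, harm-adjusted).
#' @export
net_benefit <- function(predictions, outcomes, threshold) {
  outcomes <- as.integer(outcomes)
  stopifnot(length(predictions) == length(outcomes),
            all(outcomes %in% c(0L, 1L)),
            is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  advised <- predictions >= threshold
  n <- length(outcomes)
  tp <- sum(advised & outcomes == 1L)
  fp <- sum(advised & outcomes == 0L)
  tp / n - threshold / (1 - threshold) * fp / n
}

#' Decision-curve analysis against the default PSA-threshold strategy
#'
#' Evaluates net benefit over the range of threshold probabilities at
#' which a patient might opt for biopsy (3-10% by default), for four
#' policies: the risk model, the default strategy of biopsying every man
#' with PSA >= 3.0 ng/mL (fixed classification; its net benefit still
#' varies with the threshold through the harm weight), biopsy-all and
#' biopsy-none. Also reports biopsies avoided per 1000 men by the model
#' relative to the default strategy.
#'
#' @inheritParams concordance_index
#' @param psa_values total PSA (ng/mL) aligned with `outcomes`.
#' @param grid threshold grid (default 3% to 10% in steps of 0.5%).
#' @param psa_cutoff default-strategy PSA cutoff (3.0 ng/mL).
#' @return Data frame with columns `threshold`, `nb_model`, `nb_default`,
#'   `nb_all`, `nb_none`, `biopsies_avoided_per_1000`.
#' @export
decision_curve <- function(predictions, outcomes, psa_values,
                           grid = seq(0.03, 0.10, by = 0.005),
                           psa_cutoff = 3.0) {
  outcomes <- as.integer(outcomes)
  stopifnot(length(psa_values) == length(outcomes),
            length(predictions) == length(outcomes))
  n <- length(outcomes)
  default_advised <- psa_values >= psa_cutoff
  tp_d <- sum(default_advised & outcomes == 1L)
  fp_d <- sum(default_advised & outcomes == 0L)
  prev <- mean(outcomes)
  rows <- lapply(grid, function(t) {
    w <- t / (1 - t)
    advised <- predictions >= t
    tp <- sum(advised & outcomes == 1L)
    fp <- sum(advised & outcomes == 0L)
    data.frame(
      threshold = t,
      nb_model = tp / n - w * fp / n,
      nb_default = tp_d / n - w * fp_d / n,
      nb_all = prev - w * (1 - prev),
      nb_none = 0,
      biopsies_avoided_per_1000 = 1000 * ((tp_d + fp_d) - (tp + fp)) / n)
  })
  do.call(rbind, rows)
}

#' Bootstrap optimism correction of the concordance index
#'
#' For each replicate, the cohort is resampled with replacement, the model
#' is refitted on the resample, and the difference between its concordance
#' on the resample and its concordance on the original cohort is recorded.
#' The mean difference is the optimism; subtracting it from the apparent
#' concordance gives an internally validated estimate of out-of-sample
#' discrimination. Replicates whose resample contains a single outcome
#' class (or fails to fit) are skipped and counted; more than 10% skipped
#' is an error.
#'
#' @param cohort biopsy-cohort data frame (see [fit_cspca_model()]).
#' @param predictor_set predictors for the model under evaluation.
#' @param n_boot number of bootstrap replicates (1000 by default).
#' @param seed integer seed; the run is bit-reproducible given the seed.
#' @return An object of class `metric_report`: `c_index_apparent`,
#'   `c_index_optimism`, `c_index_corrected`
#'   (= apparent - optimism), `ipa_pct` (apparent), `n_bootstrap`
#'   (replicates actually used) and `n_skipped`.
#' @export
bootstrap_optimism <- function(cohort,
                               predictor_set = c("age", "psa", "free_psa_pct"),
                               n_boot = 1000L, seed = 1L) {
  stopifnot(n_boot >= 1L)
  cohort <- check_biopsy_cohort(cohort)
  y <- as.integer(cohort$outcome == "cspca")
  model <- fit_cspca_model(cohort, predictor_set)
  pred_app <- predict_cspca_risk(model, cohort)
  c_app <- concordance_index(pred_app, y)
  ipa_app <- ipa(pred_app, y)

  set.seed(as.integer(seed))
  n <- nrow(cohort)
  diffs <- numeric(0)
  skipped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- y[idx]
    if (length(unique(yb)) < 2L) { skipped <- skipped + 1L; next }
    mb <- tryCatch(fit_cspca_model(cohort[idx, , drop = FALSE], predictor_set),
                   error = function(e) NULL)
    if (is.null(mb)) { skipped <- skipped + 1L; next }
    c_boot <- concordance_index(predict_cspca_risk(mb, cohort[idx, , drop = FALSE]), yb)
    c_orig <- concordance_index(predict_cspca_risk(mb, cohort), y)
    diffs <- c(diffs, c_boot - c_orig)
  }
  if (skipped > 0.10 * n_boot) {
    stop("more than 10% of bootstrap resamples were degenerate (",
         skipped, "/", n_boot, ")")
  }
  optimism <- if (length(diffs)) mean(diffs) else 0
  structure(list(c_index_apparent = c_app,
                 c_index_optimism = optimism,
                 c_index_corrected = c_app - optimism,
                 ipa_pct = ipa_app,
                 n_bootstrap = length(diffs),
                 n_skipped = skipped),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0("Model validation (%d bootstrap replicates, %d skipped)\n",
                     "  concordance: apparent %.3f, optimism %.3f, corrected %.3f\n",
                     "  IPA: %.1f%%\n"),
              x$n_bootstrap, x$n_skipped,
              x$c_index_apparent, x$c_index_optimism, x$c_index_corrected,
              x$ipa_pct))
  invisible(x)
}
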