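#' Weibull survival curve
#'
#' Constructs a two-parameter Weibull survival curve
#' \eqn{S(t) = \exp(-(t/\lambda)^k)} with shape \eqn{k} and scale
#' \eqn{\lambda} (years). This is the parametric form used throughout the
#' package to summarise registry survival curves: the mean of the curve is
#' the life expectancy, and proportional-hazards adjustments (treatment
#' effect, healthy-screenee correction) act on the scale only.
#'
#' @param shape positive shape parameter \eqn{k}.
#' @param scale positive scale parameter \eqn{\lambda} in years.
#' @return An object of class `weibull_survival` with elements `shape` and
#'   `scale`.
#' @examples
#' w <- weibull_survival(shape = 1.4, scale = 13.5)
#' surv_prob(w, c(5, 10))
#' weibull_mean(w)
#' @export
weibull_survival <- function(shape, scale) {
  stopifnot(is.numeric(shape), is.numeric(scale),
            length(shape) == 1L, length(scale) == 1L)
  if (!is.finite(shape) || shape <= 0) stop("shape must be a positive number")
  if (!is.finite(scale) || scale <= 0) stop("scale must be a positive number")
  structure(list(shape = shape, scale = scale), class = "weibull_survival")
}

#' @export
print.weibull_survival <- function(x, ...) {
  cat(sprintf("Weibull survival: shape %.4g, scale %.4g y (mean %.2f y)\n",
              x$shape, x$scale, weibull_mean(x)))
  invisible(x)
}

#' Survival probability of a Weibull curve
#'
#' @param w a [weibull_survival()] object.
#' @param t vector of nonnegative times in years.
#' @return `S(t)` for each time.
#' @export
surv_prob <- function(w, t) {
  stopifnot(inherits(w, "weibull_survival"), all(t >= 0))
  exp(-(t / w$scale)^w$shape)
}

#' Mean of a Weibull survival curve (life expectancy)
#'
#' The unrestricted mean \eqn{\lambda \Gamma(1 + 1/k)}. With
#' `restrict_years` set, the restricted mean
#' \eqn{\int_0^H S(t)\,dt} is returned instead; extrapolating a Weibull
#' fitted on a 15--20 year follow-up window far beyond that window is
#' unreliable, and the restricted variant bounds the horizon.
#'
#' @param w a [weibull_survival()] object.
#' @param restrict_years optional positive horizon H in years; `NULL`
#'   (default) gives the unrestricted mean.
#' @return Life expectancy in years.
#' @export
weibull_mean <- function(w, restrict_years = NULL) {
  stopifnot(inherits(w, "weibull_survival"))
  if (is.null(restrict_years)) {
    return(w$scale * gamma(1 + 1 / w$shape))
  }
  stopifnot(is.numeric(restrict_years), restrict_years > 0)
  stats::integrate(function(t) surv_prob(w, t), 0, restrict_years,
                   rel.tol = 1e-10)$value
}

#' Construct a Weibull curve with a given mean
#'
#' Inverts the mean formula: \eqn{\lambda = m / \Gamma(1 + 1/k)}. Used to
#' build reference curves whose life expectancy equals a published value.
#'
#' @param mean_years target mean in years (> 0).
#' @param shape shape parameter (> 0).
#' @return A [weibull_survival()] object with `weibull_mean()` equal to
#'   `mean_years`.
#' @export
weibull_from_mean <- function(mean_years, shape) {
  stopifnot(is.numeric(mean_years), mean_years > 0)
  weibull_survival(shape = shape, scale = mean_years / gamma(1 + 1 / shape))
}

#' Fit a Weibull curve to published survival-curve points
#'
#' Registry reports print survival proportions at a handful of times rather
#' than individual-level data. On the complementary log-log scale the
#' Weibull is linear: \eqn{\log(-\log S) = k \log t - k \log \lambda}, so an
#' ordinary least-squares line through the points recovers shape (slope)
#' and scale (from the intercept). Exact Weibull input is inverted exactly.
#'
#' @param points data frame with columns `t_years` (> 0) and `survival`
#'   (strictly inside (0, 1), nonincreasing in `t_years`).
#' @return A [weibull_survival()] object; attribute `"rss"` holds the
#'   residual sum of squares of the cloglog-scale regression.
#' @export
fit_weibull_to_points <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("t_years", "survival") %in% names(points)))
  t <- as.numeric(points$t_years)
  s <- as.numeric(points$survival)
  if (length(t) < 2L) stop("at least 2 survival points are required")
  if (any(!is.finite(t)) || any(t <= 0)) stop("times must be positive")
  if (any(!is.finite(s)) || any(s <= 0) || any(s >= 1)) {
    stop("survival proportions must lie strictly in (0, 1)")
  }
  o <- order(t)
  if (any(diff(s[o]) > 1e-12)) {
    stop("survival must be nonincreasing in time within a stratum")
  }
  x <- log(t)
  y <- log(-log(s))
  fit <- stats::lm.fit(cbind(1, x), y)
  k <- unname(fit$coefficients[2L])
  if (!is.finite(k) || k <= 0) stop("fitted shape is not positive; check input points")
  lam <- exp(-unname(fit$coefficients[1L]) / k)
  w <- weibull_survival(shape = k, scale = lam)
  attr(w, "rss") <- sum(fit$residuals^2)
  w
}

#' Tabulate a survival curve at a grid of times
#'
#' @param s_fun a `weibull_survival` object or a function of time returning
#'   survival probabilities.
#' @param times positive times in years (default 1..20, annual).
#' @return Data frame with columns `t_years`, `survival`, suitable for
#'   [fit_weibull_to_points()].
#' @export
tabulate_survival <- function(s_fun, times = 1:20) {
  stopifnot(all(times > 0))
  s <- if (inherits(s_fun, "weibull_survival")) {
    surv_prob(s_fun, times)
  } else {
    stopifnot(is.function(s_fun))
    s_fun(times)
  }
  data.frame(t_years = times, survival = s)
}

#' Refit a tabulated survival function as a Weibull curve
#'
#' Convenience wrapper: tabulate an arbitrary survival function (for
#' example a Gleason mixture or an era-adjusted curve, neither of which is
#' exactly Weibull) and approximate it by the closest Weibull on the
#' cloglog scale.
#'
#' @inheritParams tabulate_survival
#' @return A [weibull_survival()] object.
#' @export
refit_weibull <- function(s_fun, times = 1:20) {
  fit_weibull_to_points(tabulate_survival(s_fun, times))
}

#' Gleason-band mixture weights
#'
#' Registry survival curves are stratified by broad Gleason score bands;
#' the screening cohort that defines clinically significant disease (ISUP
#' grade >= 2) has a different Gleason composition. The target weights
#' re-mix the band-specific curves to that composition.
#'
#' @param source named numeric vector of registry band weights, summing
#'   to 1 (bands such as `"5-7"`, `"8-10"`).
#' @param target named numeric vector of screening-cohort band weights,
#'   summing to 1, same names as `source`.
#' @return An object of class `gleason_weights`.
#' @export
gleason_weights <- function(source, target) {
  chk <- function(w, what) {
    if (is.null(names(w)) || any(!nzchar(names(w)))) {
      stop(what, " weights must be a named vector of Gleason bands")
    }
    if (any(w < 0) || any(w > 1)) stop(what, " weights must lie in [0, 1]")
    if (abs(sum(w) - 1) > 1e-9) stop(what, " weights must sum to 1")
  }
  chk(source, "source"); chk(target, "target")
  if (!setequal(names(source), names(target))) {
    stop("source and target weights must cover the same Gleason bands")
  }
  structure(list(source = source, target = target[names(source)]),
            class = "gleason_weights")
}

#' Re-weight band-specific survival curves to a target Gleason mix
#'
#' Forms the mixture survival \eqn{S(t) = \sum_b w_b S_b(t)} with the
#' target-composition weights, so that band-stratified registry curves
#' describe the Gleason mix actually seen among screen-detected significant
#' cancers. The mixture is not itself Weibull; pass the result through
#' [refit_weibull()] to summarise it as one.
#'
#' @param curves named list of [weibull_survival()] objects, one per
#'   Gleason band.
#' @param weights a [gleason_weights()] object whose bands exactly match
#'   `names(curves)`.
#' @return A function of time returning the mixture survival probability.
#' @export
gleason_mixture_adjust <- function(curves, weights) {
  stopifnot(inherits(weights, "gleason_weights"), is.list(curves))
  if (!setequal(names(curves), names(weights$target))) {
    stop("curve bands and weight bands do not match")
  }
  for (w in curves) stopifnot(inherits(w, "weibull_survival"))
  tw <- weights$target[names(curves)]
  cl <- curves
  function(t) {
    s <- 0
    for (b in names(cl)) s <- s + tw[[b]] * surv_prob(cl[[b]], t)
    s
  }
}

#' Adjust a pre-PSA-era survival curve for screening-era cancer mortality
#'
#' Overall survival from a pre-PSA-era registry overstates prostate-cancer
#' mortality relative to the screening era. Assuming independent competing
#' hazards, overall survival factorises as
#' \eqn{S_{overall} = S_{other} \cdot S_{pca}}; the cancer-specific factor
#' is extracted against a supplied other-cause curve and its hazard is
#' multiplied by `rel_effect` (default 0.79, the published reduction in
#' prostate-cancer mortality attributable to PSA testing), i.e. the
#' adjusted curve is \eqn{S_{other} \cdot S_{pca}^{rel\_effect}}.
#'
#' @param overall [weibull_survival()] overall-survival curve.
#' @param other_cause [weibull_survival()] other-cause survival curve;
#'   must dominate `overall` pointwise.
#' @param rel_effect multiplier on the cancer-specific hazard (0.79 by
#'   default; 1 leaves the curve unchanged).
#' @return A function of time returning adjusted overall survival.
#' @export
psa_era_adjust <- function(overall, other_cause, rel_effect = 0.79) {
  stopifnot(inherits(overall, "weibull_survival"),
            inherits(other_cause, "weibull_survival"),
            is.numeric(rel_effect), rel_effect > 0)
  # check dominance on a practical horizon
  tt <- seq(0.5, 40, by = 0.5)
  if (any(surv_prob(other_cause, tt) < surv_prob(overall, tt) - 1e-12)) {
    stop("other-cause survival must be >= overall survival pointwise ",
         "(cancer-specific survival would exceed 1)")
  }
  function(t) {
    s_oth <- surv_prob(other_cause, t)
    s_pca <- surv_prob(overall, t) / s_oth
    s_oth * s_pca^rel_effect
  }
}

#' Multiply the hazard of a Weibull curve by a constant
#'
#' Under proportional hazards a Weibull keeps its shape: multiplying the
#' hazard by `ratio` maps the scale to \eqn{\lambda \cdot ratio^{-1/k}},
#' equivalently \eqn{S'(t) = S(t)^{ratio}}. Used to push the
#' healthy-screenee correction (cohort participants are healthier than the
#' general population the tool addresses) onto a fitted curve: `ratio` > 1
#' strictly shortens life expectancy.
#'
#' @param w a [weibull_survival()] object.
#' @param ratio positive hazard multiplier.
#' @return The adjusted [weibull_survival()] object.
#' @export
apply_relative_mortality <- function(w, ratio) {
  stopifnot(inherits(w, "weibull_survival"), is.numeric(ratio), ratio > 0)
  weibull_survival(shape = w$shape, scale = w$scale * ratio^(-1 / w$shape))
}
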