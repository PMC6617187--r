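---
title: "Methods: integrated risk and life-expectancy triage for prostate biopsy referral"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated risk and life-expectancy triage for prostate biopsy referral}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcatriage)
```

## The problem

Whether a man with a mildly elevated PSA should be referred for prostate
biopsy is not a question about cancer risk alone. Prostate cancer is a
disease of predominantly elderly men, many of whom will die *with* rather
than *of* it; a high probability of finding clinically significant cancer
(csPCa, ISUP grade ≥ 2, i.e. Gleason ≥ 3+4) is only actionable if the
man's remaining life expectancy leaves room for treatment to pay off.
`pcatriage` couples four quantities for one man at the point of a
primary-care visit:

1. the probability of csPCa on a current biopsy,
2. his life expectancy (LE) without csPCa,
3. his LE with undetected, untreated csPCa, and
4. the absolute LE gain expected from curative treatment,

and converts them into one of three recommendations (*no referral*,
*shared decision*, *refer*) against consensus threshold bands.

## Risk of significant cancer on biopsy

The risk component is a maximum-likelihood logistic regression of csPCa
versus everything else (no cancer and indolent ISUP 1 cancer together form
the negative class). Predictors follow primary-care availability: age,
PSA, %freePSA (the free-to-total ratio), and optionally the digital rectal
examination result, a rough three-level prostate-volume estimate (25, 40,
60 cc), family history and IPSS. PSA, %freePSA and the volume category
enter as $\log_2$ values centred at the training-cohort mean of the
$\log_2$ value; the centering constants are stored inside the model object
so prediction needs no access to the training data. The log-2 scale makes
a coefficient read as "the log-odds change per doubling", which is the
natural unit for PSA.

The default *basic model* (age + PSA + %freePSA) mirrors the deliberate
practicality trade-off of GP-facing calculators: DRE-based predictors
raise discrimination but are less uniformly available. Both predictor sets
are supported by `fit_cspca_model()`.

No published coefficients exist for this model family, so the package
ships a *reference model* (`reference_risk_model()`) fitted on the seeded
default synthetic cohort described below. It makes the command-line tool
usable out of the box and is clearly labelled a synthetic-data fit. A
consequence worth stating: for the worked example of a 65-year-old with
PSA 4.0 ng/mL and %freePSA 17%, the reference model predicts a risk of
about 4.6%, not the 9% a model fitted on real screening data produces.
The synthetic generator reproduces outcome-conditional *marginals* only;
the real covariate correlation structure is not recoverable from printed
tables, and we make no attempt to fake it.

## Model-selection metrics

`concordance_index()` is the case/control ranking probability with
prediction ties counted one half, computed via mid-ranks (identical to
all-pairs counting, and cross-checked in the tests against both a
brute-force oracle and `survival::concordance`). `ipa()` is the scaled
Brier score $\left(1 - Brier_{model}/Brier_{null}\right)\times 100$,
sensitive to calibration as well as discrimination.
`bootstrap_optimism()` implements internal validation: refit on each
resample, score the refit on the resample and on the original data, and
subtract the mean difference ("optimism") from the apparent concordance.
Replicates whose resample collapses to a single outcome class or fails to
fit are skipped and counted; more than 10% skipped aborts the run rather
than silently biasing it.

`net_benefit()` and `decision_curve()` quantify clinical utility: at a
threshold probability $t$ (the risk at which a patient is indifferent
about biopsy), $NB = TP/n - \frac{t}{1-t}\,FP/n$. The comparator is the
default strategy *biopsy if PSA ≥ 3.0 ng/mL*, whose classification is
fixed but whose harm weight still varies with $t$. The grid is 3–10% in
steps of 0.5% — fine enough for a smooth curve at negligible cost. A
`biopsies_avoided_per_1000` column accompanies the curve.

## Life expectancy as a Weibull curve

All survival curves are summarised as two-parameter Weibull survival
functions $S(t) = \exp\{-(t/\lambda)^k\}$, for three reasons: registry
curves of elderly male cohorts are well approximated by one; the mean
(the life expectancy) is closed-form, $LE = \lambda\,\Gamma(1 + 1/k)$;
and a proportional-hazards adjustment keeps the family closed — scaling
the hazard by $c$ maps $(k, \lambda) \mapsto (k, \lambda c^{-1/k})$,
equivalently $S'(t) = S(t)^c$. That last identity carries the whole
treatment-benefit and healthy-screenee calculus.

**Fitting published curve points.** Registry reports print survival
proportions at a handful of times, not individual data.
`fit_weibull_to_points()` uses the complementary log-log linearisation
$\log(-\log S) = k \log t - k \log \lambda$ and ordinary least squares;
exact Weibull input is inverted exactly, and 1% multiplicative noise on
8 points perturbs the recovered shape by well under 0.1 in median (the
test suite measures this by simulation).

**Untreated-csPCa curves.** These come stratified by age band (55–59 …
75+), Charlson comorbidity index (0, 1, 2+) and broad Gleason band (5–7,
8–10). Two adjustments bridge registry strata to the screen-detected
csPCa population:

* *Gleason re-mixing* (`gleason_mixture_adjust()`): the mixture
  $S(t) = \sum_b w_b S_b(t)$ with the screening cohort's Gleason-band
  weights replaces the registry's composition. The mixture is not itself
  Weibull; it is tabulated and refitted (`refit_weibull()`).
* *PSA-era adjustment* (`psa_era_adjust()`): pre-PSA-era registry curves
  overstate cancer mortality in the screening era. Assuming independent
  competing hazards, overall survival factorises as
  $S_{overall} = S_{other} \cdot S_{pca}$; the cancer-specific hazard is
  scaled by 0.79 (the published era effect on prostate-cancer mortality),
  i.e. the adjusted curve is $S_{other}\cdot S_{pca}^{0.79}$. The
  decomposition needs an explicit other-cause curve, supplied per stratum
  (for instance fitted from a life table); whether the original analysis
  adjusted the hazard or the cumulative incidence is not documented — we
  adjust the cause-specific hazard, which is the standard reading.

The shipped reference strata fix the shape at $k = 1.4$. That value is
not arbitrary: inverting the gain law $gain = LE\,(hr^{-1/k}-1)$ at each
published (LE, gain) pair — (12.3, 1.6), (10.9, 1.5), (9.7, 1.3) years
under HR 0.84 — yields $k \in [1.3, 1.5]$ in all three cases, and the
acceptance tests verify this inversion. At $k=1.4$ exactly, the 12.3 and
9.7 strata reproduce their printed gains to one decimal; the 10.9 stratum
gives 1.45 y, a rounding-boundary case consistent with its implied
$k \approx 1.35$. Charlson-0 values for ages 65–69/70–74/75+ carry the
published 12.3/10.9/9.7 years; the remaining cells of the default target
grid are plausible synthetic extensions, monotone in age and comorbidity.

**LE without csPCa.** `fit_weibull_regression()` is a censored-ML Weibull
accelerated-failure-time model (via `survival::survreg`): log scale
linear in age (centred at 65) and Charlson indicators, common shape.
Cohort-entry exclusions (first-round csPCa, other life-threatening
malignancies; skin cancer retained) are applied by an auditable tagged
filter, `filter_survival_cohort()`. Missing Charlson values are completed
by single-pass predictive mean matching (`impute_charlson()`): regress
the numeric score on age and vital status among complete records, then
draw each donor uniformly from the five nearest predicted means. Full
multiple imputation with pooling would add between-imputation variance
that a single covariate in a survival fit does not exercise at this
scale; we document the simplification rather than pretend to pooling.

**Healthy-screenee correction.** Screening participants are healthier
than the population a national life table describes.
`fit_relative_mortality()` computes life-table expected deaths along each
man's follow-up (attained age advancing annually, fractional final year
pro-rated) and fits a Poisson regression of observed deaths with log
expected deaths as offset, adjusted for age (centred at the cohort mean)
and Charlson category. The returned ratio is reference-population over
cohort mortality; `apply_relative_mortality()` pushes it onto the fitted
curve by the proportional-hazards rescaling, shortening LE so that the
prediction refers to a general-population man rather than a trial
participant.

Life expectancy is the *unrestricted* Weibull mean by default. Because
extrapolating a curve fitted on a 15–20-year follow-up window to extreme
ages is unreliable, `weibull_mean(w, restrict_years = 25)` provides a
restricted-mean variant behind an explicit argument.

## Treatment benefit

The benefit of curative treatment is taken from randomised trials of
treatment versus observation as a single all-cause-mortality hazard
ratio: PIVOT 0.84 (95% CI 0.70–1.01) as the primary estimate, SPCG-4 0.74
(0.62–0.87) and ProtecT 0.93 (0.65–1.35) for sensitivity analysis
(`trial_effects()`). The HR is applied uniformly — the trials found no
significant subgroup differences by age or comorbidity, and their sizes
prohibit meaningful subgroup effects — so on a Weibull curve the absolute
gain is the closed form

$$gain = LE \cdot (hr^{-1/k} - 1),$$

zero at $hr = 1$ and strictly decreasing in $hr$; the tests verify it
against numerical integration of the two curves. Gains are displayed in
whole months, rounded half away from zero (1.63 years → 20 months).
`sensitivity_across_trials()` tabulates the three trials; the gain
ordering is always the reverse of the HR ordering.

## Decision rules

The consensus bands are: risk of csPCa 5–10%, life expectancy 10–15
years, treatment benefit 1–2 years (`decision_thresholds()`). Each value
is classified *below / within / above* its band. The plain reading —
"all below: don't refer; any above: refer" — does not survive contact
with its own worked examples: a 75-year-old with Charlson 2+ can have a
csPCa risk of 15% (above the band) and still be a clear non-referral
because both his life expectancy and his expected benefit are below
their bands. The implemented rule set is therefore *benefit-led*:

1. all three below → no referral;
2. risk below (and benefit not clearly above) → no referral;
3. benefit below **and** LE below → no referral, whatever the risk;
4. benefit above (risk at least in band) → refer — risk and benefit lead
   even when LE is below 10 years (the *override*, flagged in the
   output);
5. risk above (with some expected benefit) → refer;
6. nothing below and at least one criterion at or past its band midpoint
   → refer (the consensus-band reading of the favourable worked case,
   where all three criteria are favourable but none strictly exceeds its
   band);
7. otherwise → shared decision.

The LE criterion is judged on LE *without* csPCa — the man's
competing-risk horizon; the untreated-csPCa LE is displayed but not
thresholded, since the 10–15-year band conventionally refers to general
life expectancy. The rules are property-tested for monotonicity: on a
dense grid, increasing risk or gain never moves the advice away from
referral.

## Synthetic data: what it emulates and what it cannot

No individual-level screening, registry or trial data are shipped or
downloadable here; the generators in `cohort_config()` /
`generate_biopsy_cohort()`, `generate_survival_cohort()`,
`generate_life_table()` and `generate_survival_points()` reproduce the
*study conditions* so that every code path is exercised honestly:

* **Biopsy cohort** (default n = 3616): outcome prevalences 75/16/9%;
  per-outcome log-normal PSA (medians 4.0/5.1/7.8 ng/mL) and %freePSA
  (0.22/0.17/0.12) with spreads matched to the printed interquartile
  ranges via $\sigma = \log(q_{75}/q_{25})/(2 \Phi^{-1}(0.75))$; ages
  centred at 66/67/68 (truncated 55–75); abnormal-DRE rates 31/41/66%.
  Covariate-outcome association is induced purely by outcome-conditional
  sampling — enough for fitting and metrics machinery, but it carries no
  within-outcome covariate correlations. Passing tests therefore
  demonstrate correctness of the machinery, not real-data performance.
  `generate_logistic_cohort()` adds a structural variant (known logistic
  coefficients) for parameter-recovery tests.
* **Survival cohort** (default n = 19247): Weibull AFT with shape 1.6,
  intercept 3.4357 (log years), age effect −0.035/y, Charlson effects
  −0.20/−0.45, censoring uniform over 14–20 years. These defaults were
  calibrated once so the cohort shows 10-year overall survival ≈ 81%,
  ≈ 38% deaths and median follow-up ≈ 15 years (IQR ≈ 12–17.5) — the
  printed margins of the screening cohort.
* **Life table**: Gompertz hazards $h(a) = \alpha e^{0.09 a}$ with
  $\alpha = 4.85\times10^{-5}$, chosen so the default cohort/life-table
  pair exhibits the published healthy-screenee contrast of ≈ 1.6 (the
  actual life-table values are not printed anywhere; the contrast is the
  condition that matters). The shipped reference LE model stores the
  ratio actually fitted on the seeded pair, 1.602.
* **Survival points**: exact Weibull tabulations (years 1–20) per
  age-band × Charlson stratum at shape 1.4 with the LE targets above, so
  curve-fitting round-trips exactly.

All generators are bit-reproducible under their seed.

## Numerical choices and degenerate inputs

* Logistic fitting uses `stats::glm.fit` (IRLS, max 100 iterations);
  (quasi-)separation is detected via the fitted-probability warning or a
  coefficient beyond ±15 on the transformed scale, and reported with the
  most implicated predictor rather than returned as a garbage fit.
* Survival points with $S \in \{0, 1\}$, non-positive times or
  non-monotone survival are rejected before the cloglog regression.
* `psa_era_adjust()` verifies other-cause survival dominates overall
  survival on a 40-year grid before decomposing.
* Expected-death computation errors out when the life table does not
  cover an attained age, rather than extrapolating silently.
* Bootstrap resamples that lose an outcome class or fail to fit are
  skipped and counted; >10% skipped is an error.
* Ties in concordance count one half, exactly (mid-ranks).
* Problem sizes in the test suite: parameter-recovery runs use cohorts
  of 6,000–19,000, the optimism bootstrap 50–200 replicates on cohorts
  of 100–2,500. These sizes give Monte-Carlo error comfortably inside
  the asserted bounds while keeping the default suite around half a
  minute.

## Known limitations

* The shipped risk model is a synthetic-data fit; absolute risks for real
  patients require refitting on a real biopsy cohort via
  `fit_cspca_model()` and the CSV interfaces.
* Treatment effects date from trials with decades-old treatment
  protocols; the HR is applied uniformly with no subgroup structure.
* The era adjustment assumes independent competing hazards.
* Unrestricted Weibull means extrapolate beyond observed follow-up;
  prefer the restricted variant for men at the extremes.
* Quality of life, metastasis-free survival and MRI-based diagnostic
  pathways are out of scope.
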