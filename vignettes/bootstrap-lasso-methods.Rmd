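---
title: "Bootstrap-stabilized LASSO for psychosocial screening consequences: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap-stabilized LASSO: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcqlasso)
```

## The problem

Population screening for liver disease can burden participants
psychologically even when the medical result is benign. The
Psychological Consequences Questionnaire (PCQ, negative-consequence
form) measures that burden as a total score (0–36) with emotional
(0–15), physical (0–12) and social (0–9) dysfunction subscales, the
total being the sum of the three. Survey studies of screening cohorts
ask which respondent characteristics — comorbidity burden, social
support, subjective social status, health literacy, satisfaction with
care, sociodemographics — predict these outcomes, among ~24 candidate
predictors on heterogeneous scales.

With modest samples (hundreds of respondents), skewed floor-heavy
outcomes, and correlated candidates, a single stepwise or penalized fit
is fragile. `pcqlasso` implements the bootstrap-stabilized LASSO
workflow used for this design:

1. **Penalized engine.** Linear LASSO,
   $\min_\beta \frac{1}{2n}\lVert y - X\beta\rVert_2^2 +
   \lambda\lVert\beta\rVert_1$, by cyclic coordinate descent on
   standardized predictors, with the penalty chosen by 10-fold
   cross-validation at the MSE-minimizing grid point (`lambda_min`).
2. **Stability layer.** One hundred case-bootstrap resamples per
   outcome; the cross-validated LASSO is re-run on each; a predictor is
   *relevant* when its coefficient at that resample's `lambda_min` is
   nonzero, and *selected* when relevant in at least 80% of resamples.
3. **Final inference.** The cross-validated LASSO is refit per bootstrap
   on the selected set only; coefficients are averaged across bootstraps
   (zeros included), their bootstrap standard deviation serves as the
   standard error, and 95% intervals are mean ± 1.96·SE. Model fit is
   summarized by bootstrap-averaged RMSE and MAE, with the model called
   *well fitted on average* when RMSE is below the outcome's sample SD.
4. **Descriptives and the group contrast.** A sample-characteristics
   table and a tie-corrected Mann–Whitney U comparing the total PCQ
   between positively and negatively screened respondents.

## Conventions that matter

**Objective scaling.** The \(1/(2n)\) convention makes
\(\lambda_{\max} = \max_j |x_j^\top y|/n\) the smallest all-zero
penalty; the default grid is 100 log-spaced values from
\(\lambda_{\max}\) down to \(10^{-3}\lambda_{\max}\) (appropriate for
the n ≫ p regime here; both are arguments).

**Standardization and back-transformation.** Columns are centered and
scaled to unit *population* SD (the \(1/n\) variance convention) so the
penalty treats predictors comparably; reported coefficients are always
back-transformed to original units
(\(\beta^{raw}_j = \beta^{std}_j / s_j\)), and raw-scale predictions
agree with standardized-scale predictions to numerical precision.
Zero-variance columns (possible in bootstrap resamples of rare
binaries) are dropped from the fit and reported as exact zeros.

**Penalty choice.** `lambda_min`, not the 1-SE rule, is used — the
minimal cross-validated penalty. Among exact ties the largest (sparsest)
penalty wins. Folds are assigned by a seeded shuffle with sizes
differing by at most one, re-randomized per bootstrap from a child seed.

**Seeding.** A master seed yields, through one draw of `sample.int`,
one child seed per bootstrap; the selection stage and the refit stage
derive the same children, so both stages see identical resamples. The
pipeline additionally derives one seed per outcome, so single-outcome
runs reproduce the corresponding slice of a full run.

**Missing data.** Complete-case analysis per outcome: each model uses
rows complete on its outcome and all candidate predictors. No
imputation is performed anywhere.

**Relevance threshold.** The comparison is inclusive: frequency exactly
0.80 selects. Raising the threshold can only shrink the selected set.

**Confidence intervals and significance.** The normal-approximation
interval on the bootstrap coefficient distribution is the default
(percentile intervals are available via `conf_method`). A coefficient
is flagged significant when its interval excludes zero; an endpoint
exactly at zero counts as covering. Report tables round coefficients,
intervals and fit metrics to 2 decimals and standard errors to 3.

**Fit metrics.** RMSE and MAE are computed in-sample on each
bootstrap's fitting sample and averaged; RMSE ≥ MAE always (Jensen).
Out-of-bag alternatives were considered and left out of the default
because the averaged in-sample metrics are what the reporting
convention compares against the outcome SD.

**Mann–Whitney U.** U is computed from midranks (ties count half). The
reported statistic belongs to the first group — by convention the
positively screened one; the complementary statistic is stored too,
since U_x + U_y = n₁n₂. For n₁·n₂ ≤ 400 the two-sided p-value is exact,
from a dynamic-programming enumeration of the permutation distribution
of the rank sum conditional on the observed ties; otherwise the normal
approximation with tie and continuity correction is used.

## The synthetic generator

Real survey data for this design are not bundled, so the package ships
a generator that reproduces the statistical structure the analysis
assumes, and every test runs on it.

**Predictors.** Each of the 24 candidates is driven by a latent
standard normal sharing a single factor with loading 0.3 (mild positive
collinearity — the regime where the LASSO's multicollinearity handling
matters). The marginal mechanism per variable: clipped normal for
continuous scales (e.g. age 62.37 ± 12.26), rounded clipped normal for
ordinal scales with published mean/SD (e.g. subjective social status
7.00 ± 1.70), latent-normal thresholding at fixed category
probabilities for categorical items (e.g. social support
poor/moderate/strong at 31.4/48.3/20.3%), and Bernoulli thresholds for
binaries. The positive screening result defaults to 4% prevalence. The
factor loading is a free parameter, not an estimate of the real
cohort's correlation structure. Category probabilities for items whose
source tables publish only one tail (e.g. the share dissatisfied) are
completed with plausible mass on the satisfied end; they are defaults,
not data.

**Outcomes.** Each subscale is a latent Gaussian linear model —
intercept, planted effects, a respondent-level noise component shared
across subscales, and a subscale-specific component — rounded and
clipped into its scale range; the total is the subscale sum, so the
scoring identity holds by construction. The default planted truth is
the six predictors of the published final models at their published
magnitudes (severity of comorbidities, subjective social status, social
support, age, partnership, health-literacy application), all other
effects zero.

**Calibration.** The nine noise parameters (three intercepts, three
shared and three specific SDs) were fixed once by moment matching
(Nelder–Mead on a large fixed simulation) so that the *observed* —
i.e. post-round-and-clip — subscale means and SDs and the total-score
SD reproduce the published sample values (total ≈ 6.4–6.8 mean, ≈ 8.6
SD; emotional 3.26/4.43; physical 2.27/3.08; social 1.24/2.05). The
published subscale means do not sum exactly to the published total mean
(complete-case sets differ per scale); the generator honours the
subscale moments and lets the total follow from the identity.

**What the generator does and does not emulate.** It reproduces the
marginal moments, the floor-heavy right skew, the subscale sum
identity, mild predictor collinearity, a ~4% positive-screen rate, and
MCAR missingness on request. It does *not* emulate item-level response
processes, informative missingness, the real cohort's correlation
matrix, or measurement error in the predictor indices. Two structural
consequences matter when reading test results:

* *Attenuation.* Matching the floor-heavy marginals forces large latent
  noise, and the floor/ceiling clipping then attenuates observable
  regression slopes to roughly half the planted latent magnitudes.
  Fitted coefficients on generator data are therefore expected to sit
  well below the planted values — a property of the data mechanism, not
  a bug in the estimator (the package's noise-free and low-noise tests
  recover effects essentially exactly).
* *Power.* At n = 487 with the calibrated noise, only the largest
  planted effect (comorbidity severity) is comfortably above the
  reliable-selection boundary of the 80% rule; the weaker published
  magnitudes (social support, age, partnership) correspond to
  |t| ≈ 1.3–2.5 and are selected intermittently. Conversely,
  cross-validating on bootstrap resamples lets duplicated rows span
  training and validation folds, which biases `lambda_min` downward and
  inflates selection of noise predictors that happen to correlate with
  the outcome in the realized sample. The test suite measures both
  phenomena at study scale rather than hiding them; the strict
  stability claims hold in the strong-signal and low-noise regimes the
  module tests exercise.

## Degenerate inputs and edge rules

A constant response makes \(\lambda_{\max}=0\) and raises a
"degenerate response" error. A bootstrap resample with constant outcome
is redrawn once, then dropped with the frequency denominator reduced. A
training fold with constant outcome only triggers a warning (its MSE is
still computable). An empty selected set falls back to intercept-only
bootstrap models, flagged in reports. Coordinate descent declares
convergence when the largest standardized-coefficient update in a sweep
falls below 1e-7 (cap 1e5 sweeps, warning on non-convergence); a debug
mode re-runs a reference R implementation that asserts the objective is
non-increasing sweep by sweep.

## Problem sizes used by the tests

Module tests run at n = 100–300 with B = 5–40 and shortened penalty
grids, chosen so each block isolates one property; the
acceptance-style suite runs the full study conditions (n = 487,
B = 100, k = 10, 24 candidates, 10 replicate pipelines for the
calibration properties) and the generator checks at n = 10,000. These
sizes are the package's choices for exercising every claim at desk
scale.

## Known limitations

* No post-selection inference correction: the bootstrap intervals are
  the procedure's own convention and inherit the optimism of selecting
  and estimating on the same resamples. The package reproduces the
  procedure and documents this rather than replacing it.
* `lambda_min` on bootstrap resamples overselects (see above);
  complementary-pairs stability selection or frozen-fold variants are
  out of scope.
* The exact U p-value is conditional on observed ties, as is standard;
  with heavy ties and tiny groups it can differ visibly from the
  normal approximation — the switch at n₁·n₂ = 400 favours exactness.
* PCQ item counts (5/4/3 at item range 0–3) are inferred from the
  subscale maxima; the scoring function takes `n_items` for other
  conventions. Prorated scoring of partially missing subscales is
  opt-in, never the default.
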