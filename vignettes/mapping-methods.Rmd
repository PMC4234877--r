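---
title: "Mapping QLQ-C30 to EQ-5D-3L utilities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping QLQ-C30 to EQ-5D-3L utilities: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eq5dmap)
```

## Why a bounded, inflated model

EQ-5D-3L utilities under the UK TTO tariff live on [−0.59, 1].  In
practice the distribution observed in cancer trials is left-skewed,
often multimodal, and carries a point mass at 1 (respondents in full
health) with a very small fraction of states worse than death.  A
Gaussian regression of utility on QLQ-C30 domain scores ignores all of
this: it predicts outside the valid range and systematically
over-predicts at poor health states, where most of the decision-relevant
uncertainty sits.

`eq5dmap`'s core model treats the response as a three-part mixture.
After flooring the handful of negative values at zero (defensible when
they are a fraction of a percent of observations — the floor count is
recorded on every fit), utility `y` is

* exactly 0 with probability `p0`,
* exactly 1 with probability `p1`,
* otherwise Beta-distributed in its mean/precision parameterization,
  `y ~ Beta(mu * phi, (1 - mu) * phi)`, where
  `mu = plogis(X beta)` (logit mean link) and `phi = exp(W delta)`
  (log dispersion link).

The beta density in this parameterization is
`f(y | mu, phi) = Gamma(phi) / (Gamma(mu phi) Gamma((1-mu) phi)) *
y^(mu phi - 1) (1-y)^((1-mu) phi - 1)`; `moments_to_shapes()` converts
between it and the shape form by the method of moments.  At the trial
scale of the motivating lung-cancer datasets (means near 0.6–0.75, SDs
near 0.23–0.29) the implied second shape parameter is below one — the
signature of boundary-heavy, non-normal data and the reason a bounded
likelihood is worth its extra machinery.

## Estimation

The inflated likelihood separates: boundary membership is a multinomial
observation (continuous / zero / one), independent of the beta
parameters.  `zoib()` therefore estimates

* the inflation part in closed form (constant `p0`, `p1`, the default)
  or by multinomial logit via `nnet::multinom` when covariates are given
  (`inflation = ~ ...`).  With under half a percent of zeros in data of
  this kind, covariate-driven `p0` is not identifiable, which is why the
  constant model is the default;
* the beta part by BFGS with analytic score functions, on internally
  column-scaled designs.  Starting values come from OLS on
  `logit(y*)` with `y*` shrunk off the boundaries by
  `(y (n-1) + 0.5) / n`, plus a second start at the zero vector; the
  better optimum is kept.  Convergence is a relative log-likelihood
  change below 1e−8 (tighter internally); standard errors come from the
  inverse observed information.

Repeated visits per subject are handled one of two ways, chosen
explicitly:

* **default** — fixed-effects fit with cluster-robust (sandwich)
  standard errors by subject (`subject = "subject_id"`);
* **optional** — a subject-level normal random intercept on the mean
  linear predictor (`random_intercept = TRUE`), integrated by
  Gauss–Hermite quadrature (15 nodes by default).  Both are defensible
  readings of a "mixed-effects" bounded regression; the package makes
  the choice visible rather than silent.

Predictions are either the conditional beta mean `mu` (default) or the
full mixture mean `p1 + (1 - p0 - p1) mu` (`type = "mixture"`), the
model's expected utility.  Both are inside [0, 1] for any covariate
values.  Whether a published "predicted mean" is conditional or mixture
is usually unstated; exposing both avoids committing to one reading.
The interval transform `rescale_to_unit()` (mapping [a, b] to [0, 1])
is provided for users who prefer rescaling to flooring, but it is not
applied by default: rescaled utilities change the meaning of a QALY, so
the floor-at-zero convention is the default analysis path.

## The comparators

Five benchmarks share the same fit/predict contract:

* **linear** — Gaussian ML, optional analytic random intercept
  (`lme4`, ML not REML).  Unbounded predictions; the validation layer
  counts the out-of-range share.
* **quadratic** — linear plus squared PF, EF, SF, SL, DI.  Scores are
  divided by 100 before squaring purely for conditioning; the scaling is
  stored and re-applied at prediction time.
* **tobit** — two-limit censored normal ML at (0, 1): normal-CDF mass
  terms at the limits, density between.  Default predictions clamp the
  latent mean into [0, 1]; the latent scale is available by flag.
* **quantile (LAD)** — minimizes the check loss.  No linear-programming
  solver is assumed in the environment, so the solver is iteratively
  reweighted least squares with a shrinking smoothing floor, polished by
  BFGS on a log-sum-exp–smoothed check loss (smoothing 1e−6).  Median
  solutions can be non-unique; the solver returns one minimizer, and the
  tests compare achieved loss, not coefficients, against a direct
  minimizer.
* **CLAD** — Powell's estimator by iterative LAD: refit on the subset
  whose predictions lie strictly inside (0, 1) until the active set
  stabilizes (cap 50 iterations).  The estimator is consistent but not
  efficient, so standard errors use a nonparametric cluster bootstrap
  (200 resamples by default; `boot_se = 0` skips them in
  simulation loops).  The lower censoring point is 0 by default and
  configurable, since censoring "worse than death" values to 0 versus
  −0.59 is an analysis choice.

Reduction identities pin the implementations together: with no censored
observations the tobit equals the Gaussian fit, with no active censoring
CLAD equals LAD, and with no squared terms the quadratic equals the
linear model.  All three are enforced in the test suite to optimizer
tolerance, and the tobit likelihood is additionally cross-checked
against `survival::survreg`'s interval-censored Gaussian fit.

## The trial simulator

The motivating patient-level datasets are not publicly deposited, so the
package ships a simulator whose presets reproduce their *published
structure*: a large poor-prognosis profile (`"topical"`: 670 subjects,
2038 monthly observations, utility mean 0.61, SD 0.29, modest ceiling)
and a small better-prognosis profile (`"soccar"`: 130 subjects, 1002
observations, mean 0.75, SD 0.23, 25% of responses at utility 1).

Construction (Vale–Maurelli): each of the 16 variables (utility + 15
domains) gets Fleishman cubic coefficients matching a target skewness
and excess kurtosis; correlated standard normals are drawn with an
*intermediate* correlation matrix solved per pair from the cubic
product-moment identity (root-finding; for strongly opposite-skewed
pairs the identity is non-monotone and the smallest-magnitude root is
taken); the transforms then deliver the target product-moment
correlations.  Within-subject dependence enters through a shared
subject-level component of the latent normals (intra-class correlation
0.5 by default).  Visit counts follow a truncated geometric adjusted to
the exact published observation total, emulating dropout.

Choices a user should know about:

* **Per-variable moment targets are not published.**  They are derived
  from the scaled Beta distribution matching each variable's configured
  mean/SD on its range — a one-line, reproducible rule — and clipped to
  the numerically computed Fleishman feasibility boundary.  Domain
  means/SDs and the full correlation matrix are preset choices (a
  one-factor structure anchored so the domain–utility correlations span
  0.32 for financial impact to 0.69 for physical function, positive for
  function scales, negative for symptoms).
* **Boundary structure.**  The top `p_one` fraction of latent utilities
  becomes the mass at 1 (rank-based, preserving the correlation
  structure), a small `p_zero` fraction sits at 0 and a `p_neg` fraction
  (0.15%, matching the published "3 of 2038" scale) takes small negative
  values.  The continuous remainder is affinely rescaled to its implied
  conditional moments and clamped to (0, 1); spill joins the zero mass.
* **Distortion is measured, not corrected.**  Truncating domains to
  [0, 100] and the boundary construction distort moments and
  correlations slightly (correlations of the most skewed symptom
  domains by up to ~0.1); every simulated dataset carries a
  `moment_report` attribute with achieved-versus-target values.

What passing tests on these data do **not** show: the simulator's
conditional law of utility given the domains is close to Gaussian by
construction, unlike real trial data.  Two consequences are documented
rather than hidden.  First, the AIC advantage of the inflated beta model
over the Gaussian fit — clear on data genuinely generated by an
inflated-beta process, and the direction reported in the motivating
study — does not appear on the Fleishman trials, where the boundary
entropy dominates.  Second, under this misspecification the beta ML
mean can be biased upward by a few hundredths while OLS, unbiased for a
conditional mean regardless of distribution, is not.  Real-data
performance claims require real data.

Survival: overall survival is exponential by inverse CDF,
`OS = -log(1 - U) / lambda`.  Progression-free survival is
`PFS = OS * V^(1/kappa)`, which guarantees `PFS < OS` for every subject
— the constraint the QALY decomposition needs — with `kappa` derived
from the two hazard rates (`kappa = l_os / (l_pfs - l_os)`) so that
`E[PFS] = 1 / l_pfs` exactly.

## Validation and uncertainty

`fit_metrics()` reports RMSE, MAE, R² (squared Pearson correlation of
observed and predicted by default — the common convention in the mapping
literature — with `1 − SSE/SST` always reported alongside), the
predicted mean with the descriptive `SD(pred)/sqrt(n)` standard error,
and the share of predictions outside [0, 1].  R² is reported plainly
in-sample and flagged undefined for constant predictions.
`prediction_bands()` gives the fraction of predictions within ±5% … ±30%
of the observed value; observations with observed value 0 have no
relative error and are excluded from denominators but counted.
`health_state_curve()` orders observed states from 11111 to 33333 and
tabulates observed versus predicted means, with a Poor/Good
over-prediction summary at a configurable cut state (default 11321;
22222 is the natural cut for better-prognosis profiles).
AIC is attached only to in-sample reports: comparing AICs across
datasets is meaningless, and `cross_validate()` refuses to do it.

For Monte-Carlo uncertainty, `coverage_study()` repeatedly simulates,
fits, and checks whether a 95% CI for the predicted mean contains a
target.  The CI that makes this calibrated is not the descriptive
band: `predicted_mean_ci()` uses an influence-function standard error
for the mean mixture prediction that propagates coefficient and
inflation uncertainty together with covariate sampling, clustered by
subject.  The test suite verifies ≈95% coverage for a correctly
specified model at 500 replicates — the calibration anchor for the
whole coverage machinery — and coverage near zero for an unreachable
target.

## QALYs

`patient_qaly()` is utility × years.  `group_qaly()` is the
pre/post-progression decomposition
`u_pre * E[PFS] + u_post * (E[OS] − E[PFS])`, with no discounting and
no half-cycle correction.  `qaly_psa()` draws survival times and
utility means per arm per replicate (10,000 by default; reducible) and
returns means with percentile intervals for each arm and the
between-arm difference.  Mean survival is the area under the simulated
exponential curve over its full support; a restricted horizon is
available through administrative censoring.  Pre/post-progression
utility assignment from visit data uses strictly-before-progression
visits by default.

## Numerical notes and limitations

* Problem sizes in the shipped tests: 200 replicates for
  coefficient-coverage at the 2038-observation trial scale, 500
  replicates at n = 500 for CI calibration; both chosen to make binomial
  Monte-Carlo error small relative to the bands being checked.
* The dispersion design `W` defaults to an intercept (one common
  precision); there is no published subset of domains driving the
  variance, and parsimony wins until a user states one
  (`dispersion = ~ ...`).
* Degenerate inputs fail loudly: all-boundary responses, rank-deficient
  designs, empty CLAD active sets, infeasible beta variances and
  infeasible Fleishman moment pairs all raise errors naming the
  violated condition.
* The tariff table is a plain-text resource (`inst/extdata/`); other
  additive three-level value sets can be swapped in by file.
  Worse-than-death modelling beyond the floor-at-zero convention, EQ-5D-5L,
  other national tariffs, and cost-side analysis are out of scope.
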