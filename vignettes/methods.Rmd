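---
title: "Scoring scales and estimating their reliability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring scales and estimating their reliability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumscores)
```

## The measurement model

Everything in this package rests on the classical true-score decomposition
$Y = T + E$ and its factor-analytic form. For $p$ indicators of a single
construct,

$$x_j = \nu_j + \lambda_j f + \varepsilon_j, \qquad
  f \sim N(0, 1), \quad \varepsilon_j \sim N(0, \theta_j),$$

with mutually uncorrelated errors that are uncorrelated with $f$. The
implied covariance structure is $\Sigma = \Lambda\Phi\Lambda' + \Theta$.
Three nested constraint levels are supported by `cfa_spec()`:

| constraint | loadings | unique variances | intercepts |
|---|---|---|---|
| congeneric | free | free | free |
| tau-equivalent | equal within block | free | free |
| parallel | equal within block | equal within block | free |

Without a mean structure these are the *essentially* tau-equivalent and
*essentially* parallel models; passing means with `strict_means = TRUE`
additionally equates intercepts within blocks (*strictly* variants). The
constraint sets are nested, so the minimized discrepancy is monotone:
$F_{par} \ge F_{tau} \ge F_{cong}$ on any data set — a property the test
suite asserts on random fixtures.

A unit-weight sum score $1'x$ has mean $1'\mu$ and variance $1'C1$, the grand
sum of the item covariance matrix (`composite_moments()`). Which reliability
formula is appropriate for that sum depends on which constraint level fits:
coefficient $\alpha$ is the model-based reliability under (essential)
tau-equivalence, $\omega_T$ under the congeneric model.

## Reliability estimators

* **Coefficient alpha** (`coefficient_alpha()`):
  $\alpha = \frac{p}{p-1}\bigl(1 - \sum_j s_{jj} / 1'S1\bigr)$ — pure
  covariance arithmetic, no model fit.
* **Omega-total** (`omega_total()`):
  $\omega_T = (\sum_j \hat\lambda_j)^2 / [(\sum_j \hat\lambda_j)^2 +
  \sum_j \hat\theta_j]$ from a congeneric fit. With three indicators the fit
  is just-identified and `spearman_three_indicator()` gives the closed form
  $\lambda_1 = \sqrt{c_{12} c_{13} / c_{23}}$ (cyclically), which the ML
  fitter reproduces to 1e-8.
* **Factor-score and sum-score reliabilities**
  (`nicewander_quantities()`): the squared correlation of regression-method
  factor scores with the true factor is $\lambda' C^{-1} \lambda$; for the
  unit-weight sum it is $(1'\lambda)^2 / (1'C1)$. Their correlation follows
  from $\mathrm{cov}(\hat f, 1'x) = \lambda' C^{-1} C\, 1 = 1'\lambda$ and
  $\mathrm{var}(1'x) = 1'C1$, giving
  $\rho(\hat f, 1'x) = 1'\lambda \big/ \sqrt{\lambda'C^{-1}\lambda \cdot
  1'C1}$. We derive this denominator from the covariance algebra directly;
  it is the only form that is a correlation (bounded by 1) and it reproduces
  the published worked values for both test blocks.
* **Composite reliability** (`rae_composite_reliability()`): when each
  component has a known reliability, the *reduced* covariance matrix replaces
  each diagonal entry by variance × reliability; the ratio of reduced to raw
  grand sums estimates the composite's reliability.

All estimators work in the raw-score (covariance) metric. Correlation-matrix
input must be converted explicitly with supplied SDs (`hs_scaled_moments()`
shows the pattern); nothing is rescaled silently.

## Numerical choices in the ML fitter

`fit_cfa()` minimizes
$F_{ML} = \log|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \log|S| - p$
with `stats::nlminb()` and analytic gradients.

* **Unique variances** are parameterized as $\theta_j = 10^{-6} +
  e^{t_j}$: always positive, with estimates at the floor flagged as Heywood
  cases on the result and as warnings.
* **Factor correlations** use a tanh transform, keeping each in $(-1, 1)$;
  if a parameter combination still implies a non-PD $\Sigma$, the objective
  returns a large penalty and the optimizer backs off.
* **Starts and restarts.** The start pools within-block covariances into a
  common loading guess. If the first run fails the convergence check, up to
  10 deterministic jittered restarts are tried and the best discrepancy
  kept. Restarts are skipped once a solution passes the gradient check —
  on well-posed problems the analytic start converges directly, and
  repeated fitting (bootstraps, cross-validation replications) stays fast
  without changing any result.
* **Convergence** is declared from the gradient itself (max absolute
  gradient below 1e-6, or the optimizer's own success code with gradient
  below 1e-4), because `nlminb` sometimes reports "singular convergence" at
  a perfectly flat optimum when its relative tolerance is tight.
* **Identification**: factor variances are fixed at 1 and the first loading
  of each factor is oriented positive. Three indicators per lone congeneric
  block are required.

`fit_indices()` uses the $\chi^2 = (n-1)\,F_{ML}$ convention throughout —
fit-index dialects differ across software, so one convention is fixed and
documented. RMSEA's 90% CI inverts the noncentral $\chi^2$ CDF in the
noncentrality parameter by bisection (tolerance 1e-6) at probabilities .95
and .05. CFI/TLI compare against the diagonal (independence) baseline. SRMR
is the root mean square of residuals standardized by sample SDs *including*
the diagonal terms; `srmr_type = "off_diagonal"` gives the other common
dialect. Models with $df \le 0$ are reported as saturated.

## Structural methods and their latent metric

Four ways to relate scored scales to a predictor $z$:

1. **Method 1/2** (`method_sum_regression()`): OLS of unit-weight composites
   on $z$. `d` divides the raw slope by the composite's total-sample SD
   ($n-1$ denominator); `beta` further multiplies by the SD of $z$ — with a
   single predictor, `beta` is the correlation.
2. **Method 3** (`croon_factor_score_regression()`): per-block congeneric
   fits, regression scoring weights $W = \Phi\Lambda'\Sigma^{-1}$, then the
   method-of-moments (Croon) correction
   $\widehat{\mathrm{var}}(f) = (W\Lambda)^{-1}(WSW' - W\Theta W')
   (W\Lambda)^{-T}$ and
   $\widehat{\mathrm{cov}}(f,z) = (W\Lambda)^{-1} W c_{xz}$, which undo the
   attenuation of regressing estimated factor scores directly
   (`naive_factor_score_regression()` provides that uncorrected baseline —
   its slope is attenuated by exactly the factor-score reliability).
3. **Method 4** (`simultaneous_latent_regression()`): one joint ML fit of
   the measurement model plus the latent regression, with $z$ as an
   error-free single-indicator variable; SEs from the inverse observed
   information (numerical Hessian of the discrepancy, scaled by $2/(n-1)$).

The scale of a latent outcome is a genuine design choice. `fit_cfa()` fixes
factor variances at 1 (convenient for reliability work), but a regression
outcome's variance is a function of the slope, so that convention cannot
apply. Both Method 3 and Method 4 therefore use *marker* identification —
first loading per block fixed at 1 — so their raw slopes share the metric of
each block's first indicator and agree asymptotically; the test suite checks
agreement within ±0.02 at $n = 5000$. `d` divides by the model-implied
latent outcome SD.

Method 3's standard errors come from a nonparametric bootstrap over persons
(default 499 resamples, seeded), since its sampling distribution depends on
the two-stage construction. The 95% interval is the normal-theory
$B \pm 1.96\,SE_{boot}$, which always brackets the point estimate; at
$n = 1000$ it agrees with Method 4's information-based SE within 25%.
Significance is never reported as a star — estimates, SEs, and 95% CIs only.

## What the generator simulates — and what it does not

`simulate_items()` draws factors from $N(0, \Phi)$, builds items as
$\nu + \Lambda f + \varepsilon$, and optionally discretizes each item onto
$1 \ldots L$ by equal-probability thresholds of its own normal marginal.
Criterion variables are built at the factor level,
$c = r\,f + \sqrt{1-r^2}\,\epsilon$, so the configured validity is the true
factor-level correlation and the attenuation identity
$r_{obs} = r \cdot \sqrt{\text{sum-score reliability}}$ holds exactly in
expectation — the test suite verifies it at $n = 50{,}000$.

The generator emulates the *structure* of real scale data, not its blemishes:
no item skew beyond what discretization induces, no minor nuisance factors,
no missing data, no differential item functioning. Passing tests therefore
show that the estimators recover what they claim under their own model; they
do not show robustness to misspecification.

`crossval_validity()` reproduces a split-sample design: per replication,
fit the one-factor model on a random calibration subset (default 200
persons), score the holdout with the *calibration* weights and calibration
means — reusing calibration standardization is the defensible reading of
"scoring a new sample with fixed coefficients" — then correlate factor
scores and raw sums with each criterion. Replications whose calibration fit
fails are skipped and counted, never imputed. The default emulated design
(4000 persons, 14 six-point items, 100 replications, strongest criterion
validity set so the attenuated validity is about .34) mirrors a published
personality-data demonstration; the package asserts the *equality* of
factor-score and sum-score cross-validated validities (difference < .02),
not the .34 itself.

`wilks_convergence()` evaluates the classical result that differentially
weighted and unit-weighted sums of the same items correlate ever more
highly as the number of items grows: for each $p$ it draws random positive
weight vectors and computes the correlation from the model-implied
covariances of an exchangeable pool ($r = 0.3$ by default), so the only
Monte-Carlo noise is in the weights.

## Problem sizes and seeds used by the shipped tests

All stochastic tests fix seeds and state their sizes in code: parameter
recovery at $n = 5000$, score-reliability simulation at $n = 20{,}000$,
covariance convergence at $n = 50{,}000$, $\chi^2$ calibration with 200
replications at $n = 500$, null-coverage and effect-ordering checks with 100
replications each, and the cross-validation harness at its full 100
replications. The whole suite runs in well under a minute on one core.

## Known limitations

* Plain ML only: no robust (sandwich) corrections, no ordinal/WLSMV
  estimation, no bifactor or hierarchical omega decompositions.
* The Croon correction is implemented for a single exogenous predictor;
  multi-predictor structural models are out of scope.
* Confidence intervals for $\alpha$ and $\omega_T$ are not provided.
* Exact reproduction of fit statistics from named external datasets requires
  the user to supply those raw data; the shipped fixtures carry only the
  published summary tables (covariances, correlations, SDs, reliabilities).
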