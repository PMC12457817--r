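---
title: "Doubly robust estimation of average causal effects with cross-fitting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Doubly robust estimation of average causal effects with cross-fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

`drcfit` estimates the average causal effect (ACE) of a binary exposure $X$
on a continuous outcome $Y$ given a confounder vector $W$,

$$\psi = E[Y^{X=1}] - E[Y^{X=0}],$$

under the usual identification assumptions (exchangeability given $W$,
consistency, positivity), so that $\psi = E[E(Y|X=1,W) - E(Y|X=0,W)]$.
The motivating setting is *high-dimensional confounding*: many confounders
relative to the sample size (tens of confounders at $n$ in the hundreds),
most of them continuous, possibly with non-linear and interacting effects on
both exposure and outcome. Simple parametric adjustment is then at risk of
misspecification bias, while naively plugging machine-learning fits into the
g-formula gives invalid inference. The package therefore implements the two
standard doubly robust (DR) estimators, which remain consistent if either
nuisance model (outcome regression $E[Y|X,W]$ or propensity score
$P(X=1|W)$) is consistently estimated, and which accommodate data-adaptive
nuisance estimation:

* **AIPW** (`aipw()`), the one-step estimator
  $\hat\psi = \tfrac1n \sum_i \hat E_1(w_i) - \hat E_0(w_i)
  + \tfrac{X_i(Y_i - \hat E_1(w_i))}{\hat g(w_i)}
  - \tfrac{(1-X_i)(Y_i - \hat E_0(w_i))}{1 - \hat g(w_i)}$;
* **TMLE** (`tmle()`), which updates the initial outcome predictions along a
  logistic fluctuation submodel driven by the clever covariate
  $H = X/\hat g - (1-X)/(1-\hat g)$ and then substitutes, so the estimate
  always respects the bounds implied by the observed outcome range.

Both report Wald 95% confidence intervals $\hat\psi \pm 1.96\,\widehat{SE}$
with the standard error taken from the efficient influence function (EIF):
the estimated variance is the sample variance of the per-record EIF terms
divided by $n$, i.e. $\widehat{var}(\hat\psi) = \frac{1}{n(n-1)} \sum_i
(t_i - \hat\psi)^2$. For TMLE the fluctuation solves the EIF score equation,
and `tmle()` polishes the fluctuation coefficient with Newton steps so the
empirical mean of the EIF is zero to below $10^{-8}$ on every input.

### TMLE numerical choices

The outcome is mapped to $[0,1]$ by its observed range $(a, b)$; initial
predictions are mapped with the same bounds and clipped to
$[10^{-4}, 1-10^{-4}]$ (the outcome itself is inside $[0,1]$ by construction
and is not clipped — clipping it would leave a spurious residual in the
score equation). A single intercept-free fluctuation parameter is used on
the scaled scale with the clever covariate as regressor and the logit of the
scaled prediction as offset; a linear fluctuation is not implemented. Under
cross-fitting the scaling bounds are taken from the full sample (fold-wise
ranges need not contain the fold's predictions), targeting is performed
within each held-out fold, and the point estimate is the fold-size-weighted
mean of the fold-specific substitution estimates.

## Super Learner

Nuisance models are fitted with a from-scratch Super Learner
(`fit_super_learner()`): every base learner is fitted on each of 10
fold-complements (folds stratified by the response for the propensity
model, so sparse exposure cannot empty a class at $n = 200$ with ~25%
exposure prevalence), and non-negative meta-weights summing to one minimize
the cross-validated loss — mean squared error for the outcome model, mean
negative Bernoulli log-likelihood for the propensity model — over the
probability simplex (accelerated projected gradient with backtracking; the
best single learner is a feasible fallback, so the ensemble never does worse
in CV loss than any library member). Learners that error are dropped with a
warning and the weights renormalize over the remainder.

Two library presets are shipped:

* **reduced** — GLM; GLM with all pairwise interactions (declines when the
  expanded design is wider than 90% of the training sample); ridge GLM with
  a small fixed penalty ($\lambda = 0.01$), a shrinkage stand-in for a
  Bayesian GLM that avoids a sampling dependency; GAM with cubic regression
  splines ($k = 4$ per smooth, declining when the basis outgrows the
  sample); and lasso (`glmnet`, $\alpha = 1$).
* **full** — the reduced library plus two flexible non-parametric learners
  implemented in the package because no suitable implementation exists in
  the supported dependency set: gradient-boosted depth-1 trees (100 stumps,
  shrinkage 0.1, quantile split grids) and a single-hidden-layer neural
  network (5 tanh units, weight decay 0.1, BFGS). Random-forest and
  MARS-style members were considered and omitted for the same dependency
  reason; the boosted trees cover the tree-based role in the library.

The lasso learner's default hyperparameter scheme picks its penalty by
5-fold `cv.glmnet` **once per Super Learner training set** and freezes it
for the internal cross-validation refits. This is a deliberate runtime
choice (a full-design simulation fits the ensemble tens of thousands of
times) with negligible effect on the ensemble: the frozen penalty is
re-selected for every training complement at the cross-fitting level, where
independence actually matters.

Propensity scores are truncated at the empirical 5th and 95th percentiles of
the predicted vector (`truncate_ps()`, linear-interpolation quantiles —
fixed for bit-reproducibility). Under cross-fitting, truncation is applied
within each held-out prediction vector by default, preserving the
out-of-sample character of the predictions; pooled truncation and no
truncation are available via the `truncate` argument. Note that truncation
at fixed percentile positions perturbs a fixed fraction of records at any
sample size, so it trades a small persistent bias for variance control; the
double-robustness property tests therefore run untruncated.

## Cross-fitting

`crossfit()` implements single K-fold cross-fitting: folds of near-equal
size stratified by exposure; nuisance ensembles fitted on each complement
and evaluated on the held-out fold; AIPW pools the out-of-fold per-record
terms, TMLE targets within folds as described above. The standard error in
both cases is the sample variance of the pooled out-of-fold EIF values
centred at the overall estimate, divided by $n$ (a fold-averaged variance is
not provided). Replicates in the evaluation layer are seeded per replicate,
so results are invariant to the number of parallel workers, and the data
seed is independent of estimator settings, so every estimator variant sees
identical datasets.

## The synthetic world

Five data-generating mechanisms emulate the confounding structure of an
early-life birth-cohort study in which the exposure is a dichotomized (top
quartile, hence the ~25% exposure prevalence default) inflammation marker
and the outcome a standardized cardiovascular measure. Confounders are
generated sequentially, each from a parametric model given previously
generated variables: a small set ($p = 14$, 13 continuous and 1 binary) and
a large set ($p = 87$, 78 continuous and 9 binary). Exposure follows a
logistic model and the outcome a Gaussian linear model; *simple* variants
(`simple-1`, `simple-2`) use main effects only, *complex* variants add
two-way confounder–confounder interactions to both models,
exposure–confounder interactions to the outcome model, and non-linear terms
(squares and $\log(|z|+1)$) for designated continuous confounders.
`complex-1a` and `complex-1b` scale all interaction coefficients by 2 and 4.

The fitted coefficients of the original cohort are not publicly available,
so the shipped coefficient values are package defaults, drawn once under a
fixed build seed from documented distributions (see `R/dgm-defaults.R`) and
then versioned: dependence coefficients U(−0.3, 0.3) (continuous) and
U(−0.5, 0.5) (binary, prevalences U(0.05, 0.5)); exposure and outcome main
effects scaled by $1/\sqrt p$ so the linear predictors have roughly unit and
0.6 sd regardless of the confounder count; outcome residual sd 0.8 (the
outcome is standardized in the emulated study); interaction and non-linear
coefficients at 0.3× the main-effect scale before the mechanism multiplier.
The interacting pairs (round(10p/14) confounder pairs, round(5p/14)
exposure–confounder columns) and transformed columns are likewise fixed,
versioned draws. Everything is overridable through
`dgm_params(overrides = ...)`. Because the coefficients are stand-ins, a
green simulation test establishes that the *estimators and the pipeline*
behave as designed under this stated world — not that any specific numeric
result of the original cohort analysis is reproduced. The generator also
does not emulate missing data, measurement error, or categorical confounders
in the presets (a multinomial family is implemented for overrides, emitted
as indicator columns).

### Calibration

Two quantities are calibrated rather than fixed:

* **Outcome intercept** (`calibrate_intercept()`): the marginal mean of $Y$
  is kept at 0. The mean is linear in the intercept with unit slope, so one
  large simulated draw (default $10^6$, simulated in chunks of $10^5$ to
  bound memory at $p = 87$) yields the exact correction up to Monte Carlo
  error; the routine verifies on a fresh draw (tolerance 0.005).
* **Exposure main effect** (`calibrate_effect()`): chosen so a correctly
  specified parametric AIPW analysis (with the study-wide propensity
  truncation — without it, occasional extreme weights give the power curve
  heavy tails that dominate the calibration error) rejects the null of no
  effect in ~80% of replicates at the target sample size, keeping power
  (and hence coverage comparability) constant across scenarios. Because the analysis
  model contains the exposure main effect, adding $d$ to it shifts every
  replicate's estimate by exactly $d$ and leaves the standard error
  unchanged; a single batch of replicates at a reference effect therefore
  traces the entire empirical power curve, and the bisection runs on a
  smoothed normal-approximation power estimate built from the replicate
  errors and standard errors — a variance-reduction device that removes the
  re-simulation noise of a naive search. If the smoothed solution's raw
  empirical rejection proportion deviates from the target by more than 0.03
  (the design's own precision for "approximately 80%"), the bisection falls
  back to the empirical step curve. The rejection test is invariant to the
  intercept, so the intercept is recalibrated once at the solution, which is
  equivalent to recalibrating at every update.

The **true ACE** per mechanism (`true_ace()`) is computed empirically in a
single very large sample (default $10^6$) as the mean difference of the
noise-free potential-outcome conditional means — using conditional means
rather than noisy potential outcomes removes residual-noise Monte Carlo
error at identical expectation. For simple mechanisms the truth equals the
exposure main effect to numerical precision (collapsibility), which the test
suite exploits as an oracle.

## Evaluation

`run_scenario()` executes replicates (the design grid in `scenario_grid()`:
5 mechanisms × 4 sample sizes = 20 scenarios; 2000 replicates in the full
design so the binomial MCSE of a 95% coverage stays below 0.5%), and
`performance()` reports bias, relative bias, empirical SE, model-based SE,
relative model-SE error, coverage and power with Monte Carlo standard
errors. The model-based SE is the square root of the mean estimated
variance (the convention of the standard simulation-study tutorials; the
arithmetic mean of SEs differs only in higher order). Replicates in which
AIPW degenerates — SE above 10× the median SE, or absolute estimate above
5× the absolute median estimate — are excluded by `stability_filter()`
before performance is computed; the filter is applied to AIPW only by
default (TMLE is bounded and does not produce such replicates), exclusion
counts are always reported, and estimator errors are tracked separately as
failed replicates.

## Worked example

```{r, eval = FALSE}
library(drcfit)

params <- calibrate_effect(dgm_params("simple-1"), n = 500, seed = 1)
truth <- true_ace(params, seed = 1)

d <- generate_dataset(params, n = 500, seed = 7)
estimate_ace(d, method = "tmle", folds = 5, library = "reduced", seed = 7)

res <- analyze(d, method = "aipw", folds = 5, library = "full", seed = 7)
res$ps_summary # always inspect overlap
```

## Known limitations

* Binary exposures and the ACE difference only; no continuous or
  multi-valued exposures, and no weighting-only or outcome-only production
  estimators (g-computation and IPW exist internally as baselines/oracles).
* No missing-data handling: inputs containing `NA` are refused.
* Single cross-fitting only — no double cross-fitting and no aggregation of
  estimates over repeated random splits; results at small n can depend on
  the split seed.
* The full library's flexible learners are intentionally compact
  implementations; they are adequate for the simulation design but are not
  tuned, and hyperparameter search is out of scope by design.
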