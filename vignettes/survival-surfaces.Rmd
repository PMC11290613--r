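---
title: "Methods: survival surfaces and their estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survival surfaces and their estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survsurf)
```

## The object being estimated

Everything in this package funnels into one object: the conditional
probability surface

$$\hat S(t \mid x, \mathbf{z}_0) \quad\text{or}\quad
  \hat F_1(t \mid x, \mathbf{z}_0),$$

the predicted survival (or cause-1 cumulative incidence) as a function of
time $t$ and one continuous covariate $x$, with all other covariates held at
a fixed profile $\mathbf{z}_0$. The 2D contour plot is a top-down view of
this surface; the 3D rendering shows the same object with confidence bands
as semitransparent layers. The surface is a *conditional* prediction, not a
marginal one: it answers "what does the model predict for a subject with
these adjuster values as $x$ varies", which is the question the plot is
designed to make visible.

The default profile holds continuous adjusters at their sample median and
categorical adjusters at their most frequent level (frequency ties broken by
sorted level order, a deterministic choice that keeps renders reproducible).
Any entry can be overridden.

## Estimators

### Cox proportional hazards

`fit_cox()` maximizes the partial likelihood by Newton–Raphson on a
column-centered design. Ties use the Efron approximation by default —
the de-facto standard of mainstream Cox software — with Breslow selectable.
Convergence requires both a relative log-likelihood change below $10^{-12}$
and a score below $10^{-6}$; with quadratic convergence this costs one or two
extra iterations over looser rules and buys agreement with reference
implementations at the $10^{-6}$ level that the test suite asserts.

The baseline cumulative hazard is the Breslow estimator
$\hat\Lambda_0(t) = \sum_{t_j \le t} d_j / \sum_{i \in R(t_j)} e^{x_i\hat\beta}$
(reference covariate $x = 0$), regardless of the ties method used in the
partial likelihood. With $\hat\beta = 0$ it is exactly the Nelson–Aalen
estimator. The variance of $\log\hat\Lambda(t\mid x)$ combines the
Breslow-increment variance $\sum_j d_j/S_0(t_j)^2$ with the delta-method
term $q(t)^\top \hat V q(t)$, $q(t) = \sum_j (d_j/S_0(t_j))(x - \bar x(t_j))$
— the standard covariance-inclusive formula for Cox survival curves.

**Monotone likelihood.** When a covariate perfectly separates the risk
ordering the partial likelihood has no maximizer. The fitter raises an
explicit error once any $|\hat\beta_k| > 10$ while the maximizer is still
moving, rather than returning a huge coefficient that would silently produce
a meaningless near-0/1 contour. The score itself can vanish exponentially in
$\beta$ in these datasets, so the detector keys on "past the cap and not yet
settled" instead of a fixed gradient threshold.

Stratified fits multiply within-stratum partial likelihoods (shared
$\beta$, one baseline per stratum); strata without events contribute nothing
and are reported in a warning. Competing-event codes ($\ge 2$) under a plain
Cox fit are censored at their time — the cause-specific hazard convention —
with a warning pointing to `fit_fine_gray()`.

### Weibull (right- and interval-censored)

`fit_weibull()` uses the accelerated-failure-time parameterization
$S(t\mid x) = \exp\{-(t/(\lambda e^{x\gamma}))^k\}$, optimized over
$(\log k, \log\lambda, \gamma)$ by BFGS (relative tolerance $10^{-12}$,
starting from $\log k = 0$ and $\log\lambda$ at the log mean observation
time). The covariance is the inverse numerical Hessian (central differences,
step $10^{-5}$), mapped back from the centered to the raw covariate scale.
AFT is the convention of parametric survival regression; under proportional
hazards the mapping to log hazard ratios is $\beta_{PH} = -k\gamma$.

Interval-censored subjects contribute $S(L_i|x) - S(R_i|x)$ with
$S(\infty)=0$, exact times the density, and $L = 0$ handled as $S(0)=1$.
The difference is computed on the log scale (`log1p`) to survive narrow
intervals. Interval censoring is supported *parametrically only*; the
Turnbull nonparametric MLE is out of scope, and the model-selection guide
routes interval-censored studies to this Weibull likelihood.

### Fine–Gray

`fit_fine_gray()` estimates subdistribution log hazard ratios by a weighted
Cox-type Newton–Raphson (Breslow ties). Subjects who failed from a competing
cause stay in the risk set with weight $\hat G(t-)/\hat G(T_i-)$, where
$\hat G$ is the Kaplan–Meier estimate of the censoring distribution; the
left-limit convention matches the established competing-risks software this
is cross-checked against in the tests. With zero competing events every
weight is 1 and the fit coincides with a Breslow-ties Cox fit to numerical
precision — a reduction the test suite asserts at $10^{-8}$.

The covariance is the inverse *weighted observed information*. This is
approximate for Fine–Gray (the full variance estimator has additional terms
from the estimated weights); it is documented as such, and bootstrap
percentile bands via `surface_ci(method = "bootstrap")` are the recommended
alternative when band accuracy matters. The baseline subdistribution
cumulative hazard uses the weighted Breslow formula, which makes
$\hat F_1(t|x) = 1 - \exp(-\hat\Lambda_{10}(t)e^{x\hat\beta})$ monotone and
inside $[0,1)$ by construction.

### Backends

External models (random survival forests, deep survival networks, spline
hazards) are not reimplemented; they enter through `backend_adapter()` with
a `fit` and a `predict` hook. Outputs are clipped to $[0,1]$ and monotonized
(running minimum over time for survival, running maximum for incidence) with
a warning — the surface contract is enforced at the boundary so the renderer
can rely on it.

## Confidence bands

Delta-method bands are symmetric on the $\log(-\log S)$ scale (equivalently
$\log\hat\Lambda$), then back-transformed, so they always live in $(0,1)$;
for incidence the same transform applies to $1-\hat F_1$. The paper-standard
alternative scales (plain or log) can leave $[0,1]$; the complementary
log-log scale is the usual remedy and is the only scale offered. Cells where
the estimate is exactly 0 or 1 collapse to a point band. Bootstrap bands
resample subjects with replacement, refit the same model specification, and
take pointwise percentiles (fixed seed, at least half the resamples must
refit).

## Grids, lookup and rendering conventions

* **Covariate grid**: 100 equally spaced points over the observed range by
  default. No trimming is applied; a quantile-trim option (e.g.
  `trim = c(0.01, 0.99)`) exists for outlier-dominated axes, and a quantile
  grid strategy for heavily skewed predictors. Grids stretching beyond three
  times the observed range trigger an extrapolation warning, not an error.
* **Time grid**: the sorted unique observed event times with 0 prepended —
  the exact step structure of the semiparametric estimators, so the surface
  loses nothing to discretization. An equispaced grid can be passed for
  backends that are expensive per time point.
* **Hover lookup** (`value_at`): step lookup in time (last knot $\le t$,
  matching right-continuous step estimators) and linear interpolation in the
  covariate between adjacent grid rows. Queried at a grid node it returns the
  stored cell exactly; the interactive HTML embeds the same matrix at full
  (17 significant digit) precision and implements the same lookup, so hover
  values agree with `value_at()` to machine precision.
* **Color**: a perceptually uniform sequential palette, monotone in
  lightness, oriented so darker always means worse predicted outcome (dark =
  low survival; the scale reverses for cumulative incidence). Probabilities
  are displayed as percentages with one decimal; filled contours use 0.05
  probability bands by default (`level_step`). The marginal histogram is
  orange by default and shares the y axis with the contour panel.
* **Static export** renders through ggplot2/base graphics to PNG or SVG;
  identical inputs produce byte-identical SVG. Interactive export writes a
  single self-contained HTML file (embedded JSON payload + vanilla
  JavaScript canvas renderer, drag rotation in 3D) with no external fetches,
  so figures remain viewable offline and archivable alongside a manuscript.

## Data handling choices

Event coding is fixed at 0 = censored, 1 = event of interest, $\ge 2$ =
competing causes — the dominant convention in competing-risks software.
Rows with missing values in any role column are dropped (complete-case on
role columns only) with the count reported; no imputation is attempted.
Numeric adjusters with at most 10 distinct values are treated as categorical
unless overridden, which avoids silently modeling small-integer scores as
linear effects. In interval mode an empty cell or the token `Inf` in the
right-bound column means right-censored. Validation (`validate_dataset()`)
reports invariant violations as data with row indices rather than throwing.

## What the synthetic generators emulate — and what they do not

`gen_ph_weibull()` draws event times by inverse-CDF sampling from a
proportional-hazards Weibull model (default shape 1.5, scale 5: a mildly
increasing hazard typical of chronic-disease cohorts), standard-normal
covariates, and independent exponential censoring tuned by quadrature to a
target fraction (default 30%, a common mid-study censoring level).
`gen_competing()` specifies the cause-1 CIF directly as
$F_1(t|x) = 1-\{1-p(1-e^{-t})\}^{\exp(x\beta)}$, so the generating $\beta$
*is* the Fine–Gray estimand exactly — the classical route through
cause-specific hazards would make it only approximately so, muddying
recovery tests. `gen_interval()` observes latent PH-Weibull times only
through a fixed visit schedule. Uniform and bimodal predictor options exist
so the histogram panel can be exercised on skewed shapes.

These generators validate *estimation and rendering logic*, not realism:
covariates are independent, effects are linear on the log-hazard scale,
censoring is independent of covariates, and visit schedules are perfectly
regular. Passing tests therefore demonstrate correctness of the machinery
under the stated models, not robustness to model misspecification,
informative censoring, or messy real-world visit patterns.

## Problem sizes used by the test suite

The statistical checks run at desk scale, chosen so the whole suite
completes in a few minutes on one CPU while keeping Monte-Carlo noise well
inside the asserted margins: oracle agreement on 50 random small datasets
($n \le 30$); parameter recovery over 200 replicates each for Cox
($n = 300$), Fine–Gray ($n = 800$) and interval Weibull ($n = 500$); band
coverage over 200 replicates at three interior time points (where the true
median-covariate survival is 0.8, 0.6 and 0.4); 100 random surfaces for the
contract checks; 500 bootstrap refits for the variance cross-check.

## Known limitations

* Time-varying covariates, left truncation, cure fractions and multi-state
  models are out of scope.
* The Fine–Gray analytic variance is the inverse weighted information
  (approximate); use bootstrap bands for publication-grade uncertainty.
* Bands are pointwise, not simultaneous.
* Interval censoring is parametric (Weibull) only.
* One continuous predictor per surface; two-covariate surfaces
  (time × x₁ × x₂) are not supported.
* The concordance index is Harrell's variant; pairs with tied event times
  are not comparable. The Brier window truncates where the censoring
  survival $\hat G$ reaches zero.
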