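---
title: "Measurement heterogeneity and the external validation of prediction models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement heterogeneity and the external validation of prediction models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(measureval)
```

## The problem

A clinical prediction model is derived in one setting and applied in
another, and its predictors are rarely measured the same way in both.
Height may be protocolised in the derivation study and self-reported in
practice; a biomarker may come from different assays; imaging may be read
under different systematics. `measureval` studies what such *measurement
heterogeneity* — a different measurement procedure for the same predictor
at derivation and at external validation — does to the out-of-sample
performance of a logistic prediction model, isolating it from the two
usual suspects, overfitting and case-mix shift, which are deliberately
held fixed.

## The measurement model

Let $X$ denote the exact measurement of a predictor and $W$ the pragmatic
measurement actually available. The package links them through the general
linear measurement error model

$$W = \psi_y + \theta_y X + \varepsilon_y, \qquad
  \varepsilon_y \sim N(0, \sigma^2_{\varepsilon,y}),$$

where every parameter may depend on the outcome class $y$. Three familiar
error types are special cases, and `classify_spec()` places any
specification in this taxonomy:

* **random (classical)**: $\psi = 0$, $\theta = 1$,
  $\sigma^2_\varepsilon > 0$ — $W$ is mean-unbiased but noisy;
* **systematic**: $\psi \ne 0$ and/or $\theta \ne 1$, identical in both
  classes — $W$ is shifted and/or rescaled;
* **differential**: any parameter differs between cases and noncases —
  e.g. recall bias, or predictors measured more carefully in patients
  suspected of the outcome.

`measurement_spec()` stores the noise parameter as a **variance**
(`err_var`), and the nondifferential factor grids below are specified
directly on that scale. One deliberate exception: the canonical
*differential* presets specify the case-specific noise on the SD scale
($\sigma_{\varepsilon 1} \in \{0.5, 2\}$, i.e. variances $0.25$ and $4$,
against a noncase variance of $1$). This convention makes the differential
scenarios markedly asymmetric — cases measured four times more or four
times less precisely than noncases — which is what gives them their
distinctive calibration signatures; the helper `differential_presets()`
encodes it so users do not have to remember the scale switch.

## Performance measures

For a validation sample with outcomes $y$ and linear predictor
$lp = \hat\alpha_D + \hat\beta_D^T w$ transported from the derivation fit,
the package computes:

* the empirical **c-statistic** (`concordance()`), with ties counted half,
  and its **binormal approximation**
  $\Phi\{(\bar w_1 - \bar w_0)/\sqrt{s^2_{w_1} + s^2_{w_0}}\}$
  (`binormal_auc()`). Substituting the measurement-model moments for the
  $w$-moments yields the analytic error impact `delta_auc()`: random noise
  always costs discrimination, nondifferential systematic error costs
  nothing beyond its noise, and differential error can push the
  c-statistic either way;
* the **Brier score** and its exact decomposition
  $(y-p)^2 = (y-p)(1-2p) + p(1-p)$ into a calibration term (zero in
  expectation under perfect calibration) and a refinement term
  (`brier_decomposition()`); the refinement difference
  `expected_delta_brier()` is the expected within-sample accuracy cost of
  a pragmatic measurement;
* the **calibration slope** $b$ from the logistic recalibration
  $\mathrm{logit}\,P(y=1) = a + b \cdot lp$ (`recalibrate()`): $b = 1$ is
  ideal, $b < 1$ means predictions too extreme (overfitting-like), $b > 1$
  too moderate (underfitting-like);
* **calibration-in-the-large** (`calibration_in_the_large()`): the
  intercept of an intercept-only recalibration with $lp$ as offset;
  negative values mean systematically overestimated risk. It is reported
  on the raw logit scale and multiplied by 10 only in report rendering
  (`cmd_report()`), following the customary display convention;
* a **quantile-binned calibration curve** (`calibration_curve()`, deciles
  by default). Bins replace a loess smoother on purpose: they are
  assumption-free, deterministic and cheap inside a simulation loop; a
  smoother can always be layered on for presentation graphics.

A maximum likelihood logistic fit is weakly calibrated in its own sample
by construction ($a = 0$, $b = 1$, zero calibration term); every
departure seen at validation is therefore attributable to the transport.

## Data-generating mechanisms

The single-predictor population is
$\mathrm{logit}\, P(Y = 1 \mid X) = \log(4)\,X$ with $X \sim N(0,1)$ and no
intercept, so the event rate is 50% (about 1000 events per sample of
2000) and the generating model's c-statistic on the exact measurement is
approximately 0.80. The two-predictor populations use equicorrelated
standard-normal predictors with $\rho \in \{0, 0.5, 0.9\}$ and equal
coefficients 2.3 (2.1 when $\rho = 0.9$), chosen to hold the generating
discrimination at that same level so results are comparable across model
families. The 0.80 anchor is asserted (in the test suite) for the
single-predictor model only, where it is unambiguous.

Derivation and validation cohorts are independent draws from the *same*
population; only the measurement specifications differ. This is the
design's point: any performance drop is measurement heterogeneity, not
case-mix.

## The scenario engine

`run_replication()` performs one derivation-to-validation transport: draw
a derivation cohort ($n = 2000$), apply the derivation measurement
specifications, fit the model on $W_D$ by maximum likelihood
(`stats::glm.fit`, IRLS, relative-deviance tolerance $10^{-10}$, at most
100 iterations, no penalisation — shrinkage would blur the measurement
effect with an overfitting correction the design excludes), record
in-sample performance, then draw an independent validation cohort, apply
the validation specifications, and evaluate the *transported* linear
predictor $\hat\alpha_D + \hat\beta_D^T w_V$.

Fits that do not converge or show (quasi-)complete separation are flagged,
excluded from aggregation and counted — never silently redrawn, which
would bias extreme scenarios. At $n = 2000$ with ~1000 events separation
is essentially impossible; the machinery exists for pathological
configurations.

`run_scenario()` aggregates replications the way the results are
conventionally reported: mean (and SD) for the c-statistic,
calibration-in-the-large and Brier score, median (and SD) for the
calibration slope, whose replication distribution is right-skewed.

The full factorial grid (`build_grid()`) crosses
$\psi_V \in \{0, 0.25\}$, $\theta_V \in \{0.5, 1, 2\}$ and
$\sigma^2_{\varepsilon(V)} \in \{0.5, 1, 2\}$ with derivation noise
$\sigma^2_{\varepsilon(D)} \in \{0.5, 1, 2\}$ (derivation measurement
always random: $\psi_D = 0$, $\theta_D = 1$): 54 single-predictor
scenarios, and 162 each for the two-predictor families with both or only
the first predictor heterogeneous (a consistently measured predictor
keeps its derivation specification at validation). The differential
add-on family crosses the error site (derivation or validation), the
case-specific error SD $\{0.5, 1, 2\}$, $\theta_V$ and the
nondifferential-side variance — 54 more scenarios and 432 in total. The
grid composition of this family is a package design choice (only its four
presets are canonical); it is config-defined and replaceable.

```{r grid, eval = FALSE}
grid <- build_grid(read_run_config(
  system.file("extdata", "default_config.yaml", package = "measureval")))
length(grid) # 432
```

### Reproducibility

All randomness flows from one configuration seed. Each scenario receives
`seed + scenario index`; inside a scenario, a per-replication seed table
is drawn once (`replication_seeds()`), so summaries are independent of
execution order and any single replication can be reproduced in
isolation. `cmd_simulate()` appends one summary row per completed
scenario and skips completed ids on restart, making long grid runs
resumable and byte-reproducible.

### Large-sample contrast: error versus heterogeneity

`run_large_sample()` isolates the conceptual core in one large sample
(default $N = 10^6$): *re-estimating* the model on the pragmatic
measurement (within-sample measurement error) always restores slope 1 and
a zero Brier calibration term, however noisy the measurement — only its
discrimination and refinement suffer. *Transporting* coefficients across
measurement structures is what breaks calibration: noisier validation
measurements give $b < 1$ (overfitting-like), more precise ones $b > 1$
(underfitting-like), with the Brier calibration and refinement terms
moving in opposite directions.

## Numerical and design choices

* **Replication counts.** The canonical study design uses 10 000
  replications per scenario; the packaged tests and the acceptance script
  use 1000, at which the Monte Carlo standard error of every reported
  mean/median is an order of magnitude below the tolerances being checked
  (e.g. $\approx 0.001$ for a mean c-statistic). The defaults in
  `default_config()` keep 10 000.
* **Directional laws.** "Noisier validation ⇒ slope < 1, lower
  c-statistic; cleaner validation ⇒ slope > 1" is guaranteed only for
  purely random heterogeneity ($\theta_V = 1$). A rescaled validation
  measurement interacts: e.g. $\theta_V = 2$ with slightly cleaner
  validation noise can still give $b < 1$, since the slope behaves like
  $\theta_V/(\theta_V^2 s^2 + \sigma^2_{\varepsilon(V)})$ relative to the
  derivation attenuation. The property tests therefore assert the laws on
  the $\theta_V = 1$ cells, and the $\psi_V > 0 \Rightarrow$ negative
  calibration-in-the-large law on all cells.
* **Ties** in the c-statistic get half credit (midranks), the standard
  ROC-area convention.
* **Intercepts.** The generating models carry no intercept; the 50% event
  rate keeps every class-conditional quantity well estimated at $n=2000$.
* **Degenerate inputs.** Single-class samples, constant predictors,
  constant linear predictors and non-positive-definite correlation
  requests are rejected with explicit errors; tied prediction values
  collapse calibration-curve bins with a warning.

## What the generator does and does not emulate

The synthetic cohorts reproduce the study conditions exactly: normal
predictors, a correctly specified logistic outcome model, identical
populations in both settings, and linear-normal measurement error. Real
validation studies violate most of these — skewed or categorical
predictors, case-mix shift, model misspecification, heteroscedastic or
correlated measurement errors. Passing tests therefore demonstrate the
mechanics and direction of measurement-heterogeneity effects under clean
conditions, not their magnitude in any particular clinical dataset.
Known limitations, by design: no measurement-error correction methods, no
penalised estimation, no non-logistic links, no within-setting predictor
error beyond the stationary specs above.

## A worked example

```{r example, eval = FALSE}
spec <- scenario_spec(
  dgm = single_predictor_model(),
  derivation_specs = measurement_spec(err_var = 0.5),
  validation_specs = measurement_spec(err_var = 2),
  n_replications = 1000, seed = 42
)
run_scenario(spec)[, c("c_der_mean", "c_val_mean", "slope_median",
                       "citl_mean", "brier_val_mean")]
```

A model derived on precise measurements and validated on noisy ones loses
discrimination, and its predictions — calibrated at home — are far too
extreme abroad. The same machinery scaled over `build_grid()` with
`cmd_simulate()` reproduces the full scenario study; `cmd_report()`
renders the customary grouped tables (calibration-in-the-large ×10) and
slope figures.
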