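---
title: "Calibrated spline dose-response models for pooled matched case-control studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated spline dose-response models for pooled matched case-control studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolspline)
```

## The problem

Consortia routinely pool individual-level biomarker measurements from
several matched or nested case-control studies to gain power for
dose-response analyses — circulating 25-hydroxyvitamin D and colorectal
cancer is the archetypal example.  Two complications arise together:

1. **Laboratory heterogeneity.**  Each study assayed its specimens in its
   own laboratory, and assays for analytes such as 25(OH)D or sex hormones
   can disagree systematically by 20-40%.  Before pooling, each study's
   *local* measurement $W$ must be calibrated to a common *reference*
   laboratory scale $X$.  In practice a small subset of each study's
   stored control specimens (cases are too precious) is re-assayed at the
   reference laboratory, giving paired $(W, X)$ observations from which a
   study-specific calibration line $E(X \mid W) = a_s + b_s W$ is
   estimated.
2. **Nonlinearity.**  Forcing the log relative risk to be linear in the
   biomarker can badly distort inference when the true relationship bends.
   The package models the association with restricted cubic splines, so
   linearity becomes a testable hypothesis rather than an assumption.

`poolspline` fits, for pooled matched sets indexed by study $s$ and
stratum $j$,

$$\mathrm{logit}\,P(Y_{sji}=1 \mid X_{sji}, Z_{sji})
  = \beta_{0sj} + \beta_X^\top f(X_{sji}) + \beta_Z^\top Z_{sji},$$

where $f(\cdot) = (f_1, \dots, f_{K-1})$ is a restricted cubic spline
basis with $K$ knots ($f_1(x) = x$; the $K-2$ remaining components are
truncated cubics, linear beyond the boundary knots) and the
stratum-specific intercepts $\beta_{0sj}$ are eliminated by conditioning
on the number of cases in each matched set.  Under density sampling,
$\beta_X^\top\{f(x^*) - f(x^{**})\}$ is the log relative risk comparing
biomarker levels $x^*$ and $x^{**}$.

## Conditional likelihood with imputed biomarker values

For a stratum with $n$ cases and $m$ controls the conditional likelihood
contribution is the usual conditional-logistic expression, a sum over all
$\binom{n+m}{n}$ candidate case sets.  Since $X$ is unobserved outside the
calibration subsets, the package evaluates that likelihood at imputed
reference-scale values $\tilde X$, which is the first-order (Taylor)
approximation of the observed-data likelihood around the conditional mean
of $X$.  Two assumptions underpin this step and are *assumed, not
tested*: **surrogacy** (given $X$, $Z$ and the matched design, $W$ carries
no further outcome information) and the **calibration assumption** (given
$W$, the conditional mean of $X$ does not depend on $Z$).  The
approximation is best when the biomarker effect is moderate or the
measurement error variance is small; no runtime diagnostic of its
adequacy is attempted.

Three imputation strategies are provided:

* **full** — $\tilde X = \hat a_s + \hat b_s W$ for *every* subject of a
  local-laboratory study, including re-assayed controls;
* **internalized** — $\tilde X = X$ where observed, otherwise
  $\hat a_s + \hat b_s W$;
* **naive** — $\tilde X = W$ (no calibration; the negative control).

Calibration lines are fitted by OLS among the *re-assayed controls only*,
reflecting practice: case specimens are rarely available for re-assay,
and the package rejects calibration-flagged cases as a data error rather
than silently using them.  Controls-only estimates $\hat a_{s,co},
\hat b_{s,co}$ are not exactly consistent for $a_s, b_s$ when the
biomarker affects risk; the intercept error cancels inside the full
method's within-stratum contrasts (all subjects share the same imputation
line) but not inside the internalized method's mixed contrasts.  This is
why full calibration is the recommended default and why the internalized
method grows *more* biased as the calibration subset grows — an effect
the Monte-Carlo engine reproduces.

## Two-step estimation and the stacked sandwich variance

Estimation is two-step pseudo-maximum likelihood: (1) per-study OLS
calibration among re-assayed controls, (2) Newton-Raphson maximization of
the approximate conditional log-likelihood in $\beta$ with the
calibration estimates plugged in.  The optimizer uses the analytic score
and Hessian, starts at $\beta = 0$, halves steps whenever the
log-likelihood would decrease, and declares convergence when the largest
score component falls below $10^{-8}$ (at most 100 iterations;
non-convergence is flagged, never hidden).  The conditional-logistic
log-likelihood is concave, so this is reliable; a singular observed
information at the solution (separation / degenerate design) is reported
as an explicit error.  General $n{:}m$ sets are handled by enumerating
candidate case sets, guarded at $n+m \le 20$ and $10^6$ subsets — matched
sets in pooling projects are small, and a clear error beats a silent
approximation.

Plugging in $\hat a, \hat b$ makes the model-based inverse information
too small.  The package therefore stacks the estimating equations of both
steps, $\psi = (\psi_a, \psi_b, \psi_{\beta})$, and uses the M-estimation
sandwich $A^{-1} B A^{-\top}$ with $A = -\sum_u \partial\psi_u/\partial
\theta^\top$ and $B = \sum_u \psi_u \psi_u^\top$.  The independence unit
$u$ is the **stratum**: a re-assayed control contributes its OLS score
and its stratum's likelihood score to the *same* unit, so the
cross-correlation between calibration and likelihood estimating functions
is retained.  $A$ is computed analytically throughout — the
calibration block is the OLS information, the $\beta$ block the observed
information, and the cross block follows the chain rule through
$\tilde X = a + bW$ and $f'(\tilde X)$ (for the internalized method only
imputed subjects contribute).  A central-difference numeric mode backs
the analytic cross block in the test suite.  For the naive method the
system contains no calibration parameters and reduces to the
likelihood-only robust sandwich.

Wald tests (by default of all nonlinear coefficients jointly — the test
of "no nonlinearity") and log relative-risk curves derive from the
sandwich covariance.  Curve intervals are **pointwise**, not
simultaneous, and the curve is anchored at a user-chosen reference level,
by convention the minimum observed measurement.

## Spline conventions

* Knots default to 3 and may range from 3 to 7; the fit depends far more
  on the number of knots than on their placement.
* Data-driven knots are placed at empirical quantiles using the
  median-unbiased convention (`type = 8`); the choice among quantile
  definitions moves knots by a fraction of a data spacing and is fixed
  purely for reproducibility.
* The truncated-cubic components are *unscaled* (no division by
  $(t_K - t_1)^2$); an optional `normalize` flag is off by default.  Keep
  this in mind when comparing coefficients with software that rescales.
* In simulation mode all three methods are fitted on the *same fixed
  knots* (the N(0,1) quartiles by default) so their estimates are
  directly comparable; on real data, knots are computed from the imputed
  values of the chosen method unless supplied explicitly.

## What the synthetic generator emulates

`sim_config()` / `generate_pooled_data()` implement a four-study, 1:1
matched design.  Within study $s$, $(X, W, \epsilon)$ are multivariate
normal with $X \sim N(\mu_x, \sigma^2_x)$, $Var(W) = \sigma^2_{ws}$,
$E(X \mid W) = a_s + b_s W$ and $Cov(W, \epsilon) = 0$; disease status
follows the spline risk model with stratum intercepts
$\beta_{0sj} \sim N(0, 0.01)$ (a small variance keeps case and control
candidates roughly balanced, so stratum generation is fast without
changing the conditional inference, which eliminates the intercepts
anyway).  Each stratum draws candidate subjects until it holds at least
one case and one control, then keeps one of each uniformly at random —
implemented by reservoir sampling, which is distributionally identical.
The defaults — $a = (-3, 1, -1, 3)$, $b = (0.5, 0.75, 1.25, 1.5)$,
$\sigma^2_{ws} = (3.8, 1.7, 0.6, 0.4)$, 500 pairs per study — span a wide
range of local-laboratory shifts and scales whose explained-variance
ratios $b_s^2\sigma^2_{ws}/\sigma^2_x$ sit around 0.90-0.96, i.e.
moderately noisy but informative calibration.  Calibration subsets are
simple random samples of each study's controls,
$\max(3, \mathrm{round}(p \times \#\text{controls}))$ in size.

The generator deliberately does **not** emulate several features of real
pooled data: confounders $Z$ (the fitter supports them; the generator
omits them), $n{:}m$ matched sets, non-normal biomarker distributions,
nonlinear or heteroscedastic calibration relationships, and
laboratory drift within study.  Passing Monte-Carlo checks therefore
demonstrates correctness of the estimator under the stated data-generating
mechanism, not robustness to its violations.

Each replicate derives an independent seed from (master seed, replicate
index), so runs are reproducible and trivially parallelizable; replicates
with failed or non-converged fits are excluded from summaries and counted
separately.  Relative bias is summarized as the mean of
$(\hat\beta - \beta)/\beta$ in percent, coverage as the fraction of 95%
sandwich-based Wald intervals containing the truth.

## Worked example

```{r example}
cfg <- sim_config(pairs_per_study = 200, calibration_proportion = 0.2,
                  seed = 1)
d <- generate_pooled_data(cfg, seed = 1)
d

fit <- fit_dose_response(d, method = "full", basis = rcs_basis(cfg$knots))
summary(fit)

head(log_rr_curve(fit, grid = seq(-2, 2, by = 0.5), x_ref = 0), 4)
```

A `poolspline` shell command (installed under the package's `exec`
directory) exposes the same functionality as `fit`, `curve`, `simulate`
and `fixtures` subcommands for delimited-text workflows.

## Numerical and design choices, in brief

* Quantile type 8 for data-driven knots; explicit knot vectors accepted
  everywhere.
* Newton-Raphson from $\beta = 0$, tolerance $10^{-8}$ on the score,
  step-halving, max 100 iterations.
* Enumeration guard for large matched sets ($n + m \le 20$,
  $\le 10^6$ subsets).
* A study with every reference value observed and no calibration flags is
  treated as a reference-laboratory study; flagging at least one control
  keeps a fully re-assayed study on the calibration path (the full method
  then still imputes for all its subjects).
* Sandwich bread assembled analytically; numeric differentiation retained
  as a cross-check mode.
* Test-suite Monte-Carlo runs use 250-1000 replicates of the default
  scenario (problem sizes chosen to make the checks sharp yet quick);
  the acceptance script runs 1000 replicates per scenario.

## Limitations

* The applied-data workflow (decile-stratified calibration sampling,
  cohort-specific file layouts) is out of scope; calibration subsets in
  simulation are simple random samples.
* No bootstrap or simultaneous confidence bands; likelihood-ratio tests
  are invalid under pseudo-likelihood and are deliberately absent.
* Calibration is a single two-tier hierarchy (local to reference);
  errors-in-both-variables calibration is not provided.
* The Taylor approximation degrades for very strong biomarker effects
  combined with large measurement error; the package does not quantify
  this at runtime.
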