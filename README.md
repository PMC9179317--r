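# poolspline

Dose–response analysis of a continuous biomarker in **pooled
matched/nested case–control studies**, when the studies measured the
biomarker in different laboratories.

Pooling projects (circulating 25-hydroxyvitamin D and colorectal cancer
is the canonical example) face two problems at once: local-laboratory
measurements `W` are systematically shifted and scaled relative to a
common reference-laboratory measurement `X`, and the biomarker–risk
relationship may be nonlinear.  `poolspline` addresses both.  It fits

```
logit P(Y_sji = 1 | X, Z) = beta_0sj + beta_X' f(X_sji) + beta_Z' Z_sji
```

where `f` is a restricted cubic spline basis (K knots, K−1 coefficients;
`beta_X' {f(x*) − f(x**)}` is the log relative risk comparing two
biomarker levels) and the stratum intercepts `beta_0sj` are conditioned
out of the likelihood.  Since `X` is observed only for the re-assayed
controls (the *calibration subset*), each local-laboratory study gets an
OLS calibration line `E(X | W, control) = a_s + b_s W`, and the
conditional likelihood is evaluated at imputed reference-scale values:

* **full calibration** — impute `a_s + b_s W` for *all* subjects of a
  local-laboratory study (recommended);
* **internalized calibration** — use observed `X` when available,
  imputed values otherwise;
* **naive** — use `W` untouched (negative control: badly biased).

Estimation is two-step pseudo-maximum likelihood (calibration OLS, then
Newton–Raphson on the approximate conditional likelihood).  Standard
errors come from a **sandwich over the stacked estimating equations** of
both steps, with strata as independence units, so the uncertainty of the
estimated calibration lines propagates into the spline coefficients,
Wald tests (including the test of no nonlinearity) and pointwise
confidence bands of the fitted log relative-risk curve.  A Monte-Carlo
engine generates pooled 1:1 matched data with per-study multivariate
normal measurement structure and summarizes relative bias, empirical SD
and coverage per method.

## Worked example

```r
library(poolspline)
cfg <- sim_config(pairs_per_study = 200, calibration_proportion = 0.2,
                  seed = 1)
d <- generate_pooled_data(cfg, seed = 1)
fit_calibration(d)
#> Study-specific calibration models, E(X | W, control) = a + b W
#>  study      a    se_a      b    se_b resid_var n_cal
#>     s1 -3.218 0.08245 0.5247 0.01314   0.04383    40
#>     s2  1.032 0.04671 0.7669 0.03070   0.04609    40
#>     s3 -1.030 0.06743 1.3180 0.05412   0.07126    40
#>     s4  3.012 0.14140 1.5410 0.07066   0.09428    40

fit <- fit_dose_response(d, method = "full", basis = rcs_basis(cfg$knots))
summary(fit)
#> Calibrated spline dose-response fit (full calibration)
#> Knots: -0.67449, 0, 0.67449
#>
#>     estimate      se     lower    upper      z  p_value
#> bx1  -0.2671 0.09997 -0.463100 -0.07117 -2.672 0.007544
#> bx2   0.1196 0.06355 -0.005007  0.24410  1.881 0.059950
#>
#> Wald test of no nonlinearity: chi2 = 3.539, df = 1, p = 0.05995
```

The four generated studies have true calibration lines
`a = (−3, 1, −1, 3)`, `b = (0.5, 0.75, 1.25, 1.5)`; the fitted lines
above recover them from 40 re-assayed controls each.  `bx1` and `bx2`
are the linear and cubic-spline coefficients of the risk model (true
values −0.223 and 0.08 here): the linear trend is clearly detected,
while the Wald test finds only weak evidence of nonlinearity — as it
should, since the true nonlinear coefficient is small.  The fitted
dose–response curve with pointwise 95% bands:

```r
head(log_rr_curve(fit, grid = seq(-2, 2, by = 0.5), x_ref = 0), 4)
#>      x     log_rr      lower     upper
#> 1 -2.0 0.49753497 0.13846070 0.8566092
#> 2 -1.5 0.36398004 0.10269402 0.6252661
#> 3 -1.0 0.23042511 0.06670740 0.3941428
#> 4 -0.5 0.09750532 0.02970797 0.1653027
```

A thin shell interface is installed with the package
(`exec/poolspline`), with `fit`, `curve`, `simulate` and `fixtures`
subcommands over delimited text files; see `poolspline <cmd> --help`.

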