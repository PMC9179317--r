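test_that("stacked estimating equations sum to zero at the fitted parameters", {
  cfg <- sim_config(pairs_per_study = 120, calibration_proportion = 0.2)
  d <- generate_pooled_data(cfg, seed = 4)
  basis <- rcs_basis(cfg$knots)
  for (m in c("full", "internalized")) {
    fits <- fit_calibration(d)
    imp <- impute_biomarker(d, fits, m)
    mod <- poolspline:::ps_model(d, basis, imp$xtilde)
    nr <- poolspline:::ps_newton(mod)
    sw <- poolspline:::ps_sandwich(d, mod, basis, imp, fits, nr$beta, nr)
    expect_lt(max(abs(colSums(sw$U))), 1e-6)
    # dimension: 2 calibration parameters per local study + dose-response
    expect_equal(ncol(sw$U), 2L * cfg$S + 2L)
  }
})

test_that("analytic calibration cross-derivatives match numeric differentiation", {
  cfg <- sim_config(pairs_per_study = 100, calibration_proportion = 0.25)
  d <- generate_pooled_data(cfg, seed = 14)
  basis <- rcs_basis(cfg$knots)
  for (m in c("full", "internalized")) {
    fits <- fit_calibration(d)
    imp <- impute_biomarker(d, fits, m)
    mod <- poolspline:::ps_model(d, basis, imp$xtilde)
    nr <- poolspline:::ps_newton(mod)
    sw <- poolspline:::ps_sandwich(d, mod, basis, imp, fits, nr$beta, nr)
    num <- poolspline:::ps_bread_numeric(d, basis, character(), fits, m,
                                         nr$beta)
    ana <- sw$A[2L * cfg$S + 1:2, seq_len(2L * cfg$S)]
    expect_lt(max(abs(num - ana) / (abs(ana) + 1e-6)), 1e-5)
  }
})

test_that("sandwich covariance is symmetric positive semi-definite", {
  cfg <- sim_config(pairs_per_study = 80, calibration_proportion = 0.3)
  d <- generate_pooled_data(cfg, seed = 6)
  for (m in c("full", "internalized", "naive")) {
    fit <- fit_dose_response(d, method = m, basis = rcs_basis(cfg$knots))
    V <- fit$sandwich_full
    expect_equal(V, t(V), tolerance = 1e-10)
    expect_gt(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
    expect_true(all(diag(fit$sandwich_cov) >= 0))
  }
})

test_that("naive and reference-laboratory fits reduce to the likelihood-only sandwich", {
  cfg <- sim_config(pairs_per_study = 80, calibration_proportion = 0.3)
  d <- generate_pooled_data(cfg, seed = 16)
  fit_n <- fit_dose_response(d, method = "naive", basis = rcs_basis(cfg$knots))
  expect_equal(dim(fit_n$sandwich_full), c(2L, 2L))  # shrinks by 2Q

  dref <- generate_pooled_data(
    sim_config(S = 2, pairs_per_study = 150, local_lab = c(FALSE, FALSE)),
    seed = 16)
  fit_r <- fit_dose_response(dref, method = "full",
                             basis = rcs_basis(cfg$knots))
  expect_equal(length(fit_r$param_names), 2L)
  # with a correctly specified model the robust and model-based variances
  # estimate the same quantity
  expect_equal(sqrt(diag(fit_r$sandwich_cov)),
               sqrt(diag(fit_r$model_cov)), tolerance = 0.1)
})

test_that("sandwich covariance is invariant to study and stratum relabeling", {
  cfg <- sim_config(S = 2, pairs_per_study = 60, calibration_proportion = 0.3)
  d <- generate_pooled_data(cfg, seed = 19)
  basis <- rcs_basis(cfg$knots)
  f1 <- fit_dose_response(d, basis = basis)
  d2 <- as.data.frame(d)
  d2$stratum <- 1000 - d2$stratum          # reverse stratum labels
  d2$study <- c(s1 = "zz", s2 = "aa")[d2$study]
  f2 <- fit_dose_response(pooled_data(d2), basis = basis)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$sandwich_cov, f2$sandwich_cov, tolerance = 1e-9)
})

test_that("Wald tests have the right edge behaviour", {
  fake <- structure(list(
    beta = c(bx1 = 0, bx2 = 0.392),
    sandwich_cov = diag(c(0.04, 0.04)),
    basis = rcs_basis(c(-1, 0, 1))), class = "dose_response_fit")
  w0 <- wald_test(fake, 1)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)
  # single component with beta/se = 1.96: p ~ 0.05
  w <- wald_test(fake, 2)
  expect_equal(w$z, 1.96, tolerance = 1e-10)
  expect_equal(w$p_value, 0.05, tolerance = 1e-3)
  expect_error(wald_test(fake, 5), "out of range")
  # default components: the nonlinear coefficients
  expect_equal(wald_test(fake)$df, 1L)
})

test_that("log relative-risk curves anchor at the reference level", {
  fake <- structure(list(
    beta = c(bx1 = -0.41, bx2 = 0.14),
    sandwich_cov = matrix(c(0.01, 0.002, 0.002, 0.005), 2),
    basis = rcs_basis(c(-0.6745, 0, 0.6745))), class = "dose_response_fit")
  cv <- log_rr_curve(fake, grid = seq(-2, 2, by = 0.5), x_ref = 0)
  at_ref <- cv[cv$x == 0, ]
  expect_equal(at_ref$log_rr, 0)
  expect_equal(at_ref$lower, 0)
  expect_equal(at_ref$upper, 0)
  expect_true(all(cv$lower <= cv$log_rr & cv$log_rr <= cv$upper))
  # frozen hand value at x = 1, noting f2(0) = 0.6745^3 = 0.3068639 at these
  # knots: -0.41 * (1 - 0) + 0.14 * (2.7297015 - 0.3068639)
  expect_equal(cv$log_rr[cv$x == 1], -0.0708027421, tolerance = 1e-8)
})

test_that("a zero nonlinear coefficient yields an exactly linear curve", {
  fake <- structure(list(
    beta = c(bx1 = -0.41, bx2 = 0),
    sandwich_cov = diag(c(0.01, 0.005)),
    basis = rcs_basis(c(-0.6745, 0, 0.6745))), class = "dose_response_fit")
  cv <- log_rr_curve(fake, grid = seq(-3, 3, by = 0.25), x_ref = -3)
  expect_lt(max(abs(diff(cv$log_rr, differences = 2))), 1e-10)
})
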