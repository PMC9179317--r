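test_that("stratum log-likelihood has the exact closed forms at beta = 0", {
  b <- rcs_basis(c(-1, 0, 1))
  for (nm in list(c(1, 1), c(1, 3), c(2, 2), c(3, 4))) {
    n <- nm[1]; m <- nm[2]
    fx <- rcs_eval(b, rnorm(n + m))
    case <- c(rep(0, m), rep(1, n))
    expect_equal(stratum_loglik(c(0, 0), NULL, fx, NULL, case),
                 -log(choose(n + m, n)))
  }
})

test_that("1:1 stratum reduces to the binary logistic form", {
  # scalar basis difference of 1 at beta = 0.5: -log(1 + e^0.5)
  fx <- matrix(c(1, 0, 0, 0), 2, 2)  # control f = (1, 0), case f = (0, 0)
  ll <- stratum_loglik(c(0.5, 0), NULL, fx, NULL, c(0, 1))
  expect_equal(ll, -0.9740769842, tolerance = 1e-9)
})

test_that("stratum log-likelihood equals the enumeration oracle", {
  set.seed(31)
  b <- rcs_basis(c(-0.7, 0, 0.7))
  for (rep in 1:20) {
    n <- sample(1:3, 1); m <- sample(1:3, 1)
    x <- rnorm(n + m)
    z <- matrix(rnorm(n + m), ncol = 1)
    case <- sample(c(rep(0, m), rep(1, n)))
    beta <- rnorm(3, sd = 0.7)
    got <- stratum_loglik(beta[1:2], beta[3], rcs_eval(b, x), z, case)
    want <- oracle_stratum_loglik(beta, cbind(rcs_eval(b, x), z), case)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("likelihood only sees within-stratum contrasts", {
  b <- rcs_basis(c(-1, 0, 1))
  fx <- rcs_eval(b, c(-0.4, 1.2, 0.3))
  z <- matrix(c(1, 0, 2), ncol = 1)
  case <- c(0, 0, 1)
  beta_x <- c(-0.4, 0.1); beta_z <- 0.3
  base <- stratum_loglik(beta_x, beta_z, fx, z, case)
  shifted <- stratum_loglik(beta_x, beta_z,
                            fx + matrix(c(5, -2), 3, 2, byrow = TRUE),
                            z + 11, case)
  expect_equal(shifted, base)
})

test_that("total log-likelihood, score and Hessian are mutually consistent", {
  d <- make_ref_data(n_strata = 5, seed = 13)
  basis <- rcs_basis(rcs_knots(d$reference_value))
  mod <- poolspline:::ps_model(d, basis, d$reference_value)

  # beta = 0: sum of -log C(n+m, n)
  sid <- interaction(d$study, d$stratum, drop = TRUE)
  sz <- tapply(d$case, sid, length)
  nc <- tapply(d$case, sid, sum)
  expect_equal(poolspline:::ps_loglik(mod, c(0, 0)),
               -sum(log(choose(sz, nc))))

  # analytic score vs central finite differences at random beta
  set.seed(2)
  for (r in 1:5) {
    beta <- rnorm(2, sd = 0.5)
    g <- poolspline:::ps_score(mod, beta)
    h <- 1e-6
    num <- vapply(1:2, function(i) {
      e <- replace(numeric(2), i, h)
      (poolspline:::ps_loglik(mod, beta + e) -
         poolspline:::ps_loglik(mod, beta - e)) / (2 * h)
    }, numeric(1))
    expect_equal(g, num, tolerance = 1e-5)

    # Hessian: negative semi-definite (concave conditional likelihood),
    # and equal to minus the Jacobian of the score
    info <- poolspline:::ps_info(mod, beta)$info
    ev <- eigen(info, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
    numH <- sapply(1:2, function(i) {
      e <- replace(numeric(2), i, h)
      -(poolspline:::ps_score(mod, beta + e) -
          poolspline:::ps_score(mod, beta - e)) / (2 * h)
    })
    expect_equal(info, numH, tolerance = 1e-4)
  }
})

test_that("score vanishes at beta = 0 on a case/control-swapped pair of strata", {
  b <- rcs_basis(c(-1, 0, 1))
  x <- c(0.3, -0.8)
  df <- data.frame(study = "s", stratum = rep(1:2, each = 2),
                   case = c(0L, 1L, 1L, 0L),
                   local_value = rep(x, 2), reference_value = rep(x, 2),
                   in_calibration = 0L)
  mod <- poolspline:::ps_model(pooled_data(df), b, rep(x, 2))
  expect_equal(poolspline:::ps_score(mod, c(0, 0)), c(0, 0))
})

test_that("reference-laboratory fit matches the brute-force enumeration oracle", {
  d <- make_ref_data(n_strata = 30, seed = 17)
  basis <- rcs_basis(rcs_knots(d$reference_value))
  fit <- fit_dose_response(d, method = "full", basis = basis)
  pieces <- oracle_pieces(d, basis, d$reference_value)
  bo <- oracle_fit(pieces$v, pieces$case, q = 2)
  expect_lt(max(abs(unname(fit$beta) - bo)), 1e-6)
  expect_true(fit$converged)
})

test_that("reference-laboratory fit agrees with conditional logistic regression", {
  library(survival)
  d <- make_ref_data(n_strata = 40, seed = 23)
  basis <- rcs_basis(rcs_knots(d$reference_value))
  fit <- fit_dose_response(d, method = "full", basis = basis)
  fx <- rcs_eval(basis, d$reference_value)
  sid <- as.integer(interaction(d$study, d$stratum, drop = TRUE))
  cl <- survival::clogit(case ~ fx[, 1] + fx[, 2] + strata(sid),
                         data = cbind(as.data.frame(d), sid = sid),
                         method = "exact")
  expect_equal(unname(fit$beta), unname(coef(cl)), tolerance = 1e-6)
})

test_that("fit is invariant to subject order within strata", {
  d <- make_ref_data(n_strata = 12, seed = 29)
  basis <- rcs_basis(c(-0.6745, 0, 0.6745))
  f1 <- fit_dose_response(d, basis = basis)
  set.seed(1)
  perm <- unlist(lapply(split(seq_len(nrow(d)),
                              interaction(d$study, d$stratum, drop = TRUE)),
                        sample), use.names = FALSE)
  d2 <- pooled_data(as.data.frame(d)[perm, ])
  f2 <- fit_dose_response(d2, basis = basis)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$sandwich_cov, f2$sandwich_cov, tolerance = 1e-8)
})

test_that("a null biomarker effect is recovered within sampling error", {
  cfg <- sim_config(pairs_per_study = 400, beta_x = c(0, 0),
                    calibration_proportion = 0.3)
  d <- generate_pooled_data(cfg, seed = 8)
  fit <- fit_dose_response(d, method = "full", basis = rcs_basis(cfg$knots))
  se <- sqrt(diag(fit$sandwich_cov))
  expect_true(all(abs(fit$beta) < 3 * se))
})

test_that("separation raises an explicit error", {
  # identical contrasts in every stratum push |beta| to infinity
  df <- data.frame(study = "s", stratum = rep(1:10, each = 2),
                   case = rep(c(0L, 1L), 10),
                   local_value = rep(c(1, 0), 10),
                   reference_value = rep(c(1, 0), 10),
                   in_calibration = 0L)
  expect_error(
    fit_dose_response(pooled_data(df), basis = rcs_basis(c(-1, 0, 1))),
    "separation")
})

test_that("oversized matched sets hit the enumeration guard", {
  df <- data.frame(study = "s", stratum = 1,
                   case = c(rep(0L, 15), rep(1L, 10)),
                   local_value = rnorm(25), reference_value = rnorm(25),
                   in_calibration = 0L)
  expect_error(fit_dose_response(pooled_data(df),
                                 basis = rcs_basis(c(-1, 0, 1))),
               "enumeration guard")
})
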