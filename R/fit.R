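#' Fit the calibrated spline dose-response model
#'
#' Two-step pseudo-maximum-likelihood fit of the conditional logistic risk
#' model
#' \deqn{\mathrm{logit}\, P(Y = 1) = \beta_{0,sj} + \beta_X' f(X) +
#'   \beta_Z' Z,}
#' where \eqn{f} is a restricted cubic spline basis and the stratum
#' intercepts \eqn{\beta_{0,sj}} are conditioned out.  Step 1 fits the
#' per-study calibration models among re-assayed controls
#' ([fit_calibration()]); step 2 maximizes the approximate conditional
#' likelihood with the biomarker replaced by its imputed reference-scale
#' value ([impute_biomarker()]) by Newton-Raphson with analytic score and
#' Hessian (start at 0, step-halving, convergence when the largest score
#' component is below \code{tol}).
#'
#' Two covariance estimates are returned: the model-based inverse observed
#' information, and a sandwich covariance over the estimating equations of
#' both steps stacked per stratum, which propagates the calibration
#' uncertainty into the dose-response coefficients (see
#' [sandwich_covariance()]).
#'
#' @param data a [pooled_data()] object.
#' @param method calibration strategy: \code{"full"} (impute for every
#'   subject of a local-laboratory study), \code{"internalized"} (use the
#'   observed reference measurement when available) or \code{"naive"} (use
#'   local values untouched).
#' @param knots explicit knot vector, or \code{NULL} to place knots at
#'   empirical quantiles of the imputed biomarker values.
#' @param knot_probs quantile probabilities used when \code{knots} is
#'   \code{NULL}; quartiles by default.
#' @param basis an [rcs_basis()] object, overriding \code{knots}.
#' @param covariates confounder columns; defaults to the covariates declared
#'   on \code{data}.
#' @param calibration_covariates optional matching-factor columns for the
#'   calibration models.
#' @param tol convergence tolerance on the score.
#' @param maxit maximum Newton iterations.
#' @return an object of class \code{"dose_response_fit"}; see
#'   [summary.dose_response_fit()].  Coefficients are named \code{bx1},
#'   \code{bx2}, ... for the basis columns followed by the covariate names.
#' @examples
#' d <- generate_pooled_data(sim_config(pairs_per_study = 100), seed = 7)
#' fit <- fit_dose_response(d, method = "full")
#' summary(fit)
#' @export
fit_dose_response <- function(data,
                              method = c("full", "internalized", "naive"),
                              knots = NULL, basis = NULL,
                              knot_probs = c(0.25, 0.5, 0.75),
                              covariates = attr(data, "covariates"),
                              calibration_covariates = character(),
                              tol = 1e-8, maxit = 100L) {
  stopifnot(inherits(data, "pooled_data"))
  method <- match.arg(method)
  if (is.null(covariates)) covariates <- character()
  local_lab <- attr(data, "local_lab")

  fits <- NULL
  if (method != "naive" && any(local_lab))
    fits <- fit_calibration(data, covariates = calibration_covariates)
  imp <- impute_biomarker(data, fits, method)

  if (is.null(basis)) {
    if (is.null(knots)) knots <- rcs_knots(imp$xtilde, probs = knot_probs)
    basis <- rcs_basis(knots)
  }
  mod <- ps_model(data, basis, imp$xtilde, covariates)
  nr <- ps_newton(mod, tol = tol, maxit = maxit)
  if (!nr$converged)
    warning("Newton-Raphson did not converge in ", maxit, " iterations",
            call. = FALSE)

  pnames <- c(paste0("bx", seq_len(basis$dim)), covariates)
  beta <- stats::setNames(nr$beta, pnames)
  if (rcond(nr$info) < 1e-12)
    stop("separation or degenerate design: observed information is ",
         "singular at the fitted coefficients", call. = FALSE)
  model_cov <- solve(nr$info)
  dimnames(model_cov) <- list(pnames, pnames)

  sw <- ps_sandwich(data, mod, basis, imp, fits, beta, nr)

  structure(list(
    beta = beta, model_cov = model_cov,
    sandwich_cov = sw$beta_block, sandwich_full = sw$full,
    param_names = sw$param_names,
    loglik = nr$loglik, iterations = nr$iterations,
    converged = nr$converged, method = method,
    basis = basis, calibration = fits, covariates = covariates,
    n_subjects = nrow(data), n_strata = mod$S,
    n_cases = sum(data$case)), class = "dose_response_fit")
}

# sandwich over the stacked estimating equations.  Unit = stratum; each
# unit's psi concatenates the OLS normal-equation contributions of its
# calibration-subset members (per local study) and the conditional-likelihood
# score contribution.  theta = (a_1, b_1, ..., a_Q, b_Q, beta).
ps_sandwich <- function(data, mod, basis, imp, fits, beta, nr) {
  q <- mod$q
  S <- mod$S
  pi <- nr$parts$pi
  G <- nr$G
  pnames <- names(beta)
  if (is.null(pnames)) pnames <- paste0("beta", seq_len(q))

  cal_studies <- if (is.null(fits)) character(0) else fits$study
  Q <- length(cal_studies)
  if (Q == 0L) {
    A <- nr$info
    B <- crossprod(G)
    Ai <- solve(A)
    V <- Ai %*% B %*% t(Ai)
    dimnames(V) <- list(pnames, pnames)
    return(list(full = V, beta_block = V, param_names = pnames))
  }

  npar <- 2L * Q + q
  theta_names <- c(as.vector(rbind(paste0("a_", cal_studies),
                                   paste0("b_", cal_studies))), pnames)
  stratum_of <- integer(nrow(data))
  for (j in seq_len(S)) stratum_of[mod$strata[[j]]] <- j

  # per-subject derivative of the design row wrt the subject's own study's
  # calibration parameters; zero unless the subject's value was imputed
  gmat <- rcs_eval(basis, imp$xtilde, deriv = 1L)
  dimx <- basis$dim
  da <- matrix(0, nrow(data), q)
  db <- matrix(0, nrow(data), q)
  ci <- imp$calibrated
  da[ci, seq_len(dimx)] <- gmat[ci, , drop = FALSE]
  db[ci, seq_len(dimx)] <- gmat[ci, , drop = FALSE] *
    data$local_value[ci]
  Da <- ps_stack(da, mod)
  Db <- ps_stack(db, mod)
  ua <- drop(Da %*% beta)
  ub <- drop(Db %*% beta)
  Ubar_a <- drop(rowsum(pi * ua, mod$strat))
  Ubar_b <- drop(rowsum(pi * ub, mod$strat))

  U <- matrix(0, S, npar)          # per-stratum psi contributions
  A <- matrix(0, npar, npar)       # -sum d psi / d theta'
  for (k in seq_len(Q)) {
    s <- cal_studies[k]
    ca <- 2L * (k - 1L) + 1L
    cb <- ca + 1L
    sub <- which(data$study == s & data$in_calibration == 1L)
    W <- data$local_value[sub]
    r <- data$reference_value[sub] - fits$a[k] - fits$b[k] * W
    js <- stratum_of[sub]
    # accumulate by stratum; not every stratum holds a re-assayed control
    ta <- tapply(r, js, sum)
    tb <- tapply(r * W, js, sum)
    idx <- as.integer(names(ta))
    U[idx, ca] <- U[idx, ca] + as.numeric(ta)
    U[idx, cb] <- U[idx, cb] + as.numeric(tb)

    A[ca, ca] <- length(sub)
    A[ca, cb] <- A[cb, ca] <- sum(W)
    A[cb, cb] <- sum(W^2)

    rmask <- mod$row_study == s
    smask <- mod$study_of_stratum == s
    bcols <- 2L * Q + seq_len(q)
    A[bcols, ca] <-
      crossprod(mod$D[rmask, , drop = FALSE], (pi * ua)[rmask]) -
      crossprod(G[smask, , drop = FALSE], Ubar_a[smask]) +
      crossprod(Da[rmask, , drop = FALSE], pi[rmask])
    A[bcols, cb] <-
      crossprod(mod$D[rmask, , drop = FALSE], (pi * ub)[rmask]) -
      crossprod(G[smask, , drop = FALSE], Ubar_b[smask]) +
      crossprod(Db[rmask, , drop = FALSE], pi[rmask])
  }
  bcols <- 2L * Q + seq_len(q)
  U[, bcols] <- -G
  A[bcols, bcols] <- nr$info

  B <- crossprod(U)
  Ai <- tryCatch(solve(A), error = function(e)
    stop("singular bread matrix in sandwich variance (condition number ",
         format(kappa(A), digits = 3), ")", call. = FALSE))
  V <- Ai %*% B %*% t(Ai)
  dimnames(V) <- list(theta_names, theta_names)
  list(full = V, beta_block = V[bcols, bcols, drop = FALSE],
       param_names = theta_names, U = U, A = A)
}

# numeric cross-check for the calibration cross-derivatives of the bread:
# recompute the likelihood estimating function psi_beta after perturbing one
# calibration parameter (central differences), with beta held fixed
ps_psi_beta_at <- function(data, basis, covariates, fits, method, beta) {
  imp <- impute_biomarker(data, fits, method)
  mod <- ps_model(data, basis, imp$xtilde, covariates)
  -colSums(mod$D * ps_parts(mod, beta)$pi)
}

ps_bread_numeric <- function(data, basis, covariates, fits, method, beta,
                             h = 1e-6) {
  q <- length(beta)
  Q <- nrow(fits)
  out <- matrix(0, q, 2L * Q)
  for (k in seq_len(Q)) {
    for (par in c("a", "b")) {
      hh <- h * (1 + abs(fits[[par]][k]))
      up <- fits; up[[par]][k] <- up[[par]][k] + hh
      dn <- fits; dn[[par]][k] <- dn[[par]][k] - hh
      d <- (ps_psi_beta_at(data, basis, covariates, up, method, beta) -
              ps_psi_beta_at(data, basis, covariates, dn, method, beta)) /
        (2 * hh)
      out[, 2L * (k - 1L) + match(par, c("a", "b"))] <- -d
    }
  }
  out
}

#' Sandwich covariance of the fitted parameters
#'
#' Returns the sandwich (robust) covariance \eqn{A^{-1} B A^{-T}} computed
#' from the estimating equations of both estimation steps, stacked per
#' stratum: the OLS normal equations of each study's calibration model
#' (attached to the stratum containing each re-assayed control) and the
#' conditional-likelihood score.  The bread \eqn{A} uses analytic
#' derivatives throughout, including the chain-rule block that links the
#' dose-response score to the calibration intercept and slope through the
#' imputed values.  Cross-correlation between the two steps is captured
#' because both contributions of a stratum enter the same unit.
#'
#' For the naive method (or a dataset with no local-laboratory study) there
#' are no calibration parameters and the matrix reduces to the
#' likelihood-only sandwich.
#'
#' @param fit a [fit_dose_response()] result.
#' @return list with \code{full} (covariance of all stacked parameters:
#'   calibration intercepts/slopes then dose-response coefficients),
#'   \code{beta} (the dose-response block) and \code{param_names}.
#' @export
sandwich_covariance <- function(fit) {
  stopifnot(inherits(fit, "dose_response_fit"))
  list(full = fit$sandwich_full, beta = fit$sandwich_cov,
       param_names = fit$param_names)
}

#' Wald test on dose-response coefficients
#'
#' Quadratic-form Wald test of H0: the selected coefficients are zero, using
#' the sandwich covariance.  The usual application is the test of no
#' nonlinearity (all nonlinear spline coefficients = 0).
#'
#' @param fit a [fit_dose_response()] result.
#' @param components integer indices or names of coefficients of
#'   \code{fit$beta}; default: all nonlinear basis coefficients.
#' @return list with \code{statistic}, \code{df}, \code{p_value}, and for a
#'   single component also \code{z}.
#' @export
wald_test <- function(fit, components = NULL) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (is.null(components)) {
    if (fit$basis$dim < 2L) stop("no nonlinear components", call. = FALSE)
    components <- 2:fit$basis$dim
  }
  if (is.character(components))
    components <- match(components, names(fit$beta))
  if (anyNA(components) || any(components < 1) ||
      any(components > length(fit$beta)))
    stop("component indices out of range", call. = FALSE)
  b <- fit$beta[components]
  V <- fit$sandwich_cov[components, components, drop = FALSE]
  stat <- drop(t(b) %*% solve(V, b))
  df <- length(components)
  out <- list(statistic = stat, df = df,
              p_value = stats::pchisq(stat, df, lower.tail = FALSE))
  if (df == 1L) {
    out$z <- unname(b / sqrt(V[1L, 1L]))
    out$p_value <- 2 * stats::pnorm(-abs(out$z))
  }
  out
}

#' Log relative-risk curve with pointwise confidence bands
#'
#' Evaluates \eqn{\log RR(x) = \hat\beta_X' \{f(x) - f(x_{ref})\}} on a grid
#' together with pointwise normal 95\% intervals from the sandwich
#' covariance of \eqn{\hat\beta_X}.  Intervals are pointwise, not
#' simultaneous.
#'
#' @param fit a [fit_dose_response()] result.
#' @param grid numeric vector of biomarker values (reference-laboratory
#'   scale).
#' @param x_ref reference level; defaults to \code{min(grid)}, mirroring the
#'   convention of anchoring the curve at the minimum observed measurement.
#' @param level confidence level.
#' @return data frame (class \code{"log_rr_curve"}) with columns \code{x},
#'   \code{log_rr}, \code{lower}, \code{upper}; the reference level is
#'   stored as attribute \code{x_ref}.
#' @export
log_rr_curve <- function(fit, grid, x_ref = NULL, level = 0.95) {
  stopifnot(inherits(fit, "dose_response_fit"))
  grid <- as.numeric(grid)
  if (is.null(x_ref)) x_ref <- min(grid)
  dimx <- fit$basis$dim
  bx <- fit$beta[seq_len(dimx)]
  Vx <- fit$sandwich_cov[seq_len(dimx), seq_len(dimx), drop = FALSE]
  C <- rcs_eval(fit$basis, grid) -
    matrix(rcs_eval(fit$basis, x_ref), length(grid), dimx, byrow = TRUE)
  est <- drop(C %*% bx)
  se <- sqrt(pmax(rowSums((C %*% Vx) * C), 0))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(x = grid, log_rr = est,
                    lower = est - zq * se, upper = est + zq * se)
  attr(out, "x_ref") <- x_ref
  class(out) <- c("log_rr_curve", "data.frame")
  out
}

#' @export
print.dose_response_fit <- function(x, digits = 4, ...) {
  cat("Calibrated spline dose-response fit (", x$method,
      " calibration)\n", sep = "")
  cat("  ", x$n_strata, " matched sets, ", x$n_cases, " cases, ",
      x$n_subjects, " subjects\n", sep = "")
  se <- sqrt(diag(x$sandwich_cov))
  tab <- cbind(estimate = x$beta, se_sandwich = se,
               se_model = sqrt(diag(x$model_cov)))
  print(signif(tab, digits))
  cat("log-likelihood:", format(x$loglik, digits = 7),
      " converged:", x$converged, "\n")
  invisible(x)
}

#' Summary of a dose-response fit
#'
#' Coefficient table with sandwich standard errors, Wald confidence
#' intervals and p-values, plus the joint Wald test of no nonlinearity.
#'
#' @param object a [fit_dose_response()] result.
#' @param level confidence level for the intervals.
#' @param ... unused.
#' @return a list of class \code{"summary.dose_response_fit"} with elements
#'   \code{coefficients} (matrix), \code{nonlinearity} (Wald test), and fit
#'   metadata.
#' @export
summary.dose_response_fit <- function(object, level = 0.95, ...) {
  se <- sqrt(diag(object$sandwich_cov))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  z <- object$beta / se
  tab <- cbind(estimate = object$beta, se = se,
               lower = object$beta - zq * se,
               upper = object$beta + zq * se,
               z = z, p_value = 2 * stats::pnorm(-abs(z)))
  nl <- if (object$basis$dim >= 2L) wald_test(object) else NULL
  structure(list(coefficients = tab, nonlinearity = nl,
                 method = object$method, level = level,
                 loglik = object$loglik, converged = object$converged,
                 knots = object$basis$knots),
            class = "summary.dose_response_fit")
}

#' @export
print.summary.dose_response_fit <- function(x, digits = 4, ...) {
  cat("Calibrated spline dose-response fit (", x$method,
      " calibration)\n", sep = "")
  cat("Knots:", paste(signif(x$knots, 5), collapse = ", "), "\n\n")
  print(signif(x$coefficients, digits))
  if (!is.null(x$nonlinearity))
    cat(sprintf("\nWald test of no nonlinearity: chi2 = %.4g, df = %d, p = %.4g\n",
                x$nonlinearity$statistic, x$nonlinearity$df,
                x$nonlinearity$p_value))
  invisible(x)
}

#' Serialize a fit summary to JSON
#'
#' Structured-output twin of [summary.dose_response_fit()], suitable for
#' downstream tooling.  Keys are versioned with a \code{schema} tag.
#'
#' @param fit a [fit_dose_response()] result.
#' @param path optional output file; when \code{NULL} the JSON string is
#'   returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
fit_summary_json <- function(fit, path = NULL) {
  s <- summary(fit)
  obj <- list(
    schema = "poolspline-fit/1",
    method = fit$method,
    knots = fit$basis$knots,
    coefficients = lapply(seq_along(fit$beta), function(i) list(
      name = names(fit$beta)[i],
      estimate = unname(fit$beta[i]),
      se = unname(s$coefficients[i, "se"]),
      lower95 = unname(s$coefficients[i, "lower"]),
      upper95 = unname(s$coefficients[i, "upper"]),
      p_value = unname(s$coefficients[i, "p_value"]))),
    nonlinearity_test = if (is.null(s$nonlinearity)) NULL else
      s$nonlinearity[c("statistic", "df", "p_value")],
    loglik = fit$loglik,
    iterations = fit$iterations,
    converged = fit$converged,
    n_strata = fit$n_strata, n_subjects = fit$n_subjects)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
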