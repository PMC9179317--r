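#' Simulation scenario configuration
#'
#' Defines a Monte-Carlo scenario for pooled 1:1 matched case-control data
#' with study-specific laboratory calibration.  Within each study,
#' \eqn{(X, W, \epsilon)} are multivariate normal with
#' \eqn{E(X|W) = a_s + b_s W}, \eqn{Cov(W, \epsilon) = 0}, marginal
#' \eqn{X \sim N(\mu_x, \sigma^2_x)} and \eqn{Var(W) = \sigma^2_{w,s}};
#' disease follows the spline risk model with a random stratum intercept.
#' The defaults are the canonical four-study scenario: 500 pairs per study,
#' \code{a = c(-3, 1, -1, 3)}, \code{b = c(0.5, 0.75, 1.25, 1.5)},
#' \code{sigma2_w = c(3.8, 1.7, 0.6, 0.4)} (a wide range of local-laboratory
#' scales), stratum-intercept variance 0.01, and knots fixed at the
#' quartiles of N(0, 1) so that the three calibration strategies are fitted
#' on a common basis.
#'
#' @param S number of studies.
#' @param pairs_per_study number of 1:1 matched sets per study.
#' @param mu_x,sigma2_x mean and variance of the reference-scale biomarker.
#' @param a,b per-study calibration intercepts and slopes (recycled to
#'   length \code{S}).
#' @param sigma2_w per-study variance of the local measurement; must satisfy
#'   \code{sigma2_x - b^2 * sigma2_w >= 0}.
#' @param beta0_variance variance of the N(0, .) stratum intercepts.
#' @param beta_x true spline coefficients (length = number of knots - 1).
#' @param knots spline knots used both to generate risk and to fit.
#' @param calibration_proportion fraction of each study's controls
#'   re-assayed at the reference laboratory (subset size is
#'   \code{max(3, round(proportion * controls))}).
#' @param local_lab logical per study; \code{FALSE} marks a study whose
#'   measurements are already on the reference scale.
#' @param n_replicates number of Monte-Carlo replicates for
#'   [run_simulation()].
#' @param seed master seed; each replicate uses an independent stream
#'   derived from (seed, replicate index).
#' @param max_candidates per-stratum rejection-sampling cap; exceeding it
#'   signals a pathological configuration.
#' @return validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(S = 4L, pairs_per_study = 500L,
                       mu_x = 0, sigma2_x = 1,
                       a = c(-3, 1, -1, 3), b = c(0.5, 0.75, 1.25, 1.5),
                       sigma2_w = c(3.8, 1.7, 0.6, 0.4),
                       beta0_variance = 0.01,
                       beta_x = c(-log(1.25), 0.08),
                       knots = stats::qnorm(c(0.25, 0.5, 0.75)),
                       calibration_proportion = 0.05,
                       local_lab = rep(TRUE, S),
                       n_replicates = 1000L, seed = 1L,
                       max_candidates = 1e5) {
  S <- as.integer(S)
  a <- rep_len(as.numeric(a), S)
  b <- rep_len(as.numeric(b), S)
  sigma2_w <- rep_len(as.numeric(sigma2_w), S)
  local_lab <- rep_len(as.logical(local_lab), S)
  stopifnot(S >= 1L, pairs_per_study >= 1L, sigma2_x > 0,
            all(sigma2_w > 0), beta0_variance >= 0,
            calibration_proportion > 0, calibration_proportion <= 1,
            n_replicates >= 1L)
  if (any(b == 0)) stop("calibration slopes must be nonzero", call. = FALSE)
  bad <- sigma2_x - b^2 * sigma2_w < -1e-12
  if (any(bad))
    stop("invalid covariance: sigma2_x - b^2 sigma2_w < 0 for study ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  knots <- as.numeric(knots)
  if (length(knots) < 3L || any(diff(knots) <= 0))
    stop("knots must be >= 3 strictly increasing values", call. = FALSE)
  if (length(beta_x) != length(knots) - 1L)
    stop("beta_x must have length(knots) - 1 components", call. = FALSE)
  structure(list(S = S, pairs_per_study = as.integer(pairs_per_study),
                 mu_x = mu_x, sigma2_x = sigma2_x, a = a, b = b,
                 sigma2_w = sigma2_w, beta0_variance = beta0_variance,
                 beta_x = as.numeric(beta_x), knots = knots,
                 calibration_proportion = calibration_proportion,
                 local_lab = local_lab,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 max_candidates = max_candidates),
            class = "sim_config")
}

# independent per-replicate stream derived from (master seed, index),
# kept within 32-bit integer range
replicate_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 77003 * as.numeric(i)) %% 2147483647)
}

# one study's strata: draw candidates until each stratum holds at least one
# case and one control, then keep one of each chosen uniformly at random
# (maintained by reservoir sampling as candidates stream in)
gen_study_strata <- function(nst, a, b, s2w, s2x, mu_x, beta0_sd, basis,
                             beta_x, max_candidates) {
  beta0 <- stats::rnorm(nst, 0, beta0_sd)
  muW <- (mu_x - a) / b
  sdW <- sqrt(s2w)
  sdE <- sqrt(max(s2x - b^2 * s2w, 0))
  caseW <- caseX <- ctrlW <- ctrlX <- rep(NA_real_, nst)
  ncase <- nctrl <- drawn <- integer(nst)
  repeat {
    act <- which(ncase == 0L | nctrl == 0L)
    if (!length(act)) break
    k <- length(act)
    W <- stats::rnorm(k, muW, sdW)
    X <- a + b * W + stats::rnorm(k, 0, sdE)
    eta <- beta0[act] + drop(rcs_eval(basis, X) %*% beta_x)
    Y <- stats::rbinom(k, 1L, stats::plogis(eta)) == 1L
    drawn[act] <- drawn[act] + 1L
    if (any(drawn[act] > max_candidates))
      stop("candidate cap exceeded in stratum ",
           act[which(drawn[act] > max_candidates)[1L]],
           ": check the scenario configuration", call. = FALSE)
    u <- stats::runif(k)
    ic <- act[Y]
    if (length(ic)) {
      ncase[ic] <- ncase[ic] + 1L
      take <- u[Y] < 1 / ncase[ic]
      caseW[ic[take]] <- W[Y][take]
      caseX[ic[take]] <- X[Y][take]
    }
    ic <- act[!Y]
    if (length(ic)) {
      nctrl[ic] <- nctrl[ic] + 1L
      take <- u[!Y] < 1 / nctrl[ic]
      ctrlW[ic[take]] <- W[!Y][take]
      ctrlX[ic[take]] <- X[!Y][take]
    }
  }
  list(caseW = caseW, caseX = caseX, ctrlW = ctrlW, ctrlX = ctrlX)
}

#' Generate one pooled matched case-control dataset
#'
#' Draws a [pooled_data()] realisation of a [sim_config()] scenario.  Strata
#' are 1:1; each stratum's case and control are chosen uniformly at random
#' among the candidates accumulated until both a case and a control exist.
#' Within local-laboratory studies the reference measurement is retained
#' only for the calibration subset: a simple random sample of the study's
#' controls of size \code{max(3, round(proportion * controls))}.
#' Reference-laboratory studies keep the reference value for every subject.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; identical (config, seed) pairs give identical
#'   datasets.
#' @return a [pooled_data()] object; rows are ordered control-then-case
#'   within stratum.
#' @export
generate_pooled_data <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  basis <- rcs_basis(config$knots)
  nst <- config$pairs_per_study
  parts <- vector("list", config$S)
  for (s in seq_len(config$S)) {
    g <- gen_study_strata(nst, config$a[s], config$b[s], config$sigma2_w[s],
                          config$sigma2_x, config$mu_x,
                          sqrt(config$beta0_variance), basis,
                          config$beta_x, config$max_candidates)
    ncal <- max(3L, round(config$calibration_proportion * nst))
    cal <- sample.int(nst, min(ncal, nst))
    incal <- integer(nst)
    incal[cal] <- 1L
    refctrl <- ifelse(incal == 1L, g$ctrlX, NA_real_)
    refcase <- rep(NA_real_, nst)
    if (!config$local_lab[s]) {       # already on the reference scale
      refctrl <- g$ctrlX
      refcase <- g$caseX
      incal[] <- 0L
    }
    parts[[s]] <- data.frame(
      study = sprintf("s%d", s),
      stratum = rep(seq_len(nst), each = 2L),
      case = rep(c(0L, 1L), nst),
      local_value = as.vector(rbind(g$ctrlW, g$caseW)),
      reference_value = as.vector(rbind(refctrl, refcase)),
      in_calibration = as.vector(rbind(incal, integer(nst))),
      stringsAsFactors = FALSE)
  }
  pooled_data(do.call(rbind, parts))
}

#' Run one simulation replicate
#'
#' Generates a dataset and fits the internalized, full, and naive estimators
#' on the scenario's fixed knots, recording per-coefficient estimates,
#' sandwich standard errors, and 95\% Wald-interval coverage of the truth.
#'
#' @param config a [sim_config()].
#' @param seed integer seed for this replicate.
#' @return data frame with one row per method and coefficient: columns
#'   \code{method}, \code{param}, \code{truth}, \code{estimate}, \code{se},
#'   \code{covered}, \code{converged}.
#' @export
run_replicate <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  d <- generate_pooled_data(config, seed)
  basis <- rcs_basis(config$knots)
  zq <- stats::qnorm(0.975)
  pn <- paste0("bx", seq_len(basis$dim))
  out <- lapply(c("internalized", "full", "naive"), function(m) {
    fit <- tryCatch(
      suppressWarnings(fit_dose_response(d, method = m, basis = basis)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged)
      return(data.frame(method = m, param = pn, truth = config$beta_x,
                        estimate = NA_real_, se = NA_real_, covered = NA,
                        converged = FALSE, stringsAsFactors = FALSE))
    se <- sqrt(diag(fit$sandwich_cov))[seq_len(basis$dim)]
    est <- unname(fit$beta[seq_len(basis$dim)])
    data.frame(method = m, param = pn, truth = config$beta_x,
               estimate = est, se = se,
               covered = abs(est - config$beta_x) <= zq * se,
               converged = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run a Monte-Carlo simulation study
#'
#' Aggregates [run_replicate()] over independent replicate streams and
#' summarizes, per method and coefficient: mean relative bias in percent
#' (mean of \eqn{(\hat\beta - \beta)/\beta}; \code{NA} when the true value
#' is 0), 1000 times the empirical standard deviation of the estimates
#' (\code{NA} with a single replicate), and the coverage of the 95\%
#' sandwich-based confidence interval.  Replicates whose fit fails or does
#' not converge are excluded from the summaries and counted in
#' \code{n_failed}.
#'
#' @param config a [sim_config()]; \code{config$n_replicates} and
#'   \code{config$seed} drive the experiment.
#' @param keep_replicates logical; attach the per-replicate table as
#'   attribute \code{"replicates"}.
#' @return data frame of class \code{"sim_summary"} with columns
#'   \code{method}, \code{param}, \code{truth}, \code{rel_bias_pct},
#'   \code{sd_x1000}, \code{coverage}, \code{mean_se}, \code{n_used},
#'   \code{n_failed}.
#' @export
run_simulation <- function(config, keep_replicates = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  reps <- vector("list", config$n_replicates)
  for (i in seq_len(config$n_replicates)) {
    r <- run_replicate(config, replicate_seed(config$seed, i))
    r$replicate <- i
    reps[[i]] <- r
  }
  all <- do.call(rbind, reps)
  grp <- split(all, list(all$method, all$param), drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(g) {
    ok <- g$converged & !is.na(g$estimate)
    gg <- g[ok, , drop = FALSE]
    truth <- g$truth[1L]
    data.frame(
      method = g$method[1L], param = g$param[1L], truth = truth,
      rel_bias_pct = if (truth != 0 && nrow(gg))
        mean((gg$estimate - truth) / truth) * 100 else NA_real_,
      sd_x1000 = if (nrow(gg) > 1L) stats::sd(gg$estimate) * 1000
        else NA_real_,
      coverage = if (nrow(gg)) mean(gg$covered) else NA_real_,
      mean_se = if (nrow(gg)) mean(gg$se) else NA_real_,
      n_used = nrow(gg), n_failed = sum(!ok),
      stringsAsFactors = FALSE)
  }))
  ord <- order(match(out$method, c("internalized", "full", "naive")),
               out$param)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- config
  if (keep_replicates) attr(out, "replicates") <- all
  class(out) <- c("sim_summary", "data.frame")
  out
}

#' @export
print.sim_summary <- function(x, digits = 3, ...) {
  cfg <- attr(x, "config")
  cat("Monte-Carlo summary over", cfg$n_replicates, "replicates",
      sprintf("(%d studies x %d pairs, calibration proportion %.0f%%)\n",
              cfg$S, cfg$pairs_per_study,
              100 * cfg$calibration_proportion))
  df <- as.data.frame(x)
  for (cl in c("rel_bias_pct", "sd_x1000", "coverage", "mean_se"))
    df[[cl]] <- signif(df[[cl]], digits)
  print(df, row.names = FALSE)
  invisible(x)
}
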