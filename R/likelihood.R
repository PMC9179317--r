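# Approximate conditional likelihood over matched sets.
#
# Each stratum with n cases and m controls contributes
#   log L = -log[ 1 + sum_{k in A'} exp(beta' d_k) ],
# where A' runs over all size-n subsets of the n+m members except the
# observed case set, and d_k is the within-stratum difference of summed
# design rows (spline basis of the imputed biomarker, plus confounders)
# between subset k and the case set.  Only within-stratum contrasts enter,
# so the stratum intercepts are conditioned out exactly.
#
# All strata are stacked: D holds one row per competing subset, `strat`
# maps rows to strata.  For 1:1 matching every stratum contributes a single
# row (control minus case), and everything vectorises.

# subset-difference stack of a per-subject matrix M (n x q):
# row k of the result is sum(M over subset k) - sum(M over case set).
ps_stack <- function(M, mod) {
  if (mod$all_pairs)
    M[mod$pos, , drop = FALSE] - M[mod$neg, , drop = FALSE]
  else
    mod$A %*% M
}

# internal model structure: design, stratum bookkeeping, subset incidence
ps_model <- function(data, basis, xtilde, covariates = character(),
                     max_set = 20L, max_subsets = 1e6) {
  v <- rcs_eval(basis, xtilde)
  if (length(covariates))
    v <- cbind(v, as.matrix(as.data.frame(data)[covariates]))
  q <- ncol(v)
  sid <- interaction(data$study, data$stratum, drop = TRUE, lex.order = TRUE)
  strata <- split(seq_len(nrow(data)), sid)
  S <- length(strata)
  study_of <- vapply(strata, function(ix) as.character(data$study[ix[1L]]),
                     character(1))
  ncase <- vapply(strata, function(ix) sum(data$case[ix]), numeric(1))
  nmemb <- lengths(strata)

  all_pairs <- all(ncase == 1L & nmemb == 2L)
  if (all_pairs) {
    pos <- vapply(strata, function(ix) ix[data$case[ix] == 0L], integer(1))
    neg <- vapply(strata, function(ix) ix[data$case[ix] == 1L], integer(1))
    strat <- seq_len(S)
    A <- NULL
    nrow_stack <- S
  } else {
    rows <- list(); strat <- integer(0)
    for (j in seq_len(S)) {
      ix <- strata[[j]]
      n <- sum(data$case[ix]); m <- length(ix) - n
      if (length(ix) > max_set || choose(length(ix), n) > max_subsets)
        stop("matched set of size ", length(ix),
             " exceeds the enumeration guard", call. = FALSE)
      cs <- ix[data$case[ix] == 1L]
      subs <- utils::combn(ix, n)
      keep <- colSums(matrix(subs %in% cs, nrow = n)) < n
      subs <- subs[, keep, drop = FALSE]
      for (k in seq_len(ncol(subs))) {
        r <- numeric(nrow(data))
        r[subs[, k]] <- r[subs[, k]] + 1
        r[cs] <- r[cs] - 1
        rows[[length(rows) + 1L]] <- r
        strat <- c(strat, j)
      }
    }
    A <- do.call(rbind, rows)
    pos <- neg <- NULL
    nrow_stack <- nrow(A)
  }
  mod <- list(v = v, q = q, S = S, strat = strat, all_pairs = all_pairs,
              pos = pos, neg = neg, A = A, strata = strata,
              study_of_stratum = study_of,
              stratum_names = names(strata), nrow_stack = nrow_stack)
  mod$D <- ps_stack(v, mod)
  mod$row_study <- study_of[strat]
  mod
}

# log-denominator per stratum and subset weights pi_k at beta
ps_parts <- function(mod, beta) {
  eta <- drop(mod$D %*% beta)
  if (mod$all_pairs) {
    ld <- ifelse(eta > 30, eta, log1p(exp(eta)))
    pi <- exp(eta - ld)
  } else {
    mx <- pmax(0, vapply(split(eta, mod$strat), max, numeric(1)))
    se <- drop(rowsum(exp(eta - mx[mod$strat]), mod$strat)) + exp(-mx)
    ld <- mx + log(se)
    pi <- exp(eta - ld[mod$strat])
  }
  list(eta = eta, logdenom = ld, pi = pi)
}

ps_loglik <- function(mod, beta) -sum(ps_parts(mod, beta)$logdenom)

ps_score <- function(mod, beta) {
  -colSums(mod$D * ps_parts(mod, beta)$pi)
}

# observed information (minus Hessian of the log-likelihood); also returns
# per-stratum score contributions G (psi_beta per stratum = -G)
ps_info <- function(mod, beta, parts = ps_parts(mod, beta)) {
  Dp <- mod$D * parts$pi
  G <- rowsum(Dp, mod$strat)
  list(info = crossprod(mod$D, Dp) - crossprod(G), G = G, parts = parts)
}

# Newton-Raphson with step-halving from beta = 0
ps_newton <- function(mod, tol = 1e-8, maxit = 100L) {
  beta <- numeric(mod$q)
  ll <- ps_loglik(mod, beta)
  conv <- FALSE; it <- 0L
  while (it < maxit) {
    it <- it + 1L
    ii <- ps_info(mod, beta)
    g <- -colSums(mod$D * ii$parts$pi)
    if (max(abs(g)) <= tol) { conv <- TRUE; break }
    step <- tryCatch(solve(ii$info, g), error = function(e)
      solve(ii$info + diag(1e-8, mod$q), g))
    newbeta <- beta + step
    newll <- ps_loglik(mod, newbeta)
    h <- 0L
    while (newll < ll && h < 30L) {
      h <- h + 1L
      step <- step / 2
      newbeta <- beta + step
      newll <- ps_loglik(mod, newbeta)
    }
    beta <- newbeta; ll <- newll
    if (sqrt(sum(beta^2)) > 100)
      stop("separation detected: likelihood appears unbounded ",
           "(|beta| diverging)", call. = FALSE)
  }
  if (!conv) {
    ii <- ps_info(mod, beta)
    conv <- max(abs(-colSums(mod$D * ii$parts$pi))) <= tol
  }
  list(beta = beta, loglik = ll, iterations = it, converged = conv,
       info = ii$info, G = ii$G, parts = ii$parts)
}

#' Conditional log-likelihood contribution of one matched set
#'
#' Evaluates the approximate conditional logistic log-likelihood of a single
#' stratum with \code{n} cases and \code{m} controls, enumerating all
#' competing case sets.  At \code{beta = 0} this equals
#' \code{-log(choose(n + m, n))}; for a 1:1 set it reduces to
#' \code{-log(1 + exp(beta' (d_ctrl - d_case)))}.
#'
#' @param beta_x coefficients of the biomarker basis columns.
#' @param beta_z coefficients of the confounder columns (may be
#'   \code{NULL}).
#' @param fx numeric matrix, one row per member: the spline basis evaluated
#'   at the member's (imputed) biomarker value.
#' @param z optional numeric matrix of confounders, one row per member.
#' @param case 0/1 vector of member case status.
#' @return the stratum log-likelihood (a scalar).
#' @export
stratum_loglik <- function(beta_x, beta_z = NULL, fx, z = NULL, case) {
  fx <- as.matrix(fx)
  if (!is.null(z)) z <- as.matrix(z)
  case <- as.integer(case)
  if (length(case) != nrow(fx))
    stop("case length must match rows of fx", call. = FALSE)
  if (!any(case == 1L) || !any(case == 0L))
    stop("stratum needs at least one case and one control", call. = FALSE)
  v <- if (is.null(z)) fx else cbind(fx, z)
  if (any(!is.finite(v))) stop("non-finite member values", call. = FALSE)
  beta <- c(beta_x, beta_z)
  df <- data.frame(study = 1L, stratum = 1L, case = case,
                   local_value = 0, reference_value = 0, in_calibration = 0L)
  cvn <- paste0(".v", seq_len(ncol(v)))
  df[cvn] <- as.data.frame(v)
  mod <- list(all_pairs = FALSE)
  n <- sum(case)
  cs <- which(case == 1L)
  subs <- utils::combn(length(case), n)
  keep <- colSums(matrix(subs %in% cs, nrow = n)) < n
  subs <- subs[, keep, drop = FALSE]
  A <- matrix(0, ncol(subs), length(case))
  for (k in seq_len(ncol(subs))) {
    A[k, subs[, k]] <- A[k, subs[, k]] + 1
    A[k, cs] <- A[k, cs] - 1
  }
  eta <- drop((A %*% v) %*% beta)
  mx <- pmax(0, max(eta))
  -(mx + log(sum(exp(eta - mx)) + exp(-mx)))
}
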