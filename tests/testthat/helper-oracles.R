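# Independent oracles and fixture builders.
#
# The conditional-likelihood oracle below works directly from the
# probability definition: the stratum probability is the product of the
# case terms exp(beta' v_i) divided by the sum of such products over every
# case set of the same size.  It never uses the package's stacked
# "1 + sum exp(differences)" representation, so agreement between the two
# is a genuine cross-check.

oracle_stratum_loglik <- function(beta, v, case) {
  v <- as.matrix(v)
  n <- sum(case == 1)
  eta <- drop(v %*% beta)
  num <- sum(eta[case == 1])
  subs <- combn(length(case), n)
  den <- log(sum(apply(subs, 2, function(ix) exp(sum(eta[ix])))))
  num - den
}

oracle_total_loglik <- function(beta, vlist, caselist) {
  sum(mapply(function(v, cs) oracle_stratum_loglik(beta, v, cs),
             vlist, caselist))
}

# brute-force conditional ML: coarse optim, then Newton polishing with
# finite-difference derivatives of the oracle log-likelihood
oracle_fit <- function(vlist, caselist, q) {
  nll <- function(b) -oracle_total_loglik(b, vlist, caselist)
  b <- optim(rep(0, q), nll, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 500))$par
  h <- 1e-5
  for (it in 1:8) {
    g <- numeric(q); H <- matrix(0, q, q)
    for (i in seq_len(q)) {
      ei <- replace(numeric(q), i, h)
      g[i] <- (nll(b + ei) - nll(b - ei)) / (2 * h)
      for (j in seq_len(q)) {
        ej <- replace(numeric(q), j, h)
        H[i, j] <- (nll(b + ei + ej) - nll(b + ei - ej) -
                      nll(b - ei + ej) + nll(b - ei - ej)) / (4 * h^2)
      }
    }
    step <- solve(H, g)
    b <- b - step
    if (max(abs(step)) < 1e-10) break
  }
  b
}

# split a pooled_data object into the oracle's per-stratum design pieces
oracle_pieces <- function(data, basis, xtilde, covariates = character()) {
  v <- rcs_eval(basis, xtilde)
  if (length(covariates)) v <- cbind(v, as.matrix(data[covariates]))
  sid <- interaction(data$study, data$stratum, drop = TRUE, lex.order = TRUE)
  ix <- split(seq_len(nrow(data)), sid)
  list(v = lapply(ix, function(i) v[i, , drop = FALSE]),
       case = lapply(ix, function(i) data$case[i]))
}

# small hand-built pooled dataset: all measurements on the reference scale,
# mixed n:m matched sets
make_ref_data <- function(n_strata = 30, seed = 42, sizes = c(2, 3, 5)) {
  set.seed(seed)
  rows <- list()
  for (j in seq_len(n_strata)) {
    sz <- sizes[1 + (j %% length(sizes))]
    ncs <- max(1, sz %/% 3)
    x <- rnorm(sz)
    rows[[j]] <- data.frame(study = "ref", stratum = j,
                            case = c(rep(0, sz - ncs), rep(1, ncs)),
                            local_value = x, reference_value = x,
                            in_calibration = 0L)
  }
  pooled_data(do.call(rbind, rows))
}

# tiny local-laboratory dataset with explicit values for calibration tests
make_local_data <- function() {
  df <- data.frame(
    study = "s1",
    stratum = rep(1:5, each = 2),
    case = rep(c(0L, 1L), 5),
    local_value = c(0, 1.5, 1, -0.5, 2, 0.3, -1, 0.8, 0.5, -0.2),
    reference_value = c(1, NA, 2, NA, 3, NA, NA, NA, NA, NA),
    in_calibration = c(1L, 0L, 1L, 0L, 1L, 0L, 0L, 0L, 0L, 0L))
  pooled_data(df)
}
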