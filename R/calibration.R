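#' Fit per-study calibration models
#'
#' For every local-laboratory study, regresses the reference-laboratory
#' measurement X on the local measurement W by ordinary least squares among
#' the calibration-subset controls, giving the study-specific intercept and
#' slope of E(X | W, control) = a + b W.  Matching factors (or user-supplied
#' nonlinear transforms of W) can be added through \code{covariates}.
#' Calibration is deliberately restricted to controls: case biospecimens are
#' rarely re-assayed, and rows flagged for calibration that are cases are
#' rejected when the dataset is constructed.
#'
#' @param data a [pooled_data()] object.
#' @param covariates optional character vector of extra regressor columns
#'   (matching factors) to include alongside W.
#' @return An object of class \code{"calibration_fit"}: a data frame with one
#'   row per local-laboratory study and columns \code{study, a, se_a, b,
#'   se_b, resid_var, n_cal}, plus a \code{coef_extra} attribute holding any
#'   matching-factor coefficients.
#' @examples
#' d <- generate_pooled_data(sim_config(pairs_per_study = 50), seed = 1)
#' fit_calibration(d)
#' @export
fit_calibration <- function(data, covariates = character()) {
  stopifnot(inherits(data, "pooled_data"))
  local_lab <- attr(data, "local_lab")
  studies <- names(local_lab)[local_lab]
  if (!length(studies))
    stop("no local-laboratory studies: nothing to calibrate", call. = FALSE)
  extra <- list()
  rows <- lapply(studies, function(s) {
    sub <- data[data$study == s & data$in_calibration == 1L, , drop = FALSE]
    p_extra <- length(covariates)
    if (nrow(sub) < 2L + p_extra)
      stop("calibration subset too small in study '", s, "' (",
           nrow(sub), " subjects)", call. = FALSE)
    if (any(sub$case == 1L))  # defence in depth; pooled_data() also rejects
      stop("cases present in calibration subset of study '", s, "'",
           call. = FALSE)
    W <- sub$local_value
    if (stats::var(W) <= 0)
      stop("zero variance of local measurements in calibration subset of ",
           "study '", s, "'", call. = FALSE)
    Xm <- cbind(1, W)
    if (p_extra)
      Xm <- cbind(Xm, as.matrix(sub[covariates]))
    y <- sub$reference_value
    qr_ <- qr(Xm)
    if (qr_$rank < ncol(Xm))
      stop("singular calibration design in study '", s, "'", call. = FALSE)
    cf <- qr.coef(qr_, y)
    res <- y - Xm %*% cf
    dfree <- nrow(Xm) - ncol(Xm)
    s2 <- if (dfree > 0) sum(res^2) / dfree else 0
    vc <- s2 * chol2inv(qr.R(qr_))
    extra[[s]] <<- if (p_extra) cf[-(1:2)] else numeric(0)
    data.frame(study = s, a = cf[1L], se_a = sqrt(vc[1L, 1L]),
               b = cf[2L], se_b = sqrt(vc[2L, 2L]),
               resid_var = s2, n_cal = nrow(Xm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "coef_extra") <- extra
  attr(out, "covariates") <- covariates
  class(out) <- c("calibration_fit", "data.frame")
  out
}

#' @export
print.calibration_fit <- function(x, digits = 4, ...) {
  cat("Study-specific calibration models, E(X | W, control) = a + b W\n")
  df <- as.data.frame(x)
  df$a <- signif(df$a, digits); df$b <- signif(df$b, digits)
  df$se_a <- signif(df$se_a, digits); df$se_b <- signif(df$se_b, digits)
  df$resid_var <- signif(df$resid_var, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Impute reference-scale biomarker values
#'
#' Assigns every subject a biomarker value on the reference-laboratory scale
#' according to the chosen calibration rule.  Subjects in
#' reference-laboratory studies keep their observed X under every method.
#' For local-laboratory studies:
#' \describe{
#'   \item{full}{\eqn{\tilde X = \hat a + \hat b W} for all subjects,
#'     including those with an observed reference measurement.}
#'   \item{internalized}{\eqn{\tilde X = X} when X is observed, otherwise
#'     \eqn{\hat a + \hat b W}.}
#'   \item{naive}{\eqn{\tilde X = W}: the local value is used untouched (the
#'     negative-control strategy, no calibration fit required).}
#' }
#'
#' @param data a [pooled_data()] object.
#' @param fits a [fit_calibration()] result (may be \code{NULL} for
#'   \code{method = "naive"} or when all studies use the reference
#'   laboratory).
#' @param method one of \code{"full"}, \code{"internalized"},
#'   \code{"naive"}.
#' @return data frame with columns \code{xtilde} (imputed value),
#'   \code{source} (\code{"reference"}, \code{"imputed"} or \code{"local"})
#'   and \code{calibrated} (logical: does the value depend on this study's
#'   fitted calibration parameters?), in the row order of \code{data}.
#' @export
impute_biomarker <- function(data, fits = NULL,
                             method = c("full", "internalized", "naive")) {
  stopifnot(inherits(data, "pooled_data"))
  method <- match.arg(method)
  local_lab <- attr(data, "local_lab")
  n <- nrow(data)
  xt <- data$reference_value
  src <- rep("reference", n)
  calib <- rep(FALSE, n)
  is_local <- local_lab[as.character(data$study)]

  if (method == "naive") {
    xt[is_local] <- data$local_value[is_local]
    src[is_local] <- "local"
  } else if (any(is_local)) {
    if (is.null(fits))
      stop("calibration fits required for method '", method, "'",
           call. = FALSE)
    for (s in names(local_lab)[local_lab]) {
      k <- match(s, fits$study)
      if (is.na(k))
        stop("no calibration fit for study '", s, "'", call. = FALSE)
      rows <- which(data$study == s)
      W <- data$local_value[rows]
      if (anyNA(W))
        stop("missing local_value in study '", s, "'", call. = FALSE)
      pred <- fits$a[k] + fits$b[k] * W
      if (method == "full") {
        xt[rows] <- pred
        src[rows] <- "imputed"
        calib[rows] <- TRUE
      } else {  # internalized
        have_x <- !is.na(data$reference_value[rows])
        xt[rows[!have_x]] <- pred[!have_x]
        src[rows[!have_x]] <- "imputed"
        calib[rows[!have_x]] <- TRUE
      }
    }
  }
  if (anyNA(xt))
    stop("imputation left missing values (reference-laboratory study with ",
         "missing reference_value?)", call. = FALSE)
  data.frame(xtilde = xt, source = src, calibrated = calib,
             stringsAsFactors = FALSE)
}
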