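#' Restricted cubic spline basis
#'
#' Constructs the restricted cubic spline (natural cubic spline) basis used in
#' the risk model.  With K knots \eqn{t_1 < \dots < t_K} the basis has
#' \eqn{K - 1} components: the identity \eqn{f_1(x) = x} plus \eqn{K - 2}
#' truncated-cubic components that are linear beyond the boundary knots.
#' For K = 3 the single nonlinear component is
#' \deqn{f_2(x) = (x - t_1)_+^3 - (x - t_2)_+^3 \frac{t_3 - t_1}{t_3 - t_2}
#'   + (x - t_3)_+^3 \frac{t_2 - t_1}{t_3 - t_2}.}
#' No normalisation is applied to the nonlinear components by default (some
#' texts divide by \eqn{(t_K - t_1)^2}); set \code{normalize = TRUE} to scale
#' them by that factor.
#'
#' @param knots numeric vector of K >= 3 strictly increasing knot locations,
#'   in biomarker units.  3 to 7 knots are supported.
#' @param normalize logical; divide nonlinear components by
#'   \eqn{(t_K - t_1)^2}?  Default \code{FALSE}.
#' @return An object of class \code{"rcs_basis"} with elements \code{knots},
#'   \code{dim} (number of basis functions, K - 1) and \code{normalize}.
#' @seealso [rcs_eval()], [rcs_knots()]
#' @examples
#' b <- rcs_basis(qnorm(c(0.25, 0.5, 0.75)))
#' rcs_eval(b, c(-1, 0, 1))
#' @export
rcs_basis <- function(knots, normalize = FALSE) {
  knots <- as.numeric(knots)
  if (length(knots) < 3L)
    stop("at least 3 knots are required", call. = FALSE)
  if (length(knots) > 7L)
    stop("at most 7 knots are supported", call. = FALSE)
  if (anyNA(knots) || any(!is.finite(knots)))
    stop("knots must be finite", call. = FALSE)
  if (any(diff(knots) <= 0))
    stop("degenerate knots: knot locations must be strictly increasing",
         call. = FALSE)
  structure(list(knots = knots, dim = length(knots) - 1L,
                 normalize = isTRUE(normalize)),
            class = "rcs_basis")
}

#' @export
print.rcs_basis <- function(x, ...) {
  cat("Restricted cubic spline basis:", length(x$knots), "knots,",
      x$dim, "basis functions\n")
  cat("  knots:", paste(signif(x$knots, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Knot locations from empirical quantiles
#'
#' Places knots at empirical quantiles of observed biomarker values, the usual
#' convention for restricted cubic splines.  Quantiles use the median-unbiased
#' definition (\code{type = 8} of [stats::quantile()]); knot placement is far
#' less influential on the fit than the number of knots, so the quantile
#' convention matters little, but it is fixed here for reproducibility.
#'
#' @param values numeric vector of observations (NAs dropped).
#' @param probs strictly increasing probabilities in (0, 1); defaults to the
#'   quartiles \code{c(0.25, 0.5, 0.75)}.
#' @return numeric vector of knot locations, strictly increasing.  Ties among
#'   quantiles (e.g. heavily discretised data) raise a degenerate-knots error.
#' @examples
#' rcs_knots(rnorm(500))
#' @export
rcs_knots <- function(values, probs = c(0.25, 0.5, 0.75)) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no non-missing values", call. = FALSE)
  probs <- as.numeric(probs)
  if (length(probs) < 1L || any(probs <= 0) || any(probs >= 1) ||
      any(diff(probs) <= 0))
    stop("probs must be strictly increasing within (0, 1)", call. = FALSE)
  k <- unname(stats::quantile(values, probs = probs, type = 8))
  if (any(diff(k) <= 0))
    stop("degenerate knots: quantiles are not distinct", call. = FALSE)
  k
}

#' Evaluate a restricted cubic spline basis
#'
#' @param basis an [rcs_basis()] object.
#' @param x numeric vector of evaluation points (any real values).
#' @param deriv 0 for basis values, 1 for first derivatives with respect
#'   to \code{x}.
#' @return numeric matrix with \code{length(x)} rows and \code{basis$dim}
#'   columns; column 1 is the linear term.
#' @export
rcs_eval <- function(basis, x, deriv = 0L) {
  stopifnot(inherits(basis, "rcs_basis"))
  x <- as.numeric(x)
  t <- basis$knots
  K <- length(t)
  out <- matrix(0, length(x), basis$dim)
  if (deriv == 0L) out[, 1L] <- x else out[, 1L] <- 1
  scl <- if (basis$normalize) (t[K] - t[1L])^2 else 1
  pp <- function(u) pmax(u, 0)
  for (j in seq_len(K - 2L)) {
    c1 <- (t[K] - t[j]) / (t[K] - t[K - 1L])
    c2 <- (t[K - 1L] - t[j]) / (t[K] - t[K - 1L])
    if (deriv == 0L) {
      val <- pp(x - t[j])^3 - pp(x - t[K - 1L])^3 * c1 + pp(x - t[K])^3 * c2
    } else {
      val <- 3 * (pp(x - t[j])^2 - pp(x - t[K - 1L])^2 * c1 +
                    pp(x - t[K])^2 * c2)
    }
    out[, j + 1L] <- val / scl
  }
  out
}
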