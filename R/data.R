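#' Pooled matched case-control dataset
#'
#' Validates and classifies a subject-level data frame holding a pooled
#' matched/nested case-control biomarker study.  One row per subject with
#' columns:
#' \describe{
#'   \item{study}{study identifier.}
#'   \item{stratum}{matched-set identifier, unique within study.}
#'   \item{case}{0 = control, 1 = case; strictly binary.}
#'   \item{local_value}{biomarker measurement from the study's local
#'     laboratory (W).}
#'   \item{reference_value}{measurement from the reference laboratory (X);
#'     \code{NA} when the subject was not re-assayed.}
#'   \item{in_calibration}{0/1 flag marking controls re-assayed at the
#'     reference laboratory (the calibration subset).}
#' }
#' Additional columns named in \code{covariates} enter the risk model as
#' confounders Z.  A study is treated as a reference-laboratory study (no
#' calibration needed, its measurements already on the reference scale) when
#' every subject has \code{reference_value} observed and none carries the
#' \code{in_calibration} flag; any other study is a local-laboratory study
#' and requires a calibration fit.
#'
#' Every stratum must contain at least one case and at least one control;
#' calibration-flagged subjects must be controls with both measurements
#' observed.  Violations are reported with the offending stratum or rows.
#'
#' @param df data frame as described above.
#' @param covariates character vector of confounder column names (may be
#'   empty).
#' @return \code{df}, with classes \code{c("pooled_data", "data.frame")} and
#'   attributes \code{covariates} and \code{local_lab} (named logical per
#'   study).
#' @export
pooled_data <- function(df, covariates = character()) {
  df <- as.data.frame(df)
  req <- c("study", "stratum", "case", "local_value")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"reference_value" %in% names(df)) df$reference_value <- NA_real_
  if (!"in_calibration" %in% names(df)) df$in_calibration <- 0L
  miss <- setdiff(covariates, names(df))
  if (length(miss))
    stop("covariate columns not found: ", paste(miss, collapse = ", "),
         call. = FALSE)

  if (!all(df$case %in% c(0, 1)))
    stop("case column must be strictly 0/1", call. = FALSE)
  df$case <- as.integer(df$case)
  if (!all(df$in_calibration %in% c(0, 1, NA)))
    stop("in_calibration column must be 0/1", call. = FALSE)
  df$in_calibration <- as.integer(df$in_calibration %in% 1)
  df$local_value <- as.numeric(df$local_value)
  df$reference_value <- as.numeric(df$reference_value)
  for (cv in covariates) {
    df[[cv]] <- as.numeric(df[[cv]])
    if (anyNA(df[[cv]]))
      stop("missing values in covariate '", cv, "'", call. = FALSE)
  }

  sid <- interaction(df$study, df$stratum, drop = TRUE, lex.order = TRUE)
  ncase <- tapply(df$case, sid, sum)
  nctrl <- tapply(1L - df$case, sid, sum)
  bad <- names(ncase)[ncase < 1 | nctrl < 1]
  if (length(bad))
    stop("strata without at least one case and one control: ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "", call. = FALSE)

  cal <- df$in_calibration == 1L
  if (any(cal & df$case == 1L))
    stop("calibration subset must contain controls only; case rows flagged: ",
         paste(utils::head(which(cal & df$case == 1L), 5L), collapse = ", "),
         call. = FALSE)
  if (any(cal & is.na(df$reference_value)))
    stop("calibration-flagged subjects must have reference_value; rows: ",
         paste(utils::head(which(cal & is.na(df$reference_value)), 5L),
               collapse = ", "), call. = FALSE)

  studies <- unique(df$study)
  local_lab <- vapply(studies, function(s) {
    rows <- df$study == s
    any(is.na(df$reference_value[rows])) || any(df$in_calibration[rows] == 1L)
  }, logical(1))
  names(local_lab) <- as.character(studies)

  if (any(local_lab[as.character(df$study)] & is.na(df$local_value)))
    stop("local-laboratory subjects must have local_value", call. = FALSE)

  attr(df, "covariates") <- covariates
  attr(df, "local_lab") <- local_lab
  class(df) <- c("pooled_data", "data.frame")
  df
}

#' @export
print.pooled_data <- function(x, ...) {
  ll <- attr(x, "local_lab")
  cat("Pooled matched case-control dataset:",
      nrow(x), "subjects,", length(ll), "studies",
      sprintf("(%d local-laboratory)", sum(ll)), "\n")
  sid <- interaction(x$study, x$stratum, drop = TRUE)
  cat("  strata:", nlevels(sid),
      " cases:", sum(x$case), " controls:", sum(1 - x$case),
      " calibration subset:", sum(x$in_calibration), "\n")
  cv <- attr(x, "covariates")
  if (length(cv)) cat("  covariates:", paste(cv, collapse = ", "), "\n")
  invisible(x)
}

#' Read a pooled dataset from delimited text
#'
#' Expects a header with at least \code{study, stratum, case, local_value};
#' optional \code{reference_value} (empty field = not re-assayed) and
#' \code{in_calibration}.  Any other columns may be declared as covariates.
#'
#' @param path file path.
#' @param covariates character vector of covariate column names.
#' @param sep field separator; comma by default, tab accepted.
#' @return a [pooled_data()] object.
#' @export
read_pooled_csv <- function(path, covariates = character(), sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  pooled_data(df, covariates = covariates)
}

#' Write a pooled dataset to delimited text
#'
#' Missing reference measurements are written as empty fields.  A
#' write/read round trip through [read_pooled_csv()] reproduces the dataset.
#'
#' @param data a [pooled_data()] object.
#' @param path output file path.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
write_pooled_csv <- function(data, path, sep = ",") {
  stopifnot(inherits(data, "pooled_data"))
  utils::write.table(as.data.frame(data), path, sep = sep, na = "",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
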