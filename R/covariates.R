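# Tract-level covariates step at calendar-year boundaries; the canonical
# set is the five ACS-style measures used for areal ED-visit regressions.

#' Canonical covariate names
#'
#' The five tract-level social covariates: percentage with private
#' insurance, percentage with public insurance, median age, median income,
#' and percentage with at least a high-school diploma. Percentages are on
#' the raw 0--100 scale.
#' @export
covariateNamesDefault <- function()
  c("pct_private_insurance", "pct_public_insurance", "median_age",
    "median_income", "pct_hs_diploma")

#' Construct a CovariateTable
#'
#' @param x either a 3-d numeric array \code{[tract, year, covariate]} with
#'   dimnames, or a long data.frame with columns
#'   \code{tract_id,year,covariate,value} covering every combination.
#' @param percentage named logical: which covariates are 0--100
#'   percentages? Default: names starting with \code{"pct"}.
#' @return a \linkS4class{CovariateTable}.
#' @export
CovariateTable <- function(x, percentage = NULL) {
  if (is.data.frame(x)) {
    ids <- sort(unique(as.character(x$tract_id)))
    yrs <- sort(unique(as.integer(x$year)))
    cvs <- unique(as.character(x$covariate))
    arr <- array(NA_real_, c(length(ids), length(yrs), length(cvs)),
                 dimnames = list(ids, as.character(yrs), cvs))
    arr[cbind(match(x$tract_id, ids), match(x$year, yrs),
              match(x$covariate, cvs))] <- x$value
    if (any(is.na(arr)))
      stop("covariate table incomplete: a value is required for every ",
           "(tract, year, covariate)")
    x <- arr
  }
  cvs <- dimnames(x)[[3]]
  if (is.null(percentage))
    percentage <- setNames(startsWith(cvs, "pct"), cvs)
  new("CovariateTable", values = x, percentage = percentage[cvs])
}

#' Extract the covariate array or a cell-level design block
#'
#' \code{covariateValues} returns the raw \code{[tract, year, covariate]}
#' array. \code{covariateMatrix} expands it to one row per panel cell
#' (tract, period) in column-major cell order (tract index fastest),
#' assigning each monthly cell its calendar year's value.
#'
#' @param x a \linkS4class{CovariateTable}.
#' @param panel a \linkS4class{CountPanel} aligned to the same tracts.
#' @param covariates which covariates (default all, in table order).
#' @return array or (nT x k) matrix.
#' @export
covariateValues <- function(x) x@values

#' @rdname covariateValues
#' @export
covariateMatrix <- function(x, panel, covariates = covariateNames(x)) {
  ids <- tractIds(panel)
  yrs <- periodYears(panel)
  missY <- setdiff(as.character(yrs), dimnames(x@values)[[2]])
  if (length(missY))
    stop("covariates missing for panel year(s): ",
         paste(missY, collapse = ", "))
  missT <- setdiff(ids, tractIds(x))
  if (length(missT))
    stop("covariates missing for tract(s): ", paste(missT, collapse = ", "))
  n <- length(ids); T <- length(yrs)
  out <- matrix(NA_real_, n * T, length(covariates),
                dimnames = list(NULL, covariates))
  for (j in seq_along(covariates)) {
    block <- x@values[ids, as.character(yrs), covariates[j], drop = FALSE]
    out[, j] <- as.vector(block)   # tract index fastest, then period
  }
  out
}

#' Write / read a covariate table as long-format CSV
#'
#' Columns: \code{tract_id,year,covariate,value}.
#'
#' @param x a \linkS4class{CovariateTable}.
#' @param file CSV path.
#' @export
writeCovariates <- function(x, file) {
  d <- dim(x@values); dn <- dimnames(x@values)
  long <- data.frame(
    tract_id = rep(dn[[1]], times = d[2] * d[3]),
    year = rep(rep(dn[[2]], each = d[1]), times = d[3]),
    covariate = rep(dn[[3]], each = d[1] * d[2]),
    value = as.vector(x@values))
  utils::write.csv(long, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writeCovariates
#' @inheritParams CovariateTable
#' @export
readCovariates <- function(file, percentage = NULL) {
  long <- utils::read.csv(file, colClasses = c(tract_id = "character",
                                               covariate = "character"))
  CovariateTable(long, percentage = percentage)
}

#' Read a populations CSV (\code{tract_id,population})
#'
#' @param file CSV path.
#' @return named numeric vector.
#' @export
readPopulations <- function(file) {
  df <- utils::read.csv(file, colClasses = c(tract_id = "character"))
  setNames(df$population, df$tract_id)
}
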