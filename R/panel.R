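# CountPanel construction and plain-text IO. Panels are n x T count
# matrices in lattice (lexicographic) tract order with a constant
# population at risk per tract; periods are calendar years or months.

.periodSeq <- function(studyWindow, granularity) {
  sw <- as.Date(studyWindow)
  y0 <- as.integer(format(sw[1], "%Y")); y1 <- as.integer(format(sw[2], "%Y"))
  if (granularity == "year") {
    labs <- as.character(y0:y1)
    data.frame(period = labs, year = y0:y1, month = NA_integer_)
  } else {
    yrs <- rep(y0:y1, each = 12L)
    mos <- rep(1:12, times = y1 - y0 + 1L)
    first <- as.integer(format(sw[1], "%m")); last <- as.integer(format(sw[2], "%m"))
    keep <- !(yrs == y0 & mos < first) & !(yrs == y1 & mos > last)
    data.frame(period = sprintf("%d-%02d", yrs[keep], mos[keep]),
               year = yrs[keep], month = mos[keep])
  }
}

#' Construct a CountPanel
#'
#' @param counts n-by-T matrix of non-negative integer counts, rows in
#'   lattice tract order.
#' @param populations positive per-tract population at risk (length n).
#' @param tractIds tract identifiers (length n).
#' @param periods data.frame with columns \code{period}, \code{year} and
#'   optionally \code{month}, or a character vector of period labels
#'   (\code{"2018"} or \code{"2018-01"} style).
#' @param granularity \code{"year"} or \code{"month"}; inferred from the
#'   period labels when missing.
#' @param category optional category label the panel was built for.
#' @return a \linkS4class{CountPanel}.
#' @export
CountPanel <- function(counts, populations, tractIds = rownames(counts),
                       periods = colnames(counts), granularity = NULL,
                       category = "ALL") {
  counts <- as.matrix(counts)
  if (is.character(periods) || is.null(dim(periods))) {
    labs <- as.character(periods)
    monthly <- grepl("-", labs[1], fixed = TRUE)
    periods <- data.frame(
      period = labs,
      year = as.integer(substr(labs, 1, 4)),
      month = if (monthly) as.integer(substr(labs, 6, 7)) else NA_integer_)
  }
  if (is.null(granularity))
    granularity <- if (all(is.na(periods$month))) "year" else "month"
  storage.mode(counts) <- "integer"
  rownames(counts) <- tractIds
  colnames(counts) <- periods$period
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(tract_id = as.character(tractIds),
                                   population = as.numeric(populations)),
    colData = S4Vectors::DataFrame(periods))
  S4Vectors::metadata(se)$granularity <- granularity
  S4Vectors::metadata(se)$category <- category
  methods::as(se, "CountPanel")
}

#' Aggregate visit records into a CountPanel
#'
#' Counts, per tract and calendar period, the visits whose diagnosis-code
#' set contains the requested category (\code{"ALL"}: any visit matching at
#' least one category). Visits dated outside the study window, and visits
#' whose codes match no category, are excluded and reported via a message.
#'
#' @param visits validated visit table (see \code{\link{validateVisits}}).
#' @param lattice a \linkS4class{TractLattice}; all visit tract ids must be
#'   declared in it.
#' @param populations named per-tract population vector (names = tract
#'   ids), or unnamed in lattice order.
#' @param map a \linkS4class{CategoryMap}.
#' @param category one of the map's categories, or \code{"ALL"}.
#' @param granularity \code{"year"} or \code{"month"} bins (half-open
#'   calendar bins by visit date).
#' @param studyWindow length-2 date vector bounding the panel.
#' @return a \linkS4class{CountPanel}.
#' @export
buildPanel <- function(visits, lattice, populations,
                       map = defaultCategoryMap(), category = "ALL",
                       granularity = c("year", "month"),
                       studyWindow = as.Date(c("2018-01-01", "2021-12-31"))) {
  granularity <- match.arg(granularity)
  visits <- validateVisits(visits, studyWindow)
  ids <- tractIds(lattice)
  if (is.null(names(populations))) names(populations) <- ids
  if (any(populations[ids] <= 0) || any(is.na(populations[ids])))
    stop("populations must be positive for every lattice tract")
  unknown <- setdiff(visits$tract_id, ids)
  if (length(unknown))
    stop("visit tract ids not in lattice: ",
         paste(unique(unknown), collapse = ", "))
  per <- .periodSeq(studyWindow, granularity)
  Y <- matrix(0L, length(ids), nrow(per), dimnames = list(ids, per$period))

  sw <- as.Date(studyWindow)
  inWindow <- visits$date >= sw[1] & visits$date <= sw[2]
  if (any(!inWindow))
    message(sum(!inWindow), " visit(s) outside the study window excluded")
  visits <- visits[inWindow, , drop = FALSE]

  unmapped <- 0L
  if (nrow(visits)) {
    lab <- if (granularity == "year") format(visits$date, "%Y")
           else format(visits$date, "%Y-%m")
    for (r in seq_len(nrow(visits))) {
      hit <- categorizeVisit(visits$icd_codes[[r]], map)
      if (!length(hit)) { unmapped <- unmapped + 1L; next }
      if (category == "ALL" || category %in% hit)
        Y[visits$tract_id[r], lab[r]] <- Y[visits$tract_id[r], lab[r]] + 1L
    }
  }
  if (unmapped > 0L)
    message(unmapped, " visit(s) with no mappable diagnosis code excluded")
  CountPanel(Y, populations[ids], tractIds = ids, periods = per,
             granularity = granularity, category = category)
}

#' Write / read a CountPanel as long-format CSV
#'
#' \code{writePanel} emits \code{tract_id,period,category,count} rows plus a
#' separate \code{tract_id,population} CSV; \code{readPanel} reverses this
#' exactly (counts, populations and period labels round-trip unchanged).
#'
#' @param panel a \linkS4class{CountPanel}.
#' @param countsFile,populationsFile CSV paths.
#' @return \code{readPanel}: a \linkS4class{CountPanel}.
#' @export
writePanel <- function(panel, countsFile, populationsFile) {
  Y <- panelCounts(panel)
  long <- data.frame(
    tract_id = rep(rownames(Y), times = ncol(Y)),
    period = rep(colnames(Y), each = nrow(Y)),
    category = S4Vectors::metadata(panel)$category %||% "ALL",
    count = as.vector(Y))
  utils::write.csv(long, countsFile, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(tract_id = tractIds(panel),
                              population = unname(populations(panel))),
                   populationsFile, row.names = FALSE, quote = FALSE)
  invisible(countsFile)
}

#' @rdname writePanel
#' @param category when the counts file holds several categories, which one
#'   to load (default: the single category present).
#' @export
readPanel <- function(countsFile, populationsFile, category = NULL) {
  long <- utils::read.csv(countsFile,
                          colClasses = c(tract_id = "character",
                                         period = "character"))
  if (is.null(category)) {
    category <- unique(long$category)
    if (length(category) != 1)
      stop("counts file holds several categories; pick one of: ",
           paste(category, collapse = ", "))
  }
  long <- long[long$category == category, , drop = FALSE]
  ids <- sort(unique(long$tract_id))
  per <- sort(unique(long$period))
  Y <- matrix(0L, length(ids), length(per), dimnames = list(ids, per))
  Y[cbind(match(long$tract_id, ids), match(long$period, per))] <- long$count
  pop <- utils::read.csv(populationsFile,
                         colClasses = c(tract_id = "character"))
  CountPanel(Y, setNames(pop$population, pop$tract_id)[ids],
             tractIds = ids, periods = per, category = category)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Observed per-capita rates of a panel
#'
#' @param panel a \linkS4class{CountPanel}.
#' @param margin \code{"cell"} (n x T matrix), or \code{"tract"} (per-tract
#'   totals divided by population, the areal rates used for Moran's I).
#' @param periods optional subset of period labels for the \code{"tract"}
#'   margin.
#' @return matrix or vector of rates.
#' @export
panelRates <- function(panel, margin = c("cell", "tract"), periods = NULL) {
  margin <- match.arg(margin)
  Y <- panelCounts(panel); P <- unname(populations(panel))
  if (margin == "cell") return(sweep(Y, 1, P, "/"))
  if (!is.null(periods)) Y <- Y[, periodLabels(panel) %in% periods,
                                drop = FALSE]
  setNames(rowSums(Y) / P, tractIds(panel))
}
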