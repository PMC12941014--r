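# ICD-10 visit categorisation. Eight diagnosis categories are used for ED
# mental-health surveillance; a visit carrying codes from several categories
# is counted in each of them. Substance-use stems (F10-F19) are listed
# undotted and match by prefix, everything else by exact string equality.

.icdPattern <- "^[A-Z][0-9][0-9A-Z]*(\\.[0-9A-Z]+)?$"

#' Construct a CategoryMap
#'
#' @param codeSets named list of exact-match ICD-10 code vectors, one
#'   element per category, in display order.
#' @param prefixSets named list of prefix-match stems (same names); stems
#'   match themselves and any code that extends them.
#' @return a \linkS4class{CategoryMap}.
#' @export
CategoryMap <- function(codeSets, prefixSets = NULL) {
  cats <- names(codeSets)
  if (is.null(prefixSets))
    prefixSets <- setNames(rep(list(character()), length(cats)), cats)
  for (cc in setdiff(cats, names(prefixSets)))
    prefixSets[[cc]] <- character()
  prefixSets <- prefixSets[cats]
  allCodes <- c(unlist(codeSets), unlist(prefixSets))
  bad <- allCodes[!grepl(.icdPattern, allCodes)]
  if (length(bad))
    stop("codes not matching the ICD-10 lexical pattern: ",
         paste(unique(bad), collapse = ", "))
  new("CategoryMap", categories = cats, codeSets = codeSets,
      prefixSets = prefixSets)
}

#' The default eight-category mental-health diagnosis map
#'
#' Exact ICD-10 code lists for Depression, Bipolar Disorder, Anxiety, PTSD,
#' OCD, Psychosis, Substance Abuse and Other, as used in ED mental-health
#' surveillance. The undotted substance-use stems F10--F19 are prefix
#' entries (F10 matches F10.10 etc.); all other codes match exactly.
#'
#' @return a \linkS4class{CategoryMap} with 8 categories.
#' @export
defaultCategoryMap <- function() {
  codes <- list(
    "Depression" = c(
      "F32.0", "F32.1", "F32.2", "F32.3", "F32.4", "F32.5", "F32.8",
      "F32.89", "F32.9", "F32A",
      "F33.0", "F33.1", "F33.2", "F33.3", "F33.4", "F33.40", "F33.41",
      "F33.42", "F33.8", "F33.9", "F34.1", "F53.0", "O90.6", "O99.34"),
    "Bipolar Disorder" = c(
      "F30.10", "F30.11", "F30.12", "F30.13", "F30.2", "F30.3", "F30.4",
      "F30.8", "F30.9",
      "F31.0", "F31.10", "F31.11", "F31.1", "F31.13", "F31.2", "F31.30",
      "F31.31", "F31.32", "F31.4", "F31.5", "F31.60", "F31.61", "F31.62",
      "F31.63", "F31.64", "F31.70", "F31.71", "F31.72", "F31.73", "F31.74",
      "F31.75", "F31.76", "F31.78", "F31.81", "F31.89", "F31.9",
      "F34.0", "F34.81", "F34.89", "F39"),
    "Anxiety" = c(
      "F06.4", "F40.9", "F40.00", "F40.01", "F40.10", "F40.11", "F40.218",
      "F40.240", "F40.241", "F40.8", "F41.0", "F41.1", "F41.3", "F41.8",
      "F41.9", "F43.0", "F45.8", "F48.8", "F48.9", "F93.8", "F99", "R45.7"),
    "PTSD" = c("F43.10", "F43.11", "F43.12"),
    "OCD" = c("F42.2", "F42.3", "F42.4", "F42.8", "F42.9", "R46.81"),
    "Psychosis" = c(
      "F06.0", "F06.2", "F20.0", "F20.1", "F20.2", "F20.3", "F20.5",
      "F20.81", "F20.89", "F20.9", "F21", "F22", "F23", "F24", "F25.0",
      "F25.1", "F25.8", "F25.9", "F28", "F29", "F53.1", "F44.0", "F44.1",
      "F44.2", "F44.81", "F44.89", "F44.9", "F48.1", "F48.2"),
    "Substance Abuse" = c(
      "O99.320", "O99.321", "O99.322", "O99.323", "O99.324", "O99.325"),
    "Other" = c(
      "R45.850", "R45.851", "F06.1", "F06.30", "F06.31", "F06.32", "F06.33",
      "F06.34", "F34.9", "F43.20", "F43.21", "F43.22", "F43.23", "F43.24",
      "F43.25", "F43.29", "F43.81", "F43.89", "F43.9", "F44.4", "F44.5",
      "F44.6", "F44.7", "F45.0", "F45.1", "F45.20", "F45.21", "F45.22",
      "F45.29", "F45.41", "F45.42", "F45.9", "F51.01", "F51.02", "F51.03",
      "F51.04", "F51.05", "F51.09", "F51.11", "F51.12", "F51.13", "F51.19",
      "F51.8", "F51.9", "F54", "F59", "O99.340", "O99.341", "O99.342",
      "O99.343", "O99.344", "O99.345"))
  prefixes <- list(
    "Substance Abuse" = c("F10", "F11", "F12", "F13", "F14", "F15", "F16",
                          "F17", "F18", "F19"))
  CategoryMap(codes, prefixes)
}

#' Categorise one visit's ICD-10 codes
#'
#' Returns every category with at least one matching code: a code matches a
#' category by exact equality against its code set, or by prefix against
#' its stem set. A visit can yield several categories (it is counted in
#' each) but never the same category twice; unmatched codes yield nothing.
#'
#' @param codes character vector of ICD-10 codes for one visit.
#' @param map a \linkS4class{CategoryMap}.
#' @return character vector of matched category labels, in map order
#'   (possibly empty).
#' @export
categorizeVisit <- function(codes, map = defaultCategoryMap()) {
  codes <- unique(as.character(codes))
  hit <- vapply(map@categories, function(cc) {
    if (any(codes %in% map@codeSets[[cc]])) return(TRUE)
    stems <- map@prefixSets[[cc]]
    length(stems) > 0 &&
      any(vapply(codes, function(cd) any(startsWith(cd, stems)), TRUE))
  }, TRUE)
  map@categories[hit]
}

#' Validate a visit-record table
#'
#' Visit records are a data.frame with columns \code{tract_id} (character),
#' \code{date} (Date or ISO-8601 string), \code{icd_codes} (list column of
#' character vectors, or semicolon-delimited strings), \code{age} and
#' \code{sex}. Codes must be non-empty and lexically valid ICD-10 strings;
#' dates must fall inside the study window.
#'
#' @param visits the record table.
#' @param studyWindow length-2 Date (or string) vector: first and last
#'   admissible visit date.
#' @return the normalised data.frame (Date dates, list-column codes).
#' @export
validateVisits <- function(visits,
                           studyWindow = as.Date(c("2018-01-01",
                                                   "2021-12-31"))) {
  need <- c("tract_id", "date", "icd_codes")
  if (!all(need %in% names(visits)))
    stop("visit table needs columns: ", paste(need, collapse = ", "))
  visits$tract_id <- as.character(visits$tract_id)
  visits$date <- as.Date(visits$date)
  if (!is.list(visits$icd_codes))
    visits$icd_codes <- strsplit(as.character(visits$icd_codes), ";",
                                 fixed = TRUE)
  visits$icd_codes <- lapply(visits$icd_codes, function(x) trimws(x))
  if (any(lengths(visits$icd_codes) == 0))
    stop("every visit must carry at least one ICD-10 code")
  codes <- unlist(visits$icd_codes)
  bad <- codes[!grepl(.icdPattern, codes)]
  if (length(bad))
    stop("lexically invalid ICD-10 codes: ",
         paste(unique(bad), collapse = ", "))
  sw <- as.Date(studyWindow)
  if (any(is.na(visits$date)))
    stop("unparseable visit dates")
  attr(visits, "studyWindow") <- sw
  visits
}

#' Read a visit CSV
#'
#' Expects header \code{tract_id,date,icd_codes,age,sex} with ISO-8601
#' dates and semicolon-delimited ICD-10 codes.
#'
#' @inheritParams validateVisits
#' @param file path to the CSV.
#' @return validated visit data.frame (see \code{\link{validateVisits}}).
#' @export
readVisits <- function(file, studyWindow = as.Date(c("2018-01-01",
                                                     "2021-12-31"))) {
  df <- utils::read.csv(file, colClasses = "character")
  validateVisits(df, studyWindow)
}

#' Two-period diagnosis tally with column percentages
#'
#' Splits visits at a cut date into a before/during two-period table: per
#' category the visit count in each period (a multi-diagnosis visit counts
#' once in every matched category), column percentages (100 x count /
#' column total, 2 decimals), row totals, and a grand-total row.
#'
#' @param visits validated visit table (see \code{\link{validateVisits}}).
#' @param map a \linkS4class{CategoryMap}.
#' @param splitDate first date of the second ("during") period.
#' @return data.frame with columns \code{category}, \code{before_n},
#'   \code{before_pct}, \code{during_n}, \code{during_pct}, \code{total_n},
#'   \code{total_pct}.
#' @export
covidSplitTable <- function(visits, map = defaultCategoryMap(),
                            splitDate = as.Date("2020-01-01")) {
  visits <- validateVisits(visits)
  cats <- categoryNames(map)
  before <- setNames(numeric(length(cats)), cats)
  during <- before
  if (nrow(visits)) {
    isDuring <- visits$date >= as.Date(splitDate)
    for (r in seq_len(nrow(visits))) {
      hit <- categorizeVisit(visits$icd_codes[[r]], map)
      if (isDuring[r]) during[hit] <- during[hit] + 1
      else before[hit] <- before[hit] + 1
    }
  }
  tot <- before + during
  pct <- function(x) {
    s <- sum(x)
    if (s == 0) rep(0, length(x)) else round(100 * x / s, 2)
  }
  out <- data.frame(category = c(cats, "Total"),
                    before_n = c(before, sum(before)),
                    before_pct = c(pct(before), if (sum(before)) 100 else 0),
                    during_n = c(during, sum(during)),
                    during_pct = c(pct(during), if (sum(during)) 100 else 0),
                    total_n = c(tot, sum(tot)),
                    total_pct = c(pct(tot), if (sum(tot)) 100 else 0),
                    row.names = NULL)
  out
}
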