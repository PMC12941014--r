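#' @rdname TractLattice-class
#' @param x,object an object.
#' @export
setGeneric("tractIds", function(x) standardGeneric("tractIds"))

#' @rdname TractLattice-class
#' @export
setGeneric("nTracts", function(x) standardGeneric("nTracts"))

#' @rdname TractLattice-class
#' @export
setGeneric("neighborCounts", function(x) standardGeneric("neighborCounts"))

#' @rdname TractLattice-class
#' @export
setGeneric("neighborList", function(x) standardGeneric("neighborList"))

#' @rdname TractLattice-class
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname CountPanel-class
#' @export
setGeneric("panelCounts", function(x) standardGeneric("panelCounts"))

#' @rdname CountPanel-class
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname CountPanel-class
#' @export
setGeneric("periodLabels", function(x) standardGeneric("periodLabels"))

#' @rdname CountPanel-class
#' @export
setGeneric("periodYears", function(x) standardGeneric("periodYears"))

#' @rdname CountPanel-class
#' @export
setGeneric("granularity", function(x) standardGeneric("granularity"))

#' @rdname CountPanel-class
#' @export
setGeneric("nPeriods", function(x) standardGeneric("nPeriods"))

#' @rdname CategoryMap-class
#' @export
setGeneric("categoryNames", function(x) standardGeneric("categoryNames"))

#' @rdname CovariateTable-class
#' @export
setGeneric("covariateNames", function(x) standardGeneric("covariateNames"))

#' @rdname CovariateTable-class
#' @export
setGeneric("covariateYears", function(x) standardGeneric("covariateYears"))

#' @rdname STFit-class
#' @export
setGeneric("posteriorSummary", function(x) standardGeneric("posteriorSummary"))

#' @rdname STFit-class
#' @export
setGeneric("fittedRates", function(x) standardGeneric("fittedRates"))

#' Deviance information criterion of a fitted model
#'
#' @param x an \linkS4class{STFit}.
#' @param ... unused.
#' @export
setGeneric("dic", function(x, ...) standardGeneric("dic"))

# ---- accessor methods ------------------------------------------------------

#' @rdname TractLattice-class
#' @export
setMethod("tractIds", "TractLattice", function(x) x@tractIds)

#' @rdname TractLattice-class
#' @export
setMethod("nTracts", "TractLattice", function(x) length(x@tractIds))

#' @rdname TractLattice-class
#' @export
setMethod("neighborCounts", "TractLattice", function(x)
  setNames(as.integer(Matrix::rowSums(x@adjacency)), x@tractIds))

#' @rdname TractLattice-class
#' @export
setMethod("neighborList", "TractLattice", function(x) {
  A <- x@adjacency
  out <- lapply(seq_len(nrow(A)), function(i) which(A[i, ] != 0))
  names(out) <- x@tractIds
  out
})

#' @rdname TractLattice-class
#' @export
setMethod("adjacencyMatrix", "TractLattice", function(x) x@adjacency)

#' @rdname CountPanel-class
#' @export
setMethod("panelCounts", "CountPanel", function(x)
  SummarizedExperiment::assay(x, "counts"))

#' @rdname CountPanel-class
#' @export
setMethod("populations", "CountPanel", function(x)
  setNames(SummarizedExperiment::rowData(x)$population,
           SummarizedExperiment::rowData(x)$tract_id))

#' @rdname CountPanel-class
#' @export
setMethod("tractIds", "CountPanel", function(x)
  as.character(SummarizedExperiment::rowData(x)$tract_id))

#' @rdname CountPanel-class
#' @export
setMethod("periodLabels", "CountPanel", function(x)
  as.character(SummarizedExperiment::colData(x)$period))

#' @rdname CountPanel-class
#' @export
setMethod("periodYears", "CountPanel", function(x)
  as.integer(SummarizedExperiment::colData(x)$year))

#' @rdname CountPanel-class
#' @export
setMethod("granularity", "CountPanel", function(x)
  S4Vectors::metadata(x)$granularity)

#' @rdname CountPanel-class
#' @export
setMethod("nPeriods", "CountPanel", function(x) ncol(x))

#' @rdname CategoryMap-class
#' @export
setMethod("categoryNames", "CategoryMap", function(x) x@categories)

#' @rdname CovariateTable-class
#' @export
setMethod("covariateNames", "CovariateTable", function(x)
  dimnames(x@values)[[3]])

#' @rdname CovariateTable-class
#' @export
setMethod("covariateYears", "CovariateTable", function(x)
  as.integer(dimnames(x@values)[[2]]))

#' @rdname CovariateTable-class
#' @export
setMethod("tractIds", "CovariateTable", function(x) dimnames(x@values)[[1]])

#' @rdname STFit-class
#' @export
setMethod("posteriorSummary", "STFit", function(x) x@summary)

#' @rdname STFit-class
#' @export
setMethod("fittedRates", "STFit", function(x) x@lambda)

# ---- show methods ----------------------------------------------------------

setMethod("show", "TractLattice", function(object) {
  m <- neighborCounts(object)
  cat("TractLattice with", nTracts(object), "tracts,",
      sum(m) / 2, "edges\n")
  cat("  neighbour counts: min", if (length(m)) min(m) else NA,
      "median", if (length(m)) median(m) else NA,
      "max", if (length(m)) max(m) else NA, "\n")
  if (any(m == 0))
    cat("  isolated tracts:", paste(names(m)[m == 0], collapse = ", "), "\n")
})

setMethod("show", "CategoryMap", function(object) {
  cat("CategoryMap with", length(object@categories), "categories\n")
  for (cc in object@categories)
    cat(sprintf("  %-18s %d exact + %d prefix codes\n", cc,
                length(object@codeSets[[cc]]),
                length(object@prefixSets[[cc]])))
})

setMethod("show", "CovariateTable", function(object) {
  d <- dim(object@values)
  cat("CovariateTable:", d[1], "tracts x", d[2], "years x", d[3],
      "covariates\n")
  cat("  covariates:", paste(covariateNames(object), collapse = ", "), "\n")
  cat("  years:", paste(range(covariateYears(object)), collapse = "-"), "\n")
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", object@temporal, "temporal structure,",
      object@likelihood, "likelihood\n")
  cat("  covariates:",
      if (length(object@covariateNames))
        paste(object@covariateNames, collapse = ", ") else "(none)", "\n")
  cat("  spatial ICAR:", object@spatial, " iid heterogeneity:", object@iid,
      "\n")
})

setMethod("show", "MoranResult", function(object) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f under independence, N = %d)\n",
              object@I, object@expectedI, as.integer(object@n)))
  cat(sprintf("  one-sided permutation p = %.4g (%d permutations, %s weights)\n",
              object@pValue, as.integer(object@nPerm), object@scheme))
})

setMethod("show", "STFit", function(object) {
  cat("STFit:", object@spec@temporal, "model,", object@spec@likelihood,
      "likelihood\n")
  d <- object@diagnostics
  cat(sprintf("  DIC = %.2f (Dbar = %.2f, pD = %.2f)\n",
              d$DIC, d$Dbar, d$pD))
  cat("  converged:", object@converged, "\n")
  print(head(object@summary, 12))
  if (nrow(object@summary) > 12) cat("  ...\n")
})
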