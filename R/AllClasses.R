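#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal rowSums colSums t isSymmetric diag
#' @importFrom stats rnorm rgamma rpois rnbinom runif quantile var sd median
#'   lm setNames complete.cases qgamma pgamma dpois dnbinom aggregate
#' @importFrom utils read.csv write.csv head
#' @importClassesFrom Matrix dgCMatrix
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @useDynLib stareal, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' TractLattice: areal units with a symmetric neighbourhood structure
#'
#' Holds the tract identifiers of an areal lattice together with a binary,
#' symmetric, zero-diagonal adjacency matrix. The lattice fixes the tract
#' ordering used by every downstream array (counts, covariates, random
#' effects): identifiers are sorted lexicographically at construction.
#'
#' @slot tractIds character vector of unique tract identifiers, in the fixed
#'   (lexicographic) order used by all downstream arrays.
#' @slot adjacency symmetric binary \code{dgCMatrix} with zero diagonal;
#'   \code{adjacency[i, j] == 1} iff tracts \code{i} and \code{j} are
#'   neighbours.
#' @export
setClass("TractLattice",
  representation(tractIds = "character", adjacency = "dgCMatrix"))

setValidity("TractLattice", function(object) {
  n <- length(object@tractIds)
  A <- object@adjacency
  msg <- character()
  if (anyDuplicated(object@tractIds))
    msg <- c(msg, "tract ids must be unique")
  if (nrow(A) != n || ncol(A) != n)
    msg <- c(msg, "adjacency dimensions must match number of tracts")
  if (n > 0) {
    if (!Matrix::isSymmetric(A, tol = 0))
      msg <- c(msg, "adjacency must be symmetric")
    if (any(Matrix::diag(A) != 0))
      msg <- c(msg, "self-neighbours are not allowed")
    if (length(A@x) && !all(A@x %in% c(0, 1)))
      msg <- c(msg, "adjacency entries must be 0/1")
  }
  if (length(msg)) msg else TRUE
})

#' CategoryMap: ICD-10 code sets defining diagnosis categories
#'
#' Maps ICD-10 code strings to named diagnosis categories. Codes match
#' either by exact string equality or, for designated stem entries (e.g.
#' undotted substance-use stems such as \code{"F10"}), by prefix: the stem
#' matches itself and any code extending it (\code{F10} matches
#' \code{F10.10}).
#'
#' @slot categories ordered character vector of category labels.
#' @slot codeSets named list (one element per category) of exact-match code
#'   strings.
#' @slot prefixSets named list (one element per category) of prefix-match
#'   stems.
#' @export
setClass("CategoryMap",
  representation(categories = "character", codeSets = "list",
                 prefixSets = "list"))

setValidity("CategoryMap", function(object) {
  msg <- character()
  if (anyDuplicated(object@categories))
    msg <- c(msg, "category labels must be unique")
  if (!identical(names(object@codeSets), object@categories) ||
      !identical(names(object@prefixSets), object@categories))
    msg <- c(msg, "codeSets/prefixSets must be named by the categories")
  allCodes <- c(unlist(object@codeSets), unlist(object@prefixSets))
  if (anyDuplicated(allCodes))
    msg <- c(msg, "each code may appear in exactly one category")
  if (length(msg)) msg else TRUE
})

#' CountPanel: counts by tract and period with populations at risk
#'
#' A \linkS4class{SummarizedExperiment} whose single \code{"counts"} assay is
#' the n-by-T matrix of event counts Y[i, t]. \code{rowData} carries the
#' tract id and the (time-constant) population at risk P_i; \code{colData}
#' carries the period label, calendar year and (for monthly panels) month.
#' Granularity (\code{"year"} or \code{"month"}) is stored in
#' \code{metadata(x)$granularity}.
#'
#' @export
setClass("CountPanel", contains = "SummarizedExperiment")

setValidity("CountPanel", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("a 'counts' assay is required")
  Y <- SummarizedExperiment::assay(object, "counts")
  if (any(is.na(Y)) || any(Y < 0) || any(Y != round(Y)))
    msg <- c(msg, "counts must be non-negative integers")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("tract_id", "population") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain tract_id and population")
  else if (any(rd$population <= 0))
    msg <- c(msg, "populations must be positive")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("period", "year") %in% colnames(cd)))
    msg <- c(msg, "colData must contain period and year")
  else if (is.unsorted(as.character(cd$period), strictly = TRUE))
    msg <- c(msg, "period labels must be strictly increasing")
  g <- S4Vectors::metadata(object)$granularity
  if (is.null(g) || !g %in% c("year", "month"))
    msg <- c(msg, "metadata granularity must be 'year' or 'month'")
  if (length(msg)) msg else TRUE
})

#' CovariateTable: tract-level covariates stepping at calendar years
#'
#' A complete tract-by-year-by-covariate array. Percentage covariates are on
#' the raw 0--100 scale; which covariates are percentages is recorded so the
#' range can be validated.
#'
#' @slot values numeric array \code{[tract, year, covariate]} with dimnames.
#' @slot percentage named logical vector: is each covariate a 0--100
#'   percentage?
#' @export
setClass("CovariateTable",
  representation(values = "array", percentage = "logical"))

setValidity("CovariateTable", function(object) {
  v <- object@values
  msg <- character()
  if (length(dim(v)) != 3)
    return("values must be a 3-d [tract, year, covariate] array")
  if (is.null(dimnames(v)) || any(vapply(dimnames(v), is.null, TRUE)))
    msg <- c(msg, "values must have complete dimnames")
  if (any(is.na(v)))
    msg <- c(msg, "covariate table must be complete (no NA)")
  if (!identical(names(object@percentage), dimnames(v)[[3]]))
    msg <- c(msg, "percentage flags must be named by the covariates")
  else {
    for (j in which(object@percentage)) {
      vj <- v[, , j, drop = TRUE]
      if (any(vj < 0 | vj > 100, na.rm = TRUE))
        msg <- c(msg, sprintf("percentage covariate '%s' outside [0, 100]",
                              dimnames(v)[[3]][j]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' PriorConfig: prior settings for fixed effects and hyperparameters
#'
#' Defaults follow common disease-mapping practice: a flat (precision 0)
#' normal prior on the intercept, vague normal(0, precision 0.001) priors on
#' slopes, and gamma(shape 1, rate 0.00005) priors on every precision
#' hyperparameter (prior mean shape/rate = 20,000). The negative-binomial
#' log-dispersion gets a vague normal prior.
#'
#' @slot interceptMean,interceptPrec normal prior on the intercept;
#'   precision 0 means flat/improper.
#' @slot slopeMean,slopePrec normal prior on each regression slope.
#' @slot tauShape,tauRate gamma(shape, rate) prior on each precision.
#' @slot logThetaMean,logThetaPrec normal prior on the log of the
#'   negative-binomial dispersion.
#' @export
setClass("PriorConfig",
  representation(interceptMean = "numeric", interceptPrec = "numeric",
                 slopeMean = "numeric", slopePrec = "numeric",
                 tauShape = "numeric", tauRate = "numeric",
                 logThetaMean = "numeric", logThetaPrec = "numeric"))

setValidity("PriorConfig", function(object) {
  msg <- character()
  if (object@interceptPrec < 0 || object@slopePrec < 0 ||
      object@logThetaPrec < 0)
    msg <- c(msg, "normal prior precisions must be >= 0")
  if (object@tauShape <= 0 || object@tauRate <= 0)
    msg <- c(msg, "gamma prior shape and rate must be > 0")
  if (length(msg)) msg else TRUE
})

#' ModelSpec: which spatio-temporal model to fit
#'
#' Selects the temporal structure (models 1--5), the count likelihood, the
#' covariates entering the linear predictor, the priors, and whether the
#' spatial (ICAR) and unstructured tract effects are included (both on by
#' default; switching them off yields plain log-linear regression, used
#' e.g. by the conjugate-oracle tests).
#'
#' @slot temporal one of \code{"year"} (indicators for 2019/2020/2021,
#'   reference 2018), \code{"covid"} (single 2020--2021 indicator),
#'   \code{"rw1_year"}, \code{"rw1_month"}, \code{"rw1_month_type1"}
#'   (monthly RW1 plus i.i.d. cell-level interaction), or \code{"none"}.
#' @slot likelihood \code{"poisson"} or \code{"negbin"}.
#' @slot covariateNames ordered covariate names (may be empty).
#' @slot priors a \linkS4class{PriorConfig}.
#' @slot spatial,iid include the ICAR field s / the i.i.d. field v?
#' @export
setClass("ModelSpec",
  representation(temporal = "character", likelihood = "character",
                 covariateNames = "character", priors = "PriorConfig",
                 spatial = "logical", iid = "logical"))

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (!object@temporal %in% c("year", "covid", "rw1_year", "rw1_month",
                              "rw1_month_type1", "none"))
    msg <- c(msg, "unknown temporal structure")
  if (!object@likelihood %in% c("poisson", "negbin"))
    msg <- c(msg, "likelihood must be 'poisson' or 'negbin'")
  if (length(msg)) msg else TRUE
})

#' SimulationTruth: known parameters behind a simulated panel
#'
#' Container for every generative parameter of the simulation module:
#' intercept, slopes, temporal fixed effects, the latent spatial (ICAR) and
#' unstructured fields, random-walk and i.i.d. time effects, the optional
#' space-time interaction, all precision hyperparameters, and the optional
#' negative-binomial dispersion. Empty slots (length 0) mean "term absent".
#'
#' @export
setClass("SimulationTruth",
  representation(beta0 = "numeric", beta = "numeric",
                 alphaYear = "numeric", alphaCovid = "numeric",
                 s = "numeric", v = "numeric",
                 gamma = "numeric", phi = "numeric", delta = "matrix",
                 tauS = "numeric", tauV = "numeric", tauGamma = "numeric",
                 tauPhi = "numeric", tauDelta = "numeric",
                 nbDispersion = "numeric", seed = "numeric"))

setValidity("SimulationTruth", function(object) {
  msg <- character()
  taus <- c(object@tauS, object@tauV, object@tauGamma, object@tauPhi,
            object@tauDelta)
  if (any(taus <= 0))
    msg <- c(msg, "all precisions must be > 0")
  if (length(object@s) && abs(sum(object@s)) > 1e-6 * max(1, sd(object@s)))
    msg <- c(msg, "spatial field must sum to zero")
  if (length(object@nbDispersion) && any(object@nbDispersion <= 0))
    msg <- c(msg, "nb dispersion must be > 0")
  if (length(msg)) msg else TRUE
})

#' STFit: posterior summaries and draws from a fitted model
#'
#' @slot spec the \linkS4class{ModelSpec} that was fitted.
#' @slot summary data.frame of posterior mean, sd, 2.5\%/97.5\% quantiles,
#'   effective sample size and split-chain Rhat for every reported
#'   parameter (fixed effects, precisions, dispersion).
#' @slot draws list, one matrix (draws x parameters) per chain, for the
#'   reported parameters.
#' @slot latent list of posterior means of the latent fields
#'   (\code{s}, \code{v}, \code{gamma}, \code{phi}, \code{delta}) and the
#'   plug-in linear predictor pieces.
#' @slot lambda matrix of posterior mean rates lambda[i, t] (per capita).
#' @slot devianceDraws -2 log-likelihood evaluated at each retained draw
#'   (all chains concatenated).
#' @slot diagnostics list: DIC pieces, acceptance rates, max |sum(s)| over
#'   retained draws, convergence thresholds.
#' @slot converged logical: did every reported parameter meet the Rhat and
#'   effective-sample-size thresholds?
#' @export
setClass("STFit",
  representation(spec = "ModelSpec", summary = "data.frame", draws = "list",
                 latent = "list", lambda = "matrix",
                 devianceDraws = "numeric", diagnostics = "list",
                 converged = "logical"))

#' MoranResult: Moran's I with permutation inference
#'
#' @slot I observed Moran's I.
#' @slot expectedI the null expectation -1/(N-1).
#' @slot pValue one-sided (greater) permutation p-value.
#' @slot nPerm number of permutations.
#' @slot scheme weight scheme, \code{"binary"} or \code{"row"}.
#' @slot n number of regions N.
#' @slot permuted the permuted statistics (kept for diagnostics).
#' @export
setClass("MoranResult",
  representation(I = "numeric", expectedI = "numeric", pValue = "numeric",
                 nPerm = "numeric", scheme = "character", n = "numeric",
                 permuted = "numeric"))

setValidity("MoranResult", function(object) {
  msg <- character()
  if (abs(object@expectedI - (-1 / (object@n - 1))) > 1e-12)
    msg <- c(msg, "expectedI must equal -1/(N-1)")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "p-value must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
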