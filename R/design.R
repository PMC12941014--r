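# Model specification and design assembly. The five temporal structures
# share a BYM spatial block (ICAR field s + i.i.d. heterogeneity v) and a
# log-population offset; they differ in how calendar time enters:
#   model 1  year indicators (reference = first year)
#   model 2  single pandemic indicator (last two of four years)
#   model 3  yearly RW1 + i.i.d. yearly effects
#   model 4  monthly RW1 + i.i.d. monthly effects
#   model 5  model 4 + i.i.d. space-time interaction delta_it

#' Prior configuration constructor
#'
#' Defaults: flat intercept (precision 0), vague normal(0, 0.001) slopes,
#' gamma(1, 0.00005) on every precision (prior mean 20,000), vague normal
#' prior on the log of the negative-binomial dispersion.
#'
#' @param interceptMean,interceptPrec,slopeMean,slopePrec normal priors on
#'   fixed effects (precision 0 = flat).
#' @param tauShape,tauRate gamma prior on each precision hyperparameter.
#' @param logThetaMean,logThetaPrec normal prior on log dispersion.
#' @return a \linkS4class{PriorConfig}.
#' @export
priorConfig <- function(interceptMean = 0, interceptPrec = 0,
                        slopeMean = 0, slopePrec = 0.001,
                        tauShape = 1, tauRate = 0.00005,
                        logThetaMean = 0, logThetaPrec = 0.001) {
  new("PriorConfig", interceptMean = interceptMean,
      interceptPrec = interceptPrec, slopeMean = slopeMean,
      slopePrec = slopePrec, tauShape = tauShape, tauRate = tauRate,
      logThetaMean = logThetaMean, logThetaPrec = logThetaPrec)
}

#' Prior mean of the precision hyperparameters
#'
#' For a gamma(shape, rate) prior this is shape/rate; with the defaults
#' gamma(1, 0.00005), an exponential with mean 20,000.
#'
#' @param priors a \linkS4class{PriorConfig}.
#' @return scalar prior mean.
#' @export
priorPrecisionMean <- function(priors) priors@tauShape / priors@tauRate

#' Model specification constructor
#'
#' @param model integer 1--5 selecting the temporal structure (see file
#'   header), or \code{NULL} if \code{temporal} is given directly.
#' @param temporal one of \code{"year"}, \code{"covid"}, \code{"rw1_year"},
#'   \code{"rw1_month"}, \code{"rw1_month_type1"}, \code{"none"}.
#' @param likelihood \code{"poisson"} or \code{"negbin"}.
#' @param covariates ordered covariate names entering the linear predictor
#'   (may be empty).
#' @param priors a \linkS4class{PriorConfig}.
#' @param spatial,iid include the ICAR / i.i.d. tract effects.
#' @return a \linkS4class{ModelSpec}.
#' @export
modelSpec <- function(model = NULL, temporal = NULL,
                      likelihood = c("poisson", "negbin"),
                      covariates = covariateNamesDefault(),
                      priors = priorConfig(), spatial = TRUE, iid = TRUE) {
  likelihood <- match.arg(likelihood)
  if (is.null(temporal)) {
    if (is.null(model)) stop("give either model (1-5) or temporal")
    temporal <- c("year", "covid", "rw1_year", "rw1_month",
                  "rw1_month_type1")[model]
    if (is.na(temporal)) stop("model must be an integer in 1..5")
  }
  new("ModelSpec", temporal = temporal, likelihood = likelihood,
      covariateNames = as.character(covariates), priors = priors,
      spatial = spatial, iid = iid)
}

#' Which model number (1-5) a spec corresponds to
#' @param spec a \linkS4class{ModelSpec}.
#' @return integer or NA for \code{"none"}.
#' @export
modelNumber <- function(spec)
  match(spec@temporal, c("year", "covid", "rw1_year", "rw1_month",
                         "rw1_month_type1"))

#' Assemble the fixed-effect design and random-effect index maps
#'
#' Expands a panel and covariate table into the structures the sampler
#' consumes: the cell-level fixed-effect matrix X (intercept, covariates at
#' each cell's calendar year, then temporal indicator columns), per-column
#' prior means/precisions, the log-population offset, and the tract/period
#' index of every cell. Cells are ordered column-major (tract index
#' fastest). Monthly cells take their calendar year's covariate values.
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @param panel a \linkS4class{CountPanel} whose granularity matches the
#'   spec (indicator and yearly-RW1 structures need yearly panels, monthly
#'   RW1 structures monthly panels).
#' @param covars a \linkS4class{CovariateTable} covering every panel year
#'   (not needed when the spec has no covariates).
#' @return list with elements \code{X}, \code{priorMean}, \code{priorPrec},
#'   \code{y}, \code{offset}, \code{tract}, \code{period}, \code{n},
#'   \code{T}, and logical flags \code{hasS,hasV,hasGamma,hasPhi,hasDelta}.
#' @export
buildDesign <- function(spec, panel, covars = NULL) {
  g <- granularity(panel)
  needMonthly <- spec@temporal %in% c("rw1_month", "rw1_month_type1")
  if (needMonthly && g != "month")
    stop("temporal structure '", spec@temporal, "' requires a monthly panel")
  if (!needMonthly && spec@temporal != "none" && g != "year")
    stop("temporal structure '", spec@temporal, "' requires a yearly panel")
  Y <- panelCounts(panel)
  n <- nrow(Y); T <- ncol(Y)
  yrs <- periodYears(panel)
  uy <- sort(unique(yrs))
  X <- matrix(1, n * T, 1, dimnames = list(NULL, "(Intercept)"))
  pr <- spec@priors
  priorMean <- pr@interceptMean
  priorPrec <- pr@interceptPrec
  if (length(spec@covariateNames)) {
    if (is.null(covars)) stop("spec names covariates but covars is NULL")
    Xc <- covariateMatrix(covars, panel, spec@covariateNames)
    X <- cbind(X, Xc)
    priorMean <- c(priorMean, rep(pr@slopeMean, ncol(Xc)))
    priorPrec <- c(priorPrec, rep(pr@slopePrec, ncol(Xc)))
  }
  cellYear <- rep(yrs, each = n)
  if (spec@temporal == "year") {
    for (y in uy[-1]) {
      X <- cbind(X, as.numeric(cellYear == y))
      colnames(X)[ncol(X)] <- paste0("year_", y)
      priorMean <- c(priorMean, pr@slopeMean)
      priorPrec <- c(priorPrec, pr@slopePrec)
    }
  } else if (spec@temporal == "covid") {
    if (length(uy) != 4)
      stop("the pandemic-indicator structure assumes a 4-year panel")
    X <- cbind(X, covid = as.numeric(cellYear >= uy[3]))
    priorMean <- c(priorMean, pr@slopeMean)
    priorPrec <- c(priorPrec, pr@slopePrec)
  }
  needsRW <- spec@temporal %in% c("rw1_year", "rw1_month",
                                  "rw1_month_type1")
  list(X = X, priorMean = priorMean, priorPrec = priorPrec,
       y = as.vector(Y), offset = rep(log(unname(populations(panel))), T),
       tract = rep(seq_len(n), times = T), period = rep(seq_len(T), each = n),
       n = n, T = T,
       hasS = spec@spatial, hasV = spec@iid,
       hasGamma = needsRW, hasPhi = needsRW,
       hasDelta = spec@temporal == "rw1_month_type1")
}

#' Count the parameters of each model
#'
#' Reproduces the parameter enumeration of the five models: with k
#' covariates, n tracts and T periods,
#' model 1 totals k+2n+6, model 2 k+2n+4, model 3 k+2n+14 (T = 4),
#' model 4 k+2n+2T+6 and model 5 k+2n+(n+2)T+7. The random-walk start
#' gamma_0 is counted among the fixed effects.
#'
#' @param model integer 1--5 or a \linkS4class{ModelSpec}.
#' @param k number of covariates (>= 0).
#' @param n number of tracts (>= 1).
#' @param T number of periods (must be 4 for the yearly models 1--3).
#' @return list with \code{fixed}, \code{random}, \code{hyper},
#'   \code{total}.
#' @export
parameterCount <- function(model, k, n, T = 4) {
  if (methods::is(model, "ModelSpec")) model <- modelNumber(model)
  stopifnot(k >= 0, n >= 1, T >= 1)
  if (model %in% 1:3 && T != 4)
    stop("models 1-3 are yearly four-period models (T = 4), got T = ", T)
  out <- switch(as.character(model),
    "1" = list(fixed = k + 4, random = 2 * n, hyper = 2),
    "2" = list(fixed = k + 2, random = 2 * n, hyper = 2),
    "3" = list(fixed = k + 2, random = 2 * n + 8, hyper = 4),
    "4" = list(fixed = k + 2, random = 2 * n + 2 * T, hyper = 4),
    "5" = list(fixed = k + 2, random = 2 * n + (n + 2) * T, hyper = 5),
    stop("model must be 1..5"))
  out$total <- out$fixed + out$random + out$hyper
  out
}
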