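# Pre-model multicollinearity screening (VIF), post-model quartile-contrast
# effect translation, and the 2^3 prior-sensitivity grid.

#' Variance inflation factors over tract-year observations
#'
#' Regresses each predictor on all others by ordinary least squares over
#' the pooled tract-year rows and reports VIF_j = 1 / (1 - R^2_j).
#' Calendar year can enter as a numeric linear predictor. Values of 5--10
#' indicate moderate multicollinearity, above 10 strong.
#'
#' @param covars a \linkS4class{CovariateTable}.
#' @param predictors covariate names to screen (default: all).
#' @param includeYear add a numeric \code{Year} predictor.
#' @return data.frame with columns \code{predictor}, \code{vif} (Inf for a
#'   perfectly collinear predictor, with \code{collinear = TRUE}) and
#'   \code{classification} (\code{"low"}, \code{"moderate"},
#'   \code{"strong"}).
#' @export
vifTable <- function(covars, predictors = covariateNames(covars),
                     includeYear = TRUE) {
  v <- covariateValues(covars)
  d <- dim(v)
  M <- sapply(predictors, function(cv) as.vector(v[, , cv]))
  if (includeYear)
    M <- cbind(Year = rep(covariateYears(covars), each = d[1]), M)
  M <- as.matrix(M)
  if (ncol(M) < 2) stop("need at least 2 predictors")
  if (any(apply(M, 2, sd) == 0))
    stop("constant predictor: ",
         paste(colnames(M)[apply(M, 2, sd) == 0], collapse = ", "))
  vif <- vapply(seq_len(ncol(M)), function(j) {
    fitj <- lm(M[, j] ~ M[, -j, drop = FALSE])
    # lm warns on an essentially perfect fit; that case is reported as Inf
    r2 <- suppressWarnings(summary(fitj)$r.squared)
    if (r2 >= 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(predictor = colnames(M), vif = vif,
             collinear = !is.finite(vif),
             classification = cut(vif, c(-Inf, 5, 10, Inf),
                                  labels = c("low", "moderate", "strong")),
             row.names = NULL)
}

#' First and third quartiles (linear interpolation)
#'
#' The quartile convention used for effect translation: linear
#' interpolation between order statistics (R's default type 7). Invariant
#' to input order; requires at least 4 values.
#'
#' @param values numeric vector (length >= 4).
#' @return named numeric c(q1, q3).
#' @export
quartiles <- function(values) {
  if (length(values) < 4) stop("need at least 4 values for quartiles")
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  c(q1 = q[1], q3 = q[2])
}

#' Multiplicative effect of moving a predictor from Q1 to Q3
#'
#' For a log-linear rate model the expected-count ratio between two levels
#' of predictor k (others fixed) is exp(beta_k * (x_high - x_low)); taking
#' the quartiles gives the quartile-contrast effect: a value of 1.5 means
#' a 50\% increase as the predictor moves from its first to its third
#' quartile.
#'
#' @param betaHat posterior-mean slope.
#' @param q1,q3 first and third quartiles of the predictor (q3 >= q1).
#' @param predictor optional name.
#' @return data.frame with \code{predictor}, \code{beta_hat}, \code{q1},
#'   \code{q3}, \code{effect} = exp(betaHat * (q3 - q1)).
#' @export
q1q3Effect <- function(betaHat, q1, q3, predictor = NA_character_) {
  stopifnot(q3 >= q1)
  data.frame(predictor = predictor, beta_hat = betaHat, q1 = q1, q3 = q3,
             effect = exp(betaHat * (q3 - q1)), row.names = NULL)
}

#' Quartile-contrast effect table for a set of slopes
#'
#' Takes slopes explicitly (e.g. posterior means from a fit summary) and
#' computes each predictor's quartiles over the pooled tract-year values
#' of the covariate table, then the Q1-to-Q3 multiplicative effect.
#'
#' @param slopes named numeric vector of slope estimates; names must be
#'   covariates of \code{covars}.
#' @param covars a \linkS4class{CovariateTable}.
#' @return data.frame, one row per slope.
#' @export
effectsTable <- function(slopes, covars) {
  stopifnot(!is.null(names(slopes)))
  miss <- setdiff(names(slopes), covariateNames(covars))
  if (length(miss))
    stop("slopes name unknown covariates: ", paste(miss, collapse = ", "))
  do.call(rbind, lapply(names(slopes), function(cv) {
    q <- quartiles(as.vector(covariateValues(covars)[, , cv]))
    q1q3Effect(slopes[[cv]], q[["q1"]], q[["q3"]], predictor = cv)
  }))
}

#' Prior-sensitivity grid: 2^3 combinations of the three prior choices
#'
#' Refits the model under every combination of {default, alternative} for
#' the intercept prior, the slope prior and the precision hyperprior
#' (8 fits) and tabulates the fixed-effect posterior means and intervals,
#' plus each combination's maximum absolute deviation from the
#' all-default estimates.
#'
#' @param spec a \linkS4class{ModelSpec} (its priors slot provides the
#'   defaults).
#' @param panel,covars,lattice data, as in \code{\link{fitSTModel}}.
#' @param alternative a \linkS4class{PriorConfig} supplying the
#'   alternative intercept/slope/precision settings (defaults: normal(0,
#'   prec 0.001) intercept, normal(0, prec 0.1) slopes, gamma(0.5,
#'   0.0005) precisions).
#' @param ... sampler settings passed to \code{\link{fitSTModel}}; pass a
#'   \code{seed} to make the 8 fits paired.
#' @return data.frame with one row per combination x fixed effect:
#'   indicator columns for which alternatives were active, the posterior
#'   mean and interval, and \code{max_abs_dev} per combination.
#' @export
priorSensitivity <- function(spec, panel, covars = NULL, lattice = NULL,
                             alternative = priorConfig(
                               interceptMean = 0, interceptPrec = 0.001,
                               slopePrec = 0.1,
                               tauShape = 0.5, tauRate = 0.0005),
                             ...) {
  def <- spec@priors
  grid <- expand.grid(altIntercept = c(FALSE, TRUE),
                      altSlope = c(FALSE, TRUE),
                      altPrecision = c(FALSE, TRUE))
  rows <- list()
  ref <- NULL
  for (g in seq_len(nrow(grid))) {
    pc <- priorConfig(
      interceptMean = if (grid$altIntercept[g]) alternative@interceptMean
                      else def@interceptMean,
      interceptPrec = if (grid$altIntercept[g]) alternative@interceptPrec
                      else def@interceptPrec,
      slopeMean = if (grid$altSlope[g]) alternative@slopeMean
                  else def@slopeMean,
      slopePrec = if (grid$altSlope[g]) alternative@slopePrec
                  else def@slopePrec,
      tauShape = if (grid$altPrecision[g]) alternative@tauShape
                 else def@tauShape,
      tauRate = if (grid$altPrecision[g]) alternative@tauRate
                else def@tauRate,
      logThetaMean = def@logThetaMean, logThetaPrec = def@logThetaPrec)
    sp <- spec
    sp@priors <- pc
    fit <- fitSTModel(sp, panel, covars = covars, lattice = lattice, ...)
    fx <- fit@summary[!grepl("^tau_|^nb_dispersion$",
                             fit@summary$parameter), , drop = FALSE]
    if (g == 1) ref <- setNames(fx$mean, fx$parameter)
    rows[[g]] <- data.frame(combination = g, grid[g, , drop = FALSE],
                            parameter = fx$parameter, mean = fx$mean,
                            q2.5 = fx$q2.5, q97.5 = fx$q97.5,
                            max_abs_dev = max(abs(fx$mean -
                                                  ref[fx$parameter])),
                            posterior_sd = fx$sd,
                            row.names = NULL)
  }
  do.call(rbind, rows)
}
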