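# Synthetic-data generators with the exact generative structure assumed by
# the five spatio-temporal models, with known parameters for recovery
# tests: ICAR spatial fields (exact, via the graph-Laplacian eigenbasis),
# RW1 temporal drift, yearly-stepping covariates, and Poisson or
# negative-binomial count panels over a log-population offset.

#' Draw from the intrinsic CAR (ICAR) distribution on a lattice
#'
#' Samples the zero-mean spatial field whose conditionals are
#' s_i | s_-i ~ N(mean of neighbours, 1 / (tauS * m_i)). The joint
#' precision tauS * (D - W) has rank n - 1 on a connected lattice; draws
#' are generated exactly in the span of the Laplacian eigenvectors with
#' positive eigenvalue, which enforces the sum-to-zero constraint by
#' construction (per connected component when \code{perComponent = TRUE}).
#'
#' @param lattice a connected \linkS4class{TractLattice} (n >= 2).
#' @param tauS precision of the field (> 0).
#' @param nDraws number of independent draws.
#' @param seed optional integer seed (draws are reproducible given it).
#' @param perComponent allow a disconnected lattice, centering each
#'   component separately.
#' @return numeric vector (one draw) or n x nDraws matrix.
#' @export
sampleICAR <- function(lattice, tauS, nDraws = 1, seed = NULL,
                       perComponent = FALSE) {
  stopifnot(tauS > 0)
  n <- nTracts(lattice)
  if (n < 2) stop("ICAR field undefined for a single tract")
  if (!is.null(seed)) set.seed(seed)
  Q <- icarPrecision(lattice)
  eg <- eigen(Q, symmetric = TRUE)
  tol <- 1e-8 * max(eg$values)
  zero <- sum(eg$values < tol)
  if (zero > 1 && !perComponent)
    stop("lattice is disconnected (", zero, " components); set ",
         "perComponent = TRUE to centre each component separately")
  keep <- eg$values >= tol
  lam <- eg$values[keep]
  U <- eg$vectors[, keep, drop = FALSE]
  z <- matrix(rnorm(sum(keep) * nDraws), sum(keep), nDraws)
  s <- U %*% (z / sqrt(tauS * lam))
  rownames(s) <- tractIds(lattice)
  if (nDraws == 1) s[, 1] else s
}

#' ICAR precision structure matrix D - W of a lattice
#'
#' @param lattice a \linkS4class{TractLattice}.
#' @return dense n x n matrix (degree matrix minus adjacency).
#' @export
icarPrecision <- function(lattice) {
  W <- as.matrix(adjacencyMatrix(lattice))
  diag(rowSums(W)) - W
}

#' First-order random walk
#'
#' gamma_t ~ N(gamma_{t-1}, 1/tauGamma) for t = 1..T from a fixed starting
#' value gamma_0 (default 0, which identifies the walk's level against the
#' model intercept).
#'
#' @param T number of periods (>= 1).
#' @param tauGamma increment precision (> 0).
#' @param gamma0 starting value.
#' @param seed optional integer seed.
#' @return numeric vector gamma_1..gamma_T.
#' @export
sampleRW1 <- function(T, tauGamma, gamma0 = 0, seed = NULL) {
  if (tauGamma <= 0) stop("tauGamma must be > 0")
  stopifnot(T >= 1)
  if (!is.null(seed)) set.seed(seed)
  gamma0 + cumsum(rnorm(T, 0, 1 / sqrt(tauGamma)))
}

#' Simulate yearly-stepping tract covariates
#'
#' Generates the five canonical covariates with spatially structured
#' baseline variation (an ICAR draw per covariate) and small independent
#' year-to-year steps, emulating ACS-style measures: baseline levels are
#' realistic for an urban tract map and percentage covariates are clipped
#' to [0, 100]. Median income is in thousands of dollars.
#'
#' @param lattice a \linkS4class{TractLattice}.
#' @param years integer vector of calendar years.
#' @param sdChange standard deviation of the year-to-year step, as a
#'   fraction of each covariate's baseline spread (0 = constant).
#' @param spatialTau ICAR precision of the baseline pattern.
#' @param seed optional integer seed.
#' @return a \linkS4class{CovariateTable}.
#' @export
simulateCovariates <- function(lattice, years = 2018:2021, sdChange = 0.1,
                               spatialTau = 1, seed = NULL) {
  stopifnot(length(years) >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nTracts(lattice)
  cvs <- covariateNamesDefault()
  # baseline mean and cross-tract spread per covariate
  level <- c(45, 35, 35, 45, 80)
  spread <- c(15, 12, 5, 18, 10)
  arr <- array(NA_real_, c(n, length(years), length(cvs)),
               dimnames = list(tractIds(lattice), as.character(years), cvs))
  for (j in seq_along(cvs)) {
    base <- if (n >= 2) sampleICAR(lattice, spatialTau) else numeric(n)
    base <- level[j] + spread[j] * base / max(stats::sd(base), 1e-12)
    for (y in seq_along(years)) {
      if (y == 1) arr[, y, j] <- base
      else arr[, y, j] <- arr[, y - 1, j] +
          rnorm(n, 0, sdChange * spread[j])
    }
  }
  for (j in which(startsWith(cvs, "pct")))
    arr[, , j] <- pmin(100, pmax(0, arr[, , j]))
  CovariateTable(arr)
}

#' Simulate tract populations at risk
#'
#' Log-uniform between \code{min} and \code{max} (default 200--3000),
#' mimicking census-tract populations of women aged 15--49.
#'
#' @param lattice a \linkS4class{TractLattice}.
#' @param min,max population bounds.
#' @param seed optional integer seed.
#' @return named integer vector in lattice order.
#' @export
simulatePopulations <- function(lattice, min = 200, max = 3000,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- round(exp(runif(nTracts(lattice), log(min), log(max))))
  setNames(as.integer(p), tractIds(lattice))
}

#' Generative ("true") parameters for a simulated panel
#'
#' Fills a \linkS4class{SimulationTruth} with defaults of realistic
#' magnitude for urban ED-visit mapping and draws the latent fields
#' required by \code{spec}: slopes on the order of 0.01 per covariate unit,
#' a 2020--2021 downturn in the temporal fixed effects, moderate spatial
#' structure (sd(s) ~ 0.3) and smaller unstructured noise. Any component
#' can be overridden.
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @param lattice a \linkS4class{TractLattice}.
#' @param T number of periods implied by the panel to be simulated.
#' @param beta0 intercept (log baseline rate per person-period).
#' @param beta named or plain slope vector for \code{spec@covariateNames}.
#' @param alphaYear (2019, 2020, 2021) indicator effects, reference 2018.
#' @param alphaCovid 2020--2021 indicator effect.
#' @param tauS,tauV,tauGamma,tauPhi,tauDelta precisions of the latent
#'   fields.
#' @param nbDispersion negative-binomial dispersion theta (variance
#'   mu + mu^2/theta); only used when \code{spec@likelihood == "negbin"}.
#' @param seed optional integer seed for the latent-field draws.
#' @return a \linkS4class{SimulationTruth}.
#' @export
simulationTruth <- function(spec, lattice, T = NULL,
                            beta0 = -4,
                            beta = NULL,
                            alphaYear = c(0.07, -0.18, -0.28),
                            alphaCovid = -0.26,
                            tauS = 10, tauV = 25, tauGamma = 100,
                            tauPhi = 100, tauDelta = 100,
                            nbDispersion = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nTracts(lattice)
  if (is.null(T))
    T <- if (spec@temporal %in% c("rw1_month", "rw1_month_type1")) 48L else 4L
  k <- length(spec@covariateNames)
  if (is.null(beta)) {
    defaults <- c(pct_private_insurance = 0.0006,
                  pct_public_insurance = 0.0117, median_age = 0.0134,
                  median_income = -0.0046, pct_hs_diploma = 0.0073)
    beta <- setNames(rep(0.01, k), spec@covariateNames)
    known <- intersect(spec@covariateNames, names(defaults))
    beta[known] <- defaults[known]
  }
  s <- if (spec@spatial && n >= 2) sampleICAR(lattice, tauS) else numeric(0)
  v <- if (spec@iid) rnorm(n, 0, 1 / sqrt(tauV)) else numeric(0)
  needsRW <- spec@temporal %in% c("rw1_year", "rw1_month",
                                  "rw1_month_type1")
  gamma <- if (needsRW) sampleRW1(T, tauGamma) else numeric(0)
  phi <- if (needsRW) rnorm(T, 0, 1 / sqrt(tauPhi)) else numeric(0)
  delta <- if (spec@temporal == "rw1_month_type1")
    matrix(rnorm(n * T, 0, 1 / sqrt(tauDelta)), n, T)
  else matrix(numeric(0), 0, 0)
  new("SimulationTruth",
      beta0 = beta0, beta = beta,
      alphaYear = if (spec@temporal == "year") alphaYear else numeric(0),
      alphaCovid = if (spec@temporal == "covid") alphaCovid else numeric(0),
      s = s, v = v, gamma = gamma, phi = phi, delta = delta,
      tauS = tauS, tauV = tauV, tauGamma = tauGamma, tauPhi = tauPhi,
      tauDelta = tauDelta,
      nbDispersion = if (spec@likelihood == "negbin") nbDispersion
                     else numeric(0),
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

# expected per-cell mean counts mu[i, t] = P_i * exp(eta[i, t]) under the
# generative truth; errors name the first missing required component
.truthMeans <- function(spec, truth, lattice, covars, populations,
                        studyWindow) {
  granularity <- if (spec@temporal %in% c("rw1_month", "rw1_month_type1"))
    "month" else "year"
  per <- .periodSeq(studyWindow, granularity)
  n <- nTracts(lattice); T <- nrow(per)
  ids <- tractIds(lattice)
  if (is.null(names(populations))) names(populations) <- ids
  eta <- matrix(truth@beta0, n, T, dimnames = list(ids, per$period))
  if (length(spec@covariateNames)) {
    if (length(truth@beta) != length(spec@covariateNames))
      stop("truth is missing slope(s) 'beta' for the spec covariates")
    for (y in unique(per$year)) {
      xb <- covariateValues(covars)[ids, as.character(y),
                                    spec@covariateNames, drop = FALSE]
      eta[, per$year == y] <- eta[, per$year == y] +
        as.vector(matrix(xb, n) %*% truth@beta)
    }
  }
  yrs <- sort(unique(per$year))
  if (spec@temporal == "year") {
    if (length(truth@alphaYear) != 3)
      stop("truth is missing the year-indicator effects 'alphaYear'")
    for (j in 2:4)
      eta[, per$year == yrs[j]] <- eta[, per$year == yrs[j]] +
        truth@alphaYear[j - 1]
  } else if (spec@temporal == "covid") {
    if (!length(truth@alphaCovid))
      stop("truth is missing the pandemic-indicator effect 'alphaCovid'")
    eta[, per$year >= yrs[3]] <- eta[, per$year >= yrs[3]] +
      truth@alphaCovid
  } else if (spec@temporal != "none") {
    if (length(truth@gamma) != T)
      stop("truth is missing the random-walk effects 'gamma' (length T)")
    if (length(truth@phi) != T)
      stop("truth is missing the i.i.d. time effects 'phi' (length T)")
    eta <- eta + matrix(truth@gamma + truth@phi, n, T, byrow = TRUE)
  }
  if (spec@temporal == "rw1_month_type1") {
    if (!all(dim(truth@delta) == c(n, T)))
      stop("truth is missing the space-time interaction 'delta' (n x T)")
    eta <- eta + truth@delta
  }
  if (spec@spatial) {
    if (length(truth@s) != n)
      stop("truth is missing the spatial field 's'")
    eta <- eta + truth@s
  }
  if (spec@iid) {
    if (length(truth@v) != n)
      stop("truth is missing the i.i.d. tract effects 'v'")
    eta <- eta + truth@v
  }
  mu <- sweep(exp(eta), 1, populations[ids], "*")
  list(mu = mu, periods = per, granularity = granularity)
}

#' Expected cell means of a simulated panel
#'
#' @inheritParams simulatePanel
#' @return n x T matrix of mean counts P_i * lambda_it.
#' @export
expectedCounts <- function(spec, truth, lattice, covars, populations,
                           studyWindow = as.Date(c("2018-01-01",
                                                   "2021-12-31"))) {
  .truthMeans(spec, truth, lattice, covars, populations, studyWindow)$mu
}

#' Simulate a count panel under a model specification
#'
#' Draws Y_it from Poisson(P_i lambda_it), or from the negative binomial
#' with that mean and dispersion \code{truth@nbDispersion} (variance
#' mu + mu^2/theta) when the spec's likelihood is \code{"negbin"}, with
#' log lambda_it assembled from the truth's components according to the
#' spec's temporal structure. A missing required component raises an error
#' naming it.
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @param truth a \linkS4class{SimulationTruth}.
#' @param lattice a \linkS4class{TractLattice}.
#' @param covars a \linkS4class{CovariateTable} covering the study years.
#' @param populations per-tract populations at risk.
#' @param studyWindow length-2 date vector (drives T: one period per year
#'   or month).
#' @param seed optional integer seed.
#' @return a \linkS4class{CountPanel}.
#' @export
simulatePanel <- function(spec, truth, lattice, covars, populations,
                          studyWindow = as.Date(c("2018-01-01",
                                                  "2021-12-31")),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tm <- .truthMeans(spec, truth, lattice, covars, populations, studyWindow)
  mu <- tm$mu
  Y <- if (spec@likelihood == "negbin") {
    if (!length(truth@nbDispersion))
      stop("truth is missing the dispersion 'nbDispersion' for the ",
           "negative-binomial likelihood")
    rnbinom(length(mu), size = truth@nbDispersion, mu = as.vector(mu))
  } else {
    rpois(length(mu), as.vector(mu))
  }
  CountPanel(matrix(Y, nrow(mu), ncol(mu),
                    dimnames = dimnames(mu)),
             populations[tractIds(lattice)], tractIds = tractIds(lattice),
             periods = tm$periods, granularity = tm$granularity)
}

#' Write the generative truth as JSON
#'
#' Serialises every slot of a \linkS4class{SimulationTruth} (parameters,
#' latent fields, seed) so downstream recovery tests can reload it.
#'
#' @param truth a \linkS4class{SimulationTruth}.
#' @param file output path.
#' @export
writeTruth <- function(truth, file) {
  sl <- methods::slotNames(truth)
  out <- lapply(sl, function(s) {
    x <- methods::slot(truth, s)
    if (is.matrix(x)) as.data.frame(x) else x
  })
  names(out) <- sl
  jsonlite::write_json(out, file, digits = NA, auto_unbox = FALSE)
  invisible(file)
}
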