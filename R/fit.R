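# Model fitting: R front-end over the C++ Metropolis-within-Gibbs engine,
# posterior summaries, split-chain convergence diagnostics and DIC.

.components <- function(lattice) {
  A <- adjacencyMatrix(lattice)
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  nl <- lapply(seq_len(n), function(i) which(A[i, ] != 0))
  for (st in seq_len(n)) {
    if (comp[st] != 0L) next
    cur <- cur + 1L
    stack <- st
    while (length(stack)) {
      i <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (comp[i] != 0L) next
      comp[i] <- cur
      stack <- c(stack, nl[[i]][comp[nl[[i]]] == 0L])
    }
  }
  comp
}

.nbrStructure <- function(lattice) {
  A <- adjacencyMatrix(lattice)
  n <- nrow(A)
  nl <- lapply(seq_len(n), function(i) which(A[i, ] != 0) - 1L)
  list(ptr = c(0L, cumsum(lengths(nl))), nbr = as.integer(unlist(nl)),
       nComp = max(.components(lattice)))
}

#' Poisson / negative-binomial panel log-likelihood
#'
#' Direct evaluation of the count log-likelihood at given cell means,
#' summed over cells; the oracle counterpart of the sampler's internal
#' likelihood. The negative binomial is parameterised by mean \code{mu}
#' and dispersion \code{theta} (variance mu + mu^2/theta), so it tends to
#' the Poisson as theta grows.
#'
#' @param y counts (NA cells are skipped).
#' @param mu positive means, same length.
#' @param family \code{"poisson"} or \code{"negbin"}.
#' @param theta NB dispersion.
#' @return scalar log-likelihood.
#' @export
panelLogLik <- function(y, mu, family = c("poisson", "negbin"),
                        theta = NULL) {
  family <- match.arg(family)
  keep <- !is.na(y)
  y <- y[keep]; mu <- mu[keep]
  if (family == "poisson") return(sum(dpois(y, mu, log = TRUE)))
  stopifnot(!is.null(theta))
  sum(dnbinom(y, size = theta, mu = mu, log = TRUE))
}

# split-chain potential scale reduction factor
.rhat <- function(chains) {
  half <- lapply(chains, function(x) {
    m <- length(x) %/% 2L
    list(x[seq_len(m)], x[seq_len(m) + (length(x) - m)])
  })
  xs <- unlist(half, recursive = FALSE)
  m <- length(xs); nn <- length(xs[[1]])
  if (nn < 2) return(NA_real_)
  means <- vapply(xs, mean, numeric(1))
  vars <- vapply(xs, var, numeric(1))
  W <- mean(vars)
  B <- nn * var(means)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# effective sample size via Geyer's initial positive sequence, pooled
# across chains
.ess <- function(chains) {
  nn <- length(chains[[1]]); m <- length(chains)
  if (nn < 4) return(NA_real_)
  W <- mean(vapply(chains, var, numeric(1)))
  B <- nn * var(vapply(chains, mean, numeric(1)))
  varPlus <- (nn - 1) / nn * W + if (m > 1) B / nn else 0
  if (varPlus == 0 || W == 0) return(m * nn)
  maxLag <- min(nn - 2L, 200L)
  acovs <- vapply(chains, function(x)
    stats::acf(x, lag.max = maxLag, plot = FALSE,
               type = "covariance")$acf[-1, 1, 1], numeric(maxLag))
  rho <- 1 - (W - rowMeans(acovs)) / varPlus
  # Geyer: sum consecutive pairs while positive
  tau <- 1
  l <- 1
  while (l + 1 <= maxLag) {
    pair <- rho[l] + rho[l + 1]
    if (pair < 0) break
    tau <- tau + 2 * pair
    l <- l + 2
  }
  max(m * nn / tau, 1)
}

#' Fit a spatio-temporal areal count model
#'
#' Posterior inference by adaptive Metropolis-within-Gibbs: random-walk
#' updates for fixed effects and latent fields (single-site, with
#' per-parameter proposal scales tuned during warm-up to a 44\% acceptance
#' rate), conjugate gamma updates for all precision hyperparameters, and a
#' log-scale random-walk update for the negative-binomial dispersion. The
#' ICAR field is re-centred to sum to zero every sweep, moving its level
#' into the flat-prior intercept; the random-walk start is pinned at
#' gamma_0 = 0. The log-population offset is always applied.
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @param panel a \linkS4class{CountPanel}.
#' @param covars a \linkS4class{CovariateTable} (if the spec has
#'   covariates).
#' @param lattice a \linkS4class{TractLattice} (if the spec has a spatial
#'   term).
#' @param draws retained draws per chain.
#' @param warmup warm-up (adaptation) iterations per chain, discarded.
#' @param chains number of independent chains.
#' @param thin keep every \code{thin}-th post-warm-up draw.
#' @param seed optional integer seed.
#' @param mask optional n x T logical matrix; \code{TRUE} cells are
#'   excluded from the likelihood (e.g. for prior-only checks or
#'   hold-outs).
#' @param rhatThreshold,essThreshold convergence thresholds applied to
#'   every reported parameter; a fit violating them is flagged
#'   (\code{converged = FALSE}) with a warning, never silently accepted.
#' @return an \linkS4class{STFit}.
#' @export
fitSTModel <- function(spec, panel, covars = NULL, lattice = NULL,
                       draws = 1000, warmup = 1000, chains = 2, thin = 1,
                       seed = NULL, mask = NULL,
                       rhatThreshold = 1.05, essThreshold = 100) {
  if (!is.null(seed)) set.seed(seed)
  if (spec@spatial && is.null(lattice))
    stop("spec includes a spatial term; a lattice is required")
  if (spec@spatial && nTracts(lattice) < 2)
    stop("ICAR field undefined for a single tract")
  if (any(populations(panel) <= 0)) stop("populations must be positive")
  des <- buildDesign(spec, panel, covars)
  y <- des$y
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == c(des$n, des$T)))
    y[as.vector(mask)] <- -1L
  }
  nb <- if (spec@spatial) .nbrStructure(lattice)
        else list(ptr = integer(des$n + 1L), nbr = integer(0), nComp = des$n)
  # centre non-intercept columns (decorrelates the intercept; the sampler
  # works in the centred parameterisation, the intercept draw is mapped
  # back below). Fixed-effect priors apply to the centred coordinates.
  Xc <- des$X
  xbar <- c(0, colMeans(Xc[, -1, drop = FALSE]))
  if (ncol(Xc) > 1)
    Xc[, -1] <- sweep(Xc[, -1, drop = FALSE], 2, xbar[-1])
  pr <- spec@priors
  family <- if (spec@likelihood == "negbin") 1L else 0L
  nobs <- sum(y >= 0)
  beta0init <- if (nobs > 0)
    log((sum(y[y >= 0]) + 0.5) / sum(exp(des$offset[y >= 0]))) else 0

  chainOut <- vector("list", chains)
  for (ch in seq_len(chains)) {
    init <- list(beta = c(beta0init + rnorm(1, 0, 0.1),
                          rnorm(ncol(des$X) - 1, 0, 0.02)),
                 tauS = exp(rnorm(1, log(10), 0.2)),
                 tauV = exp(rnorm(1, log(10), 0.2)),
                 tauG = exp(rnorm(1, log(10), 0.2)),
                 tauP = exp(rnorm(1, log(10), 0.2)),
                 tauD = exp(rnorm(1, log(10), 0.2)),
                 logTheta = rnorm(1, log(10), 0.2))
    chainOut[[ch]] <- .st_sampler(
      as.integer(y), des$offset, Xc, des$priorMean, des$priorPrec,
      nb$ptr, nb$nbr, nb$nComp, des$n, des$T,
      des$hasS, des$hasV, des$hasGamma, des$hasPhi, des$hasDelta,
      family, pr@tauShape, pr@tauRate, pr@logThetaMean, pr@logThetaPrec,
      as.integer(warmup), as.integer(draws), as.integer(thin), init)
  }

  parNames <- colnames(des$X)
  tauNames <- c("tau_s", "tau_v", "tau_gamma", "tau_phi", "tau_delta")
  tauActive <- c(des$hasS, des$hasV, des$hasGamma, des$hasPhi, des$hasDelta)
  drawsList <- lapply(chainOut, function(co) {
    b <- co$beta
    if (ncol(b) > 1)  # map the centred intercept back to the raw scale
      b[, 1] <- b[, 1] - b[, -1, drop = FALSE] %*% xbar[-1]
    m <- cbind(b, co$tau[, tauActive, drop = FALSE],
               if (family == 1L) co$theta)
    colnames(m) <- c(parNames, tauNames[tauActive],
                     if (family == 1L) "nb_dispersion")
    m
  })

  allPars <- colnames(drawsList[[1]])
  pooled <- do.call(rbind, drawsList)
  summ <- data.frame(
    parameter = allPars,
    mean = colMeans(pooled),
    sd = apply(pooled, 2, sd),
    q2.5 = apply(pooled, 2, quantile, 0.025),
    q97.5 = apply(pooled, 2, quantile, 0.975),
    ess = vapply(allPars, function(pp)
      .ess(lapply(drawsList, function(d) d[, pp])), numeric(1)),
    rhat = vapply(allPars, function(pp)
      .rhat(lapply(drawsList, function(d) d[, pp])), numeric(1)),
    row.names = NULL)

  avg <- function(field) Reduce(`+`, lapply(chainOut, `[[`, field)) / chains
  ids <- tractIds(panel); pls <- periodLabels(panel)
  lambda <- matrix(avg("rateMean"), des$n, des$T,
                   dimnames = list(ids, pls))
  betaMean <- colMeans(pooled[, parNames, drop = FALSE])
  latent <- list(
    s = setNames(avg("sMean"), ids), v = setNames(avg("vMean"), ids),
    gamma = setNames(avg("gammaMean"), pls),
    phi = setNames(avg("phiMean"), pls),
    delta = matrix(avg("deltaMean"), des$n, des$T,
                   dimnames = list(ids, pls)),
    etaFixed = matrix(as.vector(des$X %*% betaMean), des$n, des$T,
                      dimnames = list(ids, pls)),
    offset = matrix(des$offset, des$n, des$T))

  devDraws <- unlist(lapply(chainOut, `[[`, "deviance"))
  P <- unname(populations(panel))
  muHat <- sweep(lambda, 1, P, "*")
  yMat <- matrix(y, des$n, des$T)
  yMat[yMat < 0] <- NA_integer_
  thetaHat <- if (family == 1L) mean(pooled[, "nb_dispersion"]) else NULL
  Dhat <- -2 * panelLogLik(as.vector(yMat), as.vector(muHat),
                           spec@likelihood, thetaHat)
  Dbar <- mean(devDraws)
  pD <- Dbar - Dhat
  maxRhat <- suppressWarnings(max(summ$rhat, na.rm = TRUE))
  minEss <- suppressWarnings(min(summ$ess, na.rm = TRUE))
  converged <- is.finite(maxRhat) && maxRhat < rhatThreshold &&
    minEss > essThreshold
  if (!converged)
    warning(sprintf(
      "fit flagged as unconverged: max Rhat = %.3f, min ESS = %.0f", maxRhat,
      minEss))
  diagnostics <- list(
    DIC = Dbar + pD, Dbar = Dbar, pD = pD, Dhat = Dhat,
    nDraws = draws, nChains = chains, thin = thin,
    seed = if (is.null(seed)) NA else seed,
    maxRhat = maxRhat, minEss = minEss,
    rhatThreshold = rhatThreshold, essThreshold = essThreshold,
    maxAbsSumS = max(vapply(chainOut, `[[`, numeric(1), "maxAbsSumS")),
    accept = lapply(chainOut, `[[`, "accept"))
  new("STFit", spec = spec, summary = summ, draws = drawsList,
      latent = latent, lambda = lambda, devianceDraws = devDraws,
      diagnostics = diagnostics, converged = converged)
}

#' Plug-in linear predictor of a fit (mean structure)
#'
#' Assembles log lambda from the posterior means of each component
#' (fixed-effect part, s, v, gamma, phi and optionally delta). Unlike
#' \code{log(fittedRates(x))} this is exactly additive in space and time,
#' so it exposes the parallel-curves structure of the additive models.
#'
#' @param x an \linkS4class{STFit}.
#' @param interaction include the space-time interaction posterior means?
#' @return n x T matrix of plug-in log-rates.
#' @export
fittedLogRates <- function(x, interaction = TRUE) {
  l <- x@latent
  eta <- l$etaFixed +
    matrix(l$s, nrow(l$etaFixed), ncol(l$etaFixed)) +
    matrix(l$v, nrow(l$etaFixed), ncol(l$etaFixed)) +
    matrix(l$gamma, nrow(l$etaFixed), ncol(l$etaFixed), byrow = TRUE) +
    matrix(l$phi, nrow(l$etaFixed), ncol(l$etaFixed), byrow = TRUE)
  if (interaction) eta <- eta + l$delta
  eta
}

#' @rdname dic
#' @return list with \code{DIC}, \code{Dbar}, \code{pD}, \code{Dhat},
#'   \code{nDraws}, \code{nChains}, \code{seed}. DIC = Dbar + pD with
#'   pD = Dbar - D(posterior mean rates); lower is better.
#' @export
setMethod("dic", "STFit", function(x, ...) {
  if (!length(x@devianceDraws)) stop("no stored deviance draws")
  d <- x@diagnostics
  list(DIC = d$DIC, Dbar = d$Dbar, pD = d$pD, Dhat = d$Dhat,
       nDraws = d$nDraws, nChains = d$nChains, seed = d$seed)
})

#' Compare two DIC values at the conventional +/- 2 threshold
#'
#' Models whose DICs differ by 2 or less are considered to have a similar
#' degree of fit.
#'
#' @param dic1,dic2 DIC scalars (or \code{dic()} results / STFits).
#' @param threshold similarity threshold (default 2).
#' @return list with \code{delta} (dic1 - dic2) and \code{verdict}:
#'   \code{"similar"} or \code{"better"} (the smaller one fits better).
#' @export
compareDIC <- function(dic1, dic2, threshold = 2) {
  val <- function(d) {
    if (methods::is(d, "STFit")) return(dic(d)$DIC)
    if (is.list(d)) return(d$DIC)
    d
  }
  d1 <- val(dic1); d2 <- val(dic2)
  list(delta = d1 - d2,
       verdict = if (abs(d1 - d2) <= threshold) "similar" else "better",
       preferred = if (abs(d1 - d2) <= threshold) NA_integer_
                   else if (d1 < d2) 1L else 2L)
}

#' Fit several specifications and tabulate DIC
#'
#' @param specs list of \linkS4class{ModelSpec}s (>= 2).
#' @param panel,covars,lattice shared data.
#' @param ... sampler settings passed to \code{\link{fitSTModel}}; a
#'   \code{seed} is reused for every spec so comparisons are paired.
#' @return data.frame with one row per spec: model label, DIC, Dbar, pD,
#'   and a \code{similar} flag (within 2 of the best DIC).
#' @export
compareModels <- function(specs, panel, covars = NULL, lattice = NULL,
                          ...) {
  stopifnot(length(specs) >= 2)
  rows <- lapply(specs, function(sp) {
    fit <- fitSTModel(sp, panel, covars = covars, lattice = lattice, ...)
    d <- dic(fit)
    data.frame(model = sp@temporal, likelihood = sp@likelihood,
               DIC = d$DIC, Dbar = d$Dbar, pD = d$pD)
  })
  out <- do.call(rbind, rows)
  out$similar <- out$DIC - min(out$DIC) <= 2
  out
}
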