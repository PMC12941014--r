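# Sampler correctness: conjugate oracle, likelihood limits, constraint
# enforcement, prior reproduction, DIC arithmetic and model comparison.

test_that("the NB log-likelihood tends to the Poisson as dispersion grows", {
  set.seed(40)
  y <- rpois(50, 7)
  mu <- runif(50, 2, 15)
  perCellNB <- dnbinom(y, size = 1e8, mu = mu, log = TRUE)
  perCellP <- dpois(y, mu, log = TRUE)
  expect_lt(max(abs(perCellNB - perCellP)), 1e-4)
  expect_equal(panelLogLik(y, mu, "negbin", theta = 1e8),
               panelLogLik(y, mu, "poisson"), tolerance = 1e-6)
  # NA cells are excluded
  y2 <- y; y2[1:5] <- NA
  expect_equal(panelLogLik(y2, mu, "poisson"),
               sum(perCellP[-(1:5)]))
})

test_that("an intercept-only fit matches the conjugate gamma posterior", {
  spec <- modelSpec(temporal = "none", covariates = character(),
                    spatial = FALSE, iid = FALSE)
  Y <- matrix(c(7L, 8L, 6L, 9L), 1, 4, dimnames = list("A", 2018:2021))
  pan <- CountPanel(Y, populations = 100, tractIds = "A",
                    periods = as.character(2018:2021))
  fit <- quickFit(spec, pan, draws = 2000, warmup = 1000, chains = 2,
                  seed = 41)
  lam <- exp(do.call(rbind, fit@draws)[, 1])
  # flat prior on log-rate => rate | y ~ Gamma(sum y = 30, exposure = 400)
  expect_equal(mean(lam), 30 / 400, tolerance = 0.02)
  expect_equal(unname(quantile(lam, 0.025)), qgamma(0.025, 30, 400),
               tolerance = 0.03)
  expect_equal(unname(quantile(lam, 0.975)), qgamma(0.975, 30, 400),
               tolerance = 0.03)
  # a single rate parameter: effective parameter count near 1
  d <- dic(fit)
  expect_equal(d$DIC, d$Dbar + d$pD)
  expect_gt(d$pD, 0.4)
  expect_lt(d$pD, 1.6)
})

test_that("the ICAR field sums to zero in every retained draw", {
  s <- testPanelSetup(4, 4, seed = 42)
  fit <- quickFit(s$spec, s$panel, s$covars, s$lattice, draws = 400,
                  warmup = 400, seed = 43)
  expect_lt(fit@diagnostics$maxAbsSumS, 1e-9)
  expect_true(all(fittedRates(fit) > 0))
  su <- posteriorSummary(fit)
  expect_true(all(su$q2.5 <= su$mean & su$mean <= su$q97.5))
})

test_that("fits are reproducible given a seed", {
  s <- testPanelSetup(3, 3, seed = 44)
  f1 <- quickFit(s$spec, s$panel, s$covars, s$lattice, draws = 200,
                 warmup = 200, seed = 45)
  f2 <- quickFit(s$spec, s$panel, s$covars, s$lattice, draws = 200,
                 warmup = 200, seed = 45)
  expect_identical(f1@draws, f2@draws)
  expect_identical(dic(f1)$DIC, dic(f2)$DIC)
})

test_that("a fully masked panel reproduces the precision prior", {
  # with no likelihood the sampler must return the gamma(1, 0.00005)
  # prior for tau (mean 20,000)
  lat <- makeGridLattice(3, 3)
  spec <- modelSpec(temporal = "none", covariates = character(),
                    spatial = FALSE, iid = TRUE)
  Y <- matrix(5L, 9, 4, dimnames = list(tractIds(lat), 2018:2021))
  pan <- CountPanel(Y, populations = rep(1000, 9),
                    tractIds = tractIds(lat),
                    periods = as.character(2018:2021))
  fit <- quickFit(spec, pan, draws = 5000, warmup = 500, chains = 2,
                  thin = 2, seed = 46, mask = matrix(TRUE, 9, 4))
  tv <- do.call(rbind, fit@draws)[, "tau_v"]
  ess <- fit@summary$ess[fit@summary$parameter == "tau_v"]
  se <- sd(tv) / sqrt(ess)
  expect_lt(abs(mean(tv) - priorPrecisionMean(priorConfig())), 3 * se)
})

test_that("additive monthly fits have parallel log-rate curves within
          covariate-constant years; the interaction breaks them", {
  lat <- makeGridLattice(3, 3)
  cv <- simulateCovariates(lat, seed = 47)
  pops <- simulatePopulations(lat, seed = 48)
  sp5 <- modelSpec(5, covariates = character())
  tr5 <- simulationTruth(sp5, lat, tauDelta = 25, seed = 49)
  pan5 <- simulatePanel(sp5, tr5, lat, cv, pops, seed = 50)
  fit <- quickFit(sp5, pan5, NULL, lat, draws = 300, warmup = 300,
                  seed = 51)
  etaAdd <- fittedLogRates(fit, interaction = FALSE)
  withinYearSpread <- function(eta) {
    out <- 0
    for (y in 0:3) {
      d <- eta[1, y * 12 + 1:12] - eta[2, y * 12 + 1:12]
      out <- max(out, max(abs(d - mean(d))))
    }
    out
  }
  expect_lt(withinYearSpread(etaAdd), 1e-6)
  etaInt <- fittedLogRates(fit, interaction = TRUE)
  expect_gt(withinYearSpread(etaInt), 1e-3)
})

test_that("posterior ICAR fields are spatially smoother than the iid
          fields", {
  s <- testPanelSetup(5, 5, seed = 52, tauS = 2, tauV = 25)
  fit <- quickFit(s$spec, s$panel, s$covars, s$lattice, draws = 800,
                  warmup = 800, seed = 53)
  iS <- moransI(fit@latent$s, s$lattice)
  iV <- moransI(fit@latent$v, s$lattice)
  expect_gt(iS, iV)
})

test_that("unconverged runs are flagged, not silently accepted", {
  s <- testPanelSetup(3, 3, seed = 54)
  expect_warning(
    fit <- fitSTModel(s$spec, s$panel, s$covars, s$lattice, draws = 30,
                      warmup = 10, chains = 2, seed = 55),
    "unconverged")
  expect_false(fit@converged)
})

test_that("input validation catches structural errors", {
  s <- testPanelSetup(3, 3, seed = 56)
  expect_error(fitSTModel(s$spec, s$panel, s$covars, lattice = NULL),
               "lattice is required")
  lat1 <- suppressWarnings(TractLattice("A"))
  expect_error(fitSTModel(s$spec, s$panel, s$covars, lat1),
               "single tract")
})

test_that("DIC comparison helpers implement the +/- 2 convention", {
  expect_equal(compareDIC(100, 101.5)$verdict, "similar")
  cmp <- compareDIC(100, 104)
  expect_equal(cmp$verdict, "better")
  expect_equal(cmp$preferred, 1L)
  expect_equal(compareDIC(104, 100)$preferred, 2L)
})

test_that("model comparison is paired by seed and order-invariant", {
  s <- testPanelSetup(3, 3, seed = 57)
  specs <- list(modelSpec(1, covariates = s$spec@covariateNames),
                modelSpec(2, covariates = s$spec@covariateNames))
  t1 <- suppressWarnings(compareModels(specs, s$panel, s$covars,
                                       s$lattice, draws = 200,
                                       warmup = 200, seed = 58))
  t2 <- suppressWarnings(compareModels(rev(specs), s$panel, s$covars,
                                       s$lattice, draws = 200,
                                       warmup = 200, seed = 58))
  expect_equal(sort(t1$DIC), sort(t2$DIC))
  # identical specs, same seed -> identical DIC
  t3 <- suppressWarnings(compareModels(list(specs[[1]], specs[[1]]),
                                       s$panel, s$covars, s$lattice,
                                       draws = 200, warmup = 200,
                                       seed = 58))
  expect_equal(t3$DIC[1], t3$DIC[2])
})

test_that("negative-binomial fits recover the dispersion scale", {
  lat <- makeGridLattice(4, 4)
  cv <- simulateCovariates(lat, seed = 60)
  pops <- simulatePopulations(lat, seed = 61)
  sp <- modelSpec(2, likelihood = "negbin", covariates = character())
  tr <- simulationTruth(sp, lat, nbDispersion = 5, seed = 62)
  pan <- simulatePanel(sp, tr, lat, cv, pops, seed = 63)
  fit <- quickFit(sp, pan, NULL, lat, draws = 800, warmup = 800,
                  seed = 64)
  su <- posteriorSummary(fit)
  row <- su[su$parameter == "nb_dispersion", ]
  expect_gt(row$q97.5, 5 * 0.5)
  expect_lt(row$q2.5, 5 * 2)
})
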