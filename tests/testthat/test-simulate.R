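# Generator properties: ICAR draws against the Laplacian-eigenbasis
# oracle, RW1 increments, covariate stepping, and panel distributions.

test_that("ICAR draws sum to zero and are reproducible by seed", {
  lat <- makeGridLattice(4, 4)
  s1 <- sampleICAR(lat, tauS = 3, seed = 5)
  s2 <- sampleICAR(lat, tauS = 3, seed = 5)
  s3 <- sampleICAR(lat, tauS = 3, seed = 6)
  expect_lt(abs(sum(s1)), 1e-9)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_error(sampleICAR(makeGridLattice(1, 1), 1), "single tract")
})

test_that("disconnected lattices need per-component centering", {
  lat <- suppressWarnings(TractLattice(c("A", "B", "C", "D"),
                                       rbind(c("A", "B"), c("C", "D"))))
  expect_error(sampleICAR(lat, 1, seed = 1), "disconnected")
  s <- sampleICAR(lat, 1, seed = 1, perComponent = TRUE)
  expect_lt(abs(sum(s[c("A", "B")])), 1e-9)
  expect_lt(abs(sum(s[c("C", "D")])), 1e-9)
})

test_that("ICAR empirical covariance matches the pseudo-inverse of
          tau * (D - W)", {
  lat <- makeGridLattice(3, 3)
  tau <- 2
  S <- sampleICAR(lat, tauS = tau, nDraws = 20000, seed = 1)
  emp <- cov(t(S))
  eg <- eigen(icarPrecision(lat), symmetric = TRUE)
  keep <- eg$values > 1e-8
  pinv <- eg$vectors[, keep] %*% diag(1 / (tau * eg$values[keep])) %*%
    t(eg$vectors[, keep])
  expect_lt(max(abs(emp - pinv)), 0.012)  # ~3 Monte-Carlo s.e.
})

test_that("ICAR fields have conditional mean slope ~ 1 on neighbour means", {
  lat <- makeGridLattice(6, 6)
  S <- sampleICAR(lat, tauS = 1, nDraws = 2000, seed = 2)
  nm <- apply(S, 2, function(s) neighborMeans(lat, s))
  slope <- coef(lm(as.vector(S) ~ as.vector(nm)))[2]
  expect_equal(unname(slope), 1, tolerance = 0.08)
})

test_that("RW1 draws have the stated increment distribution", {
  expect_error(sampleRW1(4, tauGamma = 0), "tauGamma")
  # zero-variance limit: the walk sticks to its start
  g <- sampleRW1(5, tauGamma = 1e12, gamma0 = 2, seed = 1)
  expect_equal(g, rep(2, 5), tolerance = 1e-4)
  expect_length(sampleRW1(1, 1, seed = 1), 1)
  set.seed(3)
  draws <- replicate(10000, sampleRW1(5, tauGamma = 4))
  incs <- diff(rbind(0, draws))
  expect_equal(var(as.vector(incs)), 1 / 4, tolerance = 0.05)
})

test_that("simulated covariates step yearly within valid ranges", {
  lat <- makeGridLattice(3, 3)
  cv <- simulateCovariates(lat, years = 2018:2021, sdChange = 0,
                           seed = 4)
  v <- covariateValues(cv)
  expect_true(all(v[, 1, ] == v[, 4, ]))      # constant when sd = 0
  cv2 <- simulateCovariates(lat, years = 2018:2021, seed = 4)
  v2 <- covariateValues(cv2)
  pct <- v2[, , startsWith(covariateNames(cv2), "pct")]
  expect_true(all(pct >= 0 & pct <= 100))
  expect_identical(covariateValues(simulateCovariates(lat, seed = 4)),
                   covariateValues(simulateCovariates(lat, seed = 4)))
})

test_that("simulated populations are log-uniform within bounds", {
  lat <- makeGridLattice(10, 10)
  p <- simulatePopulations(lat, seed = 5)
  expect_true(all(p >= 200 & p <= 3000))
  expect_identical(p, simulatePopulations(lat, seed = 5))
})

test_that("null-effect panels have Poisson cell means P * exp(beta0)", {
  lat <- makeGridLattice(10, 5)  # 50 tracts x 4 periods = 200 cells
  spec <- modelSpec(temporal = "none", covariates = character(),
                    spatial = FALSE, iid = FALSE)
  truth <- simulationTruth(spec, lat, beta0 = log(0.01), seed = 6)
  pops <- setNames(rep(1000, 50), tractIds(lat))
  pan <- simulatePanel(spec, truth, lat, NULL, pops, seed = 7)
  m <- mean(panelCounts(pan))
  se <- sqrt(10 / 200)
  expect_lt(abs(m - 10), 3 * se)
})

test_that("a missing truth component raises an error naming the term", {
  s <- testPanelSetup(3, 3, model = 5, seed = 8)
  tr <- s$truth
  tr@delta <- matrix(numeric(0), 0, 0)
  expect_error(simulatePanel(s$spec, tr, s$lattice, s$covars, s$pops),
               "delta")
  tr2 <- s$truth
  tr2@gamma <- numeric(0)
  expect_error(simulatePanel(s$spec, tr2, s$lattice, s$covars, s$pops),
               "gamma")
})

test_that("year-indicator and pandemic-indicator structures agree when the
          indicator patterns coincide", {
  lat <- makeGridLattice(4, 4)
  cv <- simulateCovariates(lat, seed = 9)
  pops <- simulatePopulations(lat, seed = 10)
  sp1 <- modelSpec(1); sp2 <- modelSpec(2)
  tr2 <- simulationTruth(sp2, lat, seed = 11)
  tr1 <- simulationTruth(sp1, lat, seed = 11,
                         alphaYear = c(0, tr2@alphaCovid, tr2@alphaCovid))
  m1 <- expectedCounts(sp1, tr1, lat, cv, pops)
  m2 <- expectedCounts(sp2, tr2, lat, cv, pops)
  expect_equal(m1, m2)
})

test_that("small tau_delta inflates cell variance beyond the additive
          model at equal means", {
  lat <- makeGridLattice(4, 4)
  cv <- simulateCovariates(lat, seed = 12)
  pops <- simulatePopulations(lat, seed = 13)
  sp4 <- modelSpec(4, covariates = character())
  sp5 <- modelSpec(5, covariates = character())
  tr4 <- simulationTruth(sp4, lat, seed = 14)
  tr5 <- simulationTruth(sp5, lat, seed = 14, tauDelta = 1)
  tr5@gamma <- tr4@gamma; tr5@phi <- tr4@phi
  mu <- expectedCounts(sp4, tr4, lat, cv, pops)
  set.seed(15)
  excess4 <- excess5 <- 0
  for (b in 1:200) {
    p4 <- simulatePanel(sp4, tr4, lat, cv, pops)
    tr5@delta <- matrix(rnorm(16 * 48, 0, 1), 16, 48)
    p5 <- simulatePanel(sp5, tr5, lat, cv, pops)
    excess4 <- excess4 + var(as.vector((panelCounts(p4) - mu) / sqrt(mu)))
    excess5 <- excess5 + var(as.vector((panelCounts(p5) - mu) / sqrt(mu)))
  }
  expect_gt(excess5, excess4)
})

test_that("negative-binomial panels recover the Poisson dispersion index
          as the dispersion grows", {
  lat <- makeGridLattice(5, 5)
  cv <- simulateCovariates(lat, seed = 16)
  pops <- simulatePopulations(lat, seed = 17)
  spNB <- modelSpec(2, likelihood = "negbin", covariates = character())
  trBig <- simulationTruth(spNB, lat, nbDispersion = 1e8, seed = 18)
  mu <- expectedCounts(spNB, trBig, lat, cv, pops)
  pan <- simulatePanel(spNB, trBig, lat, cv, pops, seed = 19)
  idx <- var(as.vector((panelCounts(pan) - mu) / sqrt(mu)))
  expect_lt(abs(idx - 1), 0.35)   # Pearson dispersion index ~ 1
  trSmall <- simulationTruth(spNB, lat, nbDispersion = 2, seed = 18)
  pan2 <- simulatePanel(spNB, trSmall, lat, cv, pops, seed = 19)
  idx2 <- var(as.vector((panelCounts(pan2) - mu) / sqrt(mu)))
  expect_gt(idx2, 3)
})
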