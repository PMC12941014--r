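# VIF screening, quartile-contrast effects, and the prior grid.

covarsFromMatrix <- function(M, years = 2018) {
  arr <- array(NA_real_, c(nrow(M), length(years), ncol(M)),
               dimnames = list(sprintf("t%03d", seq_len(nrow(M))),
                               as.character(years), colnames(M)))
  for (y in seq_along(years)) arr[, y, ] <- M
  CovariateTable(arr, percentage = setNames(rep(FALSE, ncol(M)),
                                            colnames(M)))
}

test_that("independent predictors have VIF near 1", {
  set.seed(70)
  M <- cbind(a = rnorm(2000), b = rnorm(2000))
  tab <- vifTable(covarsFromMatrix(M), includeYear = FALSE)
  expect_true(all(abs(tab$vif - 1) < 0.05))
  expect_true(all(tab$classification == "low"))
})

test_that("a pair with correlation 0.9 has VIF = 1/(1 - 0.81)", {
  set.seed(71)
  x <- rnorm(500)
  e <- rnorm(500)
  e <- residuals(lm(e ~ x))                  # exactly orthogonal to x
  x <- (x - mean(x)) / sd(x)
  e <- e / sd(e)
  y <- 0.9 * x + sqrt(1 - 0.81) * e          # sample correlation 0.9
  M <- cbind(a = x, b = y)
  tab <- vifTable(covarsFromMatrix(M), includeYear = FALSE)
  expect_equal(tab$vif, rep(1 / (1 - 0.81), 2), tolerance = 1e-6)
  expect_true(all(tab$classification == "moderate"))
})

test_that("perfect collinearity is flagged as infinite", {
  set.seed(72)
  x <- rnorm(100)
  M <- cbind(a = x, b = 2 * x + 3, c = rnorm(100))
  tab <- vifTable(covarsFromMatrix(M), includeYear = FALSE)
  expect_true(all(tab$collinear[tab$predictor %in% c("a", "b")]))
  expect_error(vifTable(covarsFromMatrix(cbind(a = x, b = rep(1, 100))),
                        includeYear = FALSE), "constant")
})

test_that("VIF is invariant to affine rescaling of a predictor", {
  set.seed(73)
  M <- cbind(a = rnorm(300), b = rnorm(300), c = rnorm(300))
  M[, "b"] <- M[, "a"] * 0.5 + M[, "b"]
  t1 <- vifTable(covarsFromMatrix(M), includeYear = FALSE)
  M2 <- M; M2[, "a"] <- 100 * M2[, "a"] - 7
  t2 <- vifTable(covarsFromMatrix(M2), includeYear = FALSE)
  expect_equal(t1$vif, t2$vif, tolerance = 1e-8)
})

test_that("VIF includes calendar year as a numeric predictor", {
  lat <- makeGridLattice(4, 4)
  cv <- simulateCovariates(lat, seed = 74)
  tab <- vifTable(cv)
  expect_true("Year" %in% tab$predictor)
  expect_equal(nrow(tab), 6)
})

test_that("quartiles use linear interpolation and bracket the median", {
  expect_equal(quartiles(1:8), c(q1 = 2.75, q3 = 6.25))
  expect_equal(quartiles(8:1), c(q1 = 2.75, q3 = 6.25))
  expect_equal(quartiles(rep(3.5, 6)), c(q1 = 3.5, q3 = 3.5))
  expect_error(quartiles(1:3), "at least 4")
  set.seed(75)
  for (r in 1:10) {
    x <- rnorm(20)
    q <- quartiles(x)
    expect_lte(q[["q1"]], median(x))
    expect_gte(q[["q3"]], median(x))
  }
})

test_that("the quartile-contrast effect follows its closed form", {
  expect_equal(round(q1q3Effect(0.0117, 24.1, 50.3)$effect, 3), 1.359)
  expect_equal(q1q3Effect(0, 1, 99)$effect, 1)
  expect_equal(q1q3Effect(0.1, 0, 10)$effect, exp(1))
  expect_error(q1q3Effect(1, 5, 2))
  # monotone in the slope; 1 iff slope 0 or q1 = q3
  b <- seq(-0.5, 0.5, by = 0.25)
  eff <- vapply(b, function(bb) q1q3Effect(bb, 2, 4)$effect, numeric(1))
  expect_true(all(diff(eff) > 0))
  expect_equal(q1q3Effect(0.7, 3, 3)$effect, 1)
})

test_that("the effect table computes quartiles from the covariate table", {
  lat <- makeGridLattice(4, 4)
  cv <- simulateCovariates(lat, seed = 76)
  tab <- effectsTable(c(median_age = 0.01, median_income = -0.002), cv)
  expect_equal(nrow(tab), 2)
  q <- quartiles(as.vector(covariateValues(cv)[, , "median_age"]))
  expect_equal(tab$effect[1], exp(0.01 * (q[["q3"]] - q[["q1"]])))
  expect_error(effectsTable(c(nope = 1), cv), "unknown covariates")
})

test_that("the prior grid yields 8 combinations, identical when the
          alternatives equal the defaults", {
  s <- testPanelSetup(3, 3, seed = 77,
                     covariates = "pct_public_insurance")
  sameAsDefault <- priorConfig()
  tab <- suppressWarnings(priorSensitivity(
    modelSpec(1, covariates = "pct_public_insurance"), s$panel, s$covars,
    s$lattice, alternative = sameAsDefault, draws = 150, warmup = 150,
    chains = 1, seed = 78))
  expect_equal(length(unique(tab$combination)), 8)
  base <- tab[tab$combination == 1, "mean"]
  for (g in 2:8)
    expect_equal(tab[tab$combination == g, "mean"], base)
})

test_that("with informative data the prior choice moves estimates little", {
  s <- testPanelSetup(4, 4, seed = 79,
                     covariates = "pct_public_insurance")
  tab <- suppressWarnings(priorSensitivity(
    modelSpec(1, covariates = "pct_public_insurance"), s$panel, s$covars,
    s$lattice, draws = 400, warmup = 400, chains = 1, seed = 80))
  slopes <- tab[tab$parameter == "pct_public_insurance", ]
  spread <- max(slopes$mean) - min(slopes$mean)
  expect_lt(spread, 2 * max(slopes$posterior_sd))
})
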