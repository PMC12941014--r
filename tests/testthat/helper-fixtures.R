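# Shared fixtures, built in code: tiny lattices, visit tables, and a
# fast-fit wrapper for tests that only need a rough posterior.

makeVisits <- function(tract, date, codes, age = 30, sex = "F") {
  n <- length(tract)
  data.frame(tract_id = tract, date = as.Date(date),
             icd_codes = I(if (is.list(codes)) codes else as.list(codes)),
             age = rep_len(age, n), sex = rep_len(sex, n),
             stringsAsFactors = FALSE)
}

# n single-code visits spread over a date
repeatedVisits <- function(n, tract, date, code) {
  if (n == 0) return(makeVisits(character(), as.Date(character()),
                                character())[0, ])
  makeVisits(rep(tract, n), rep(as.Date(date), n), as.list(rep(code, n)))
}

testPanelSetup <- function(rows = 5, cols = 5, seed = 42,
                           covariates = c("pct_public_insurance",
                                          "median_age"),
                           model = 1, likelihood = "poisson", ...) {
  lat <- makeGridLattice(rows, cols)
  spec <- modelSpec(model, likelihood = likelihood,
                    covariates = covariates)
  covars <- simulateCovariates(lat, seed = seed)
  pops <- simulatePopulations(lat, seed = seed + 1)
  truth <- simulationTruth(spec, lat, seed = seed + 2, ...)
  panel <- simulatePanel(spec, truth, lat, covars, pops, seed = seed + 3)
  list(lattice = lat, spec = spec, covars = covars, pops = pops,
       truth = truth, panel = panel)
}

quickFit <- function(spec, panel, covars = NULL, lattice = NULL,
                     draws = 600, warmup = 600, chains = 2, seed = 1, ...) {
  suppressWarnings(fitSTModel(spec, panel, covars = covars,
                              lattice = lattice, draws = draws,
                              warmup = warmup, chains = chains,
                              seed = seed, ...))
}

# brute-force Moran's I by explicit double loop (independent oracle)
bruteMoran <- function(values, W) {
  N <- length(values)
  xbar <- mean(values)
  num <- 0; S0 <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) {
    num <- num + W[i, j] * (values[i] - xbar) * (values[j] - xbar)
    S0 <- S0 + W[i, j]
  }
  (N / S0) * num / sum((values - xbar)^2)
}
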