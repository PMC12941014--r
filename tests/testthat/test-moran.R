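# Moran's I against a brute-force double-loop oracle, its invariances,
# and the permutation test.

test_that("Moran's I equals the brute-force double sum on small lattices", {
  set.seed(1)
  lattices <- list(makeGridLattice(2, 2), makeGridLattice(2, 3),
                   makeGridLattice(1, 5), makeGridLattice(1, 6),
                   suppressWarnings(TractLattice(
                     letters[1:5], rbind(c("a", "b"), c("b", "c"),
                                         c("c", "d"), c("d", "e"),
                                         c("a", "e"), c("b", "e")))))
  for (lat in lattices) {
    x <- rnorm(nTracts(lat))
    W <- as.matrix(adjacencyMatrix(lat))
    expect_equal(moransI(x, lat, "binary"), bruteMoran(x, W),
                 tolerance = 1e-12)
    Wr <- W / rowSums(W)
    expect_equal(moransI(x, lat, "row"), bruteMoran(x, Wr),
                 tolerance = 1e-12)
  }
})

test_that("Moran's I agrees with an independent reference implementation", {
  lat <- makeGridLattice(4, 5)
  set.seed(2)
  x <- rnorm(20)
  # ape row-normalises the supplied weight matrix
  ref <- ape::Moran.I(x, as.matrix(adjacencyMatrix(lat)), scaled = FALSE)
  expect_equal(moransI(x, lat, "row"), ref$observed, tolerance = 1e-10)
})

test_that("a perfect checkerboard on a rook lattice gives I = -1", {
  lat <- makeGridLattice(4, 4, "rook")
  board <- outer(1:4, 1:4, function(r, c) (-1)^(r + c))
  # lattice ids are row-major, so flatten by row
  x <- as.vector(t(board))
  expect_equal(moransI(x, lat), -1)
})

test_that("Moran's I is invariant to shift and positive scaling", {
  lat <- makeGridLattice(3, 4)
  set.seed(3)
  x <- rnorm(12)
  base <- moransI(x, lat)
  expect_equal(moransI(x + 100, lat), base)
  expect_equal(moransI(3.7 * x, lat), base)
  perm <- sample(x)
  expect_equal(sum((perm - mean(perm))^2), sum((x - mean(x))^2))
})

test_that("degenerate inputs are rejected", {
  lat <- makeGridLattice(2, 2)
  expect_error(moransI(rep(1, 4), lat), "zero variance")
  latIso <- suppressWarnings(TractLattice(c("A", "B", "C"),
                                          cbind("A", "B")))
  expect_error(moransI(c(1, 2, 3), latIso, scheme = "row"), "isolated")
  expect_silent(moransI(c(1, 2, 3), latIso, scheme = "row",
                        allowZeroRows = TRUE))
})

test_that("the permutation test is reproducible with the documented null", {
  lat <- makeGridLattice(5, 2)
  set.seed(4)
  x <- rnorm(10)
  r1 <- moranTest(x, lat, nPerm = 499, seed = 9)
  r2 <- moranTest(x, lat, nPerm = 499, seed = 9)
  expect_identical(r1@pValue, r2@pValue)
  expect_equal(r1@expectedI, -1 / 9)
  expect_gt(r1@pValue, 0)
  expect_lte(r1@pValue, 1)
})

test_that("the permutation null mean is -1/(N-1) within Monte-Carlo error", {
  lat <- makeGridLattice(5, 5)
  set.seed(5)
  x <- rnorm(25, 10, 2)
  r <- moranTest(x, lat, nPerm = 5000, seed = 6)
  mcse <- sd(r@permuted) / sqrt(r@nPerm)
  expect_lt(abs(mean(r@permuted) - (-1 / 24)), 3 * mcse)
})

test_that("iid fields give I near the null expectation on average", {
  lat <- makeGridLattice(4, 4)
  set.seed(7)
  Is <- replicate(400, moransI(rnorm(16), lat))
  se <- sd(Is) / sqrt(length(Is))
  expect_lt(abs(mean(Is) - (-1 / 15)), 3 * se)
})

test_that("strong spatial smoothing is detected with high power", {
  lat <- makeGridLattice(7, 7)
  sig <- 0
  for (r in 1:50) {
    s <- sampleICAR(lat, tauS = 0.5, seed = 3000 + r)
    field <- s + rnorm(49, 0, 0.05)
    sig <- sig + (moranTest(field, lat, nPerm = 199,
                            seed = 4000 + r)@pValue <= 0.05)
  }
  expect_gte(sig / 50, 0.9)
})

test_that("the moran table reports one row per category and period group", {
  s <- testPanelSetup(4, 4, seed = 20)
  tab <- moranTable(list(ALL = s$panel, SUB = s$panel), s$lattice,
                    periodGroups = list(before = c("2018", "2019"),
                                        during = c("2020", "2021")),
                    nPerm = 99, seed = 1)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$expected_I, rep(-1 / 15, 4))
  expect_equal(tab$n[1], sum(panelCounts(s$panel)[, 1:2]))
})
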