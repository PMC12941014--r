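# ICD-10 categorisation, panel building, and the two-period tally.

test_that("the default category map has 8 disjoint categories", {
  map <- defaultCategoryMap()
  expect_identical(categoryNames(map),
                   c("Depression", "Bipolar Disorder", "Anxiety", "PTSD",
                     "OCD", "Psychosis", "Substance Abuse", "Other"))
  allCodes <- c(unlist(map@codeSets), unlist(map@prefixSets))
  expect_equal(anyDuplicated(allCodes), 0L)
})

test_that("visits are categorised by exact and prefix code matching", {
  map <- defaultCategoryMap()
  expect_equal(categorizeVisit("F32.9", map), "Depression")
  expect_setequal(categorizeVisit(c("F32.9", "F41.1"), map),
                  c("Depression", "Anxiety"))
  # undotted substance-use stems match by prefix
  expect_equal(categorizeVisit("F10.10", map), "Substance Abuse")
  expect_equal(categorizeVisit("F19", map), "Substance Abuse")
  # unmatched codes yield the empty set
  expect_length(categorizeVisit("Z00.0", map), 0)
  # several codes from one category count it once
  expect_equal(categorizeVisit(c("F32.0", "F33.9"), map), "Depression")
})

test_that("visit validation enforces the ICD-10 lexical pattern", {
  expect_error(validateVisits(makeVisits("A", "2019-01-01", "notacode")),
               "lexically invalid")
  expect_error(validateVisits(makeVisits("A", "2019-01-01",
                                         list(character()))),
               "at least one")
  v <- validateVisits(makeVisits("A", "2019-01-01", "F32A"))
  expect_s3_class(v$date, "Date")
})

test_that("panels count category-matching visits per tract and period", {
  lat <- suppressWarnings(TractLattice(c("A", "B")))
  pops <- c(A = 100, B = 200)
  visits <- rbind(repeatedVisits(3, "A", "2019-05-01", "F32.9"),
                  makeVisits("B", "2020-07-01", list(c("F32.9", "F41.1"))))
  dep <- buildPanel(visits, lat, pops, category = "Depression")
  expect_equal(panelCounts(dep)["A", "2019"], 3L)
  expect_equal(sum(panelCounts(dep)), 4L)
  # the multi-diagnosis visit appears in both category panels
  anx <- buildPanel(visits, lat, pops, category = "Anxiety")
  expect_equal(panelCounts(anx)["B", "2020"], 1L)
  expect_equal(sum(panelCounts(anx)), 1L)
  # monthly granularity over the 4-year window gives T = 48
  mon <- buildPanel(visits, lat, pops, granularity = "month")
  expect_equal(nPeriods(mon), 48L)
  expect_equal(panelCounts(mon)["A", "2019-05"], 3L)
})

test_that("out-of-window and unmappable visits are excluded with a log", {
  lat <- suppressWarnings(TractLattice("A"))
  visits <- rbind(makeVisits("A", "2017-12-31", "F32.9"),
                  makeVisits("A", "2019-01-01", "Z00.0"),
                  makeVisits("A", "2019-01-01", "F32.9"))
  expect_message(
    expect_message(
      p <- buildPanel(visits, lat, c(A = 10)),
      "outside the study window"),
    "no mappable")
  expect_equal(sum(panelCounts(p)), 1L)
  expect_error(buildPanel(makeVisits("X", "2019-01-01", "F32.9"), lat,
                          c(A = 10)), "not in lattice")
})

test_that("per-category totals exceed the ALL total only via multi-diagnosis
          visits", {
  lat <- suppressWarnings(TractLattice(c("A", "B")))
  pops <- c(A = 10, B = 10)
  map <- defaultCategoryMap()
  single <- rbind(repeatedVisits(2, "A", "2019-02-01", "F32.9"),
                  repeatedVisits(3, "B", "2020-03-01", "F41.1"))
  multi <- rbind(single,
                 makeVisits("A", "2021-01-01", list(c("F32.9", "F41.1"))))
  for (visits in list(single, multi)) {
    perCat <- sum(vapply(categoryNames(map), function(cc)
      sum(panelCounts(buildPanel(visits, lat, pops, category = cc))),
      numeric(1)))
    all <- sum(panelCounts(buildPanel(visits, lat, pops)))
    expect_gte(perCat, all)
    nMulti <- sum(vapply(visits$icd_codes, function(cd)
      length(categorizeVisit(cd, map)) > 1, TRUE))
    expect_equal(perCat - all, nMulti)
  }
})

test_that("the two-period tally reports counts and column percentages", {
  visits <- rbind(repeatedVisits(3, "A", "2019-01-15", "F32.9"),
                  repeatedVisits(1, "A", "2019-02-15", "F41.1"),
                  repeatedVisits(4, "A", "2020-06-15", "F41.1"))
  tab <- covidSplitTable(visits)
  anx <- tab[tab$category == "Anxiety", ]
  expect_equal(anx$before_n, 1)
  expect_equal(anx$before_pct, 25)     # 1 of 4 pre-period visits
  expect_equal(anx$during_n, 4)
  expect_equal(anx$during_pct, 100)
  expect_equal(anx$total_n, 5)
  expect_equal(anx$total_pct, 62.5)
  expect_equal(tab$total_n[tab$category == "Total"], 8)
  # empty input: all counts and percentages zero
  empty <- covidSplitTable(makeVisits(character(), as.Date(character()),
                                      character())[0, ])
  expect_true(all(empty$total_n == 0) && all(empty$total_pct == 0))
})

test_that("panels and covariates round-trip through CSV exactly", {
  s <- testPanelSetup(rows = 3, cols = 3, seed = 11)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writePanel(s$panel, f1, f2)
  back <- readPanel(f1, f2)
  expect_identical(panelCounts(back), panelCounts(s$panel))
  expect_equal(populations(back), populations(s$panel))
  expect_identical(periodLabels(back), periodLabels(s$panel))
  expect_identical(granularity(back), granularity(s$panel))
  f3 <- tempfile(fileext = ".csv")
  writeCovariates(s$covars, f3)
  covBack <- readCovariates(f3)
  expect_equal(covariateValues(covBack), covariateValues(s$covars))
})
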