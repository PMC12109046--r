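test_that("generated checklists hit the requested taxonomic shape exactly", {
  sim <- generateChecklist(45, 38, 20, 11, seed = 42)
  cl <- sim$checklist
  expect_equal(nSpecies(cl), 45)
  expect_equal(nGenera(cl), 38)
  expect_equal(nFamilies(cl), 20)
  expect_equal(nOrders(cl), 11)
  expect_s4_class(sim$truth, "SyntheticTruth")

  one <- generateChecklist(1, 1, 1, 1, seed = 1)$checklist
  expect_equal(c(nSpecies(one), nGenera(one), nFamilies(one), nOrders(one)),
               rep(1, 4))

  expect_error(generateChecklist(5, 8, 2, 1), "nSpecies >= nGenera")

  # determinism
  a <- generateChecklist(30, 20, 10, 5, seed = 7)$checklist
  b <- generateChecklist(30, 20, 10, 5, seed = 7)$checklist
  expect_identical(taxa(a), taxa(b))
  # shapes vary but stay proper over random requests
  set.seed(1)
  for (i in 1:10) {
    no <- sample(1:5, 1); nf <- no + sample(0:5, 1)
    ng <- nf + sample(0:8, 1); ns <- ng + sample(0:20, 1)
    cli <- generateChecklist(ns, ng, nf, no, seed = i)$checklist
    expect_equal(c(nSpecies(cli), nGenera(cli), nFamilies(cli), nOrders(cli)),
                 c(ns, ng, nf, no))
  }
})

test_that("generated surveys respect membership, legend and determinism", {
  cl <- exampleChecklist()
  tr <- defaultTruth(seed = 3)
  sv <- generateSurveys(cl, 2014:2016, 10, truth = tr)
  r <- surveyRecords(sv)
  expect_true(all(r$species %in% taxa(cl)$species))
  expect_true(all(r$habitat %in% habitatClasses()))
  expect_true(all(r$count >= 1))
  sv2 <- generateSurveys(cl, 2014:2016, 10, truth = tr)
  expect_identical(surveyRecords(sv2), r)
  expect_error(generateSurveys(cl, integer(0), 10, truth = tr), "non-empty")
})

test_that("guild water response shapes expected counts as programmed", {
  # dabbling optimum 1.2 m: mean dabbling counts near 1.2 m exceed those
  # near 2.8 m over a large survey draw
  cl <- suppressWarnings(assignGuilds(exampleChecklist()))
  tr <- defaultTruth(seed = 21, trendFactor = 1)
  sv <- generateSurveys(cl, 2001:2050, 20, truth = tr)  # 1000 site-years
  r <- surveyRecords(sv)
  dab <- taxa(cl)$species[taxa(cl)$guild == "dabbling"]
  rd <- r[r$species %in% dab, ]
  near <- function(w) abs(rd$water_level_m - w) <= 0.2
  expect_gt(mean(rd$count[near(1.2)]), mean(rd$count[near(2.8)]))
})

test_that("trendless truth yields equal first- and last-year totals", {
  cl <- exampleChecklist()
  tr <- defaultTruth(seed = 5, trendFactor = 1)
  sv <- generateSurveys(cl, 2014:2023, 20, truth = tr)
  tot <- totalAbundanceByYear(sv)
  expect_equal(unname(tot[length(tot)] / tot[1]), 1, tolerance = 0.15)
})

test_that("flock quantisation reports large congregations at coarse steps", {
  cl <- exampleChecklist()
  tr <- defaultTruth(seed = 8, baseAbundance = 3000)
  sv <- generateSurveys(cl, 2020, 10, truth = tr, flockQuantize = TRUE)
  ct <- surveyRecords(sv)$count
  expect_true(any(ct >= 500))
  expect_true(all(ct[ct >= 500] %% 50 == 0))
  expect_true(all(ct[ct >= 200 & ct < 500] %% 20 == 0))
  expect_true(all(ct[ct >= 50 & ct < 200] %% 10 == 0))
})

test_that("land-cover series follow the programmed transition dynamics", {
  # identity matrix -> constant series
  ser <- generateLandcoverSeries(15, 15, rep(0.2, 5),
                                 diag(5), nSteps = 3, seed = 2)
  for (i in 2:4)
    expect_identical(gridCodes(ser[[i]]), gridCodes(ser[[1]]))

  # degenerate initial proportions -> single-class first grid
  ser <- generateLandcoverSeries(10, 10, c(1, 0, 0, 0, 0),
                                 defaultTransitionMatrix(), 0, seed = 2)
  expect_true(all(gridCodes(ser[[1]]) == 1L))

  # law of large numbers: empirical one-step frequencies near the matrix
  tm <- defaultTransitionMatrix()
  ser <- generateLandcoverSeries(200, 200, rep(0.2, 5), tm, 1, seed = 11)
  est <- transitionProbabilities(crosstabTransitions(ser[[1]], ser[[2]]))
  expect_lt(max(abs(est - tm)), 0.02)

  # cell count conserved across the series
  expect_equal(sum(!is.na(gridCodes(ser[[2]]))),
               sum(!is.na(gridCodes(ser[[1]]))))

  expect_error(generateLandcoverSeries(5, 5, rep(0.2, 5),
                                       matrix(1, 5, 5), 1, seed = 1),
               "row-stochastic")
})
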