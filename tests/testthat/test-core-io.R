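test_that("checklist construction validates hierarchy and derives counts", {
  cl <- Checklist(smallTaxa())
  expect_equal(nSpecies(cl), 4)
  expect_equal(nGenera(cl), 3)
  expect_equal(nFamilies(cl), 3)
  expect_equal(nOrders(cl), 3)

  # singleton
  cl1 <- Checklist(smallTaxa()[1, ])
  expect_equal(c(nSpecies(cl1), nGenera(cl1), nFamilies(cl1), nOrders(cl1)),
               rep(1, 4))

  # duplicate species named in the error
  dup <- rbind(smallTaxa(), smallTaxa()[1, ])
  expect_error(Checklist(dup), "Anas acuta")

  # genus under two families
  bad <- smallTaxa()
  bad$family[2] <- "Ardeidae"
  expect_error(Checklist(bad), "genus mapped to more than one family")

  # unknown tokens
  bad <- smallTaxa(); bad$guild[1] <- "swimmer"
  expect_error(Checklist(bad), "unknown guild")
  bad <- smallTaxa(); bad$iucn_status[1] <- "XX"
  expect_error(Checklist(bad), "unknown IUCN")
})

test_that("checklist names are whitespace- and case-normalised", {
  t <- smallTaxa()
  t$species[1] <- "  anas   Acuta "
  t$genus[1] <- "ANAS"
  cl <- Checklist(t)
  expect_equal(taxa(cl)$species[1], "Anas acuta")
  expect_equal(taxa(cl)$genus[1], "Anas")
  # derived counts idempotent under re-validation
  cl2 <- Checklist(taxa(cl))
  expect_identical(taxa(cl2), taxa(cl))
})

test_that("checklist CSV round-trips through read/write", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeChecklist(exampleChecklist(), p)
  cl <- readChecklist(p)
  expect_equal(nSpecies(cl), 45)
  expect_identical(taxa(cl), taxa(exampleChecklist()))
})

test_that("survey validation enforces counts, habitats and membership", {
  cl <- Checklist(smallTaxa())
  st <- SurveyTable(smallSurveyDf(), cl)
  expect_equal(length(st), 3)

  bad <- smallSurveyDf(); bad$count[1] <- -1L
  expect_error(SurveyTable(bad), "non-negative")

  bad <- smallSurveyDf(); bad$habitat[2] <- "forest"
  expect_error(SurveyTable(bad), "forest")

  unknown <- smallSurveyDf(); unknown$species[3] <- "Grus grus"
  expect_error(SurveyTable(unknown, cl, strict = TRUE), "Grus grus")
  expect_warning(SurveyTable(unknown, cl, strict = FALSE), "Grus grus")
})

test_that("survey CSV round-trips and totals are preserved", {
  p <- withr::local_tempfile(fileext = ".csv")
  st <- SurveyTable(smallSurveyDf())
  writeSurveys(st, p)
  st2 <- readSurveys(p)
  expect_equal(surveyRecords(st2)$count, surveyRecords(st)$count)
  expect_equal(totalAbundanceByYear(st2), c(`2014` = 7, `2015` = 7))
})

test_that("community matrix sums counts per group and conserves individuals", {
  df <- data.frame(year = 2014L, site_id = "s1", habitat = "water",
                   species = "Anas acuta", count = c(5L, 7L),
                   water_level_m = 1)
  cm <- buildCommunityMatrix(SurveyTable(df))
  expect_equal(dim(cm), c(1, 1))
  expect_equal(unname(abundanceMatrix(cm)[1, 1]), 12)

  # 100 random records vs full re-scan oracle
  set.seed(11)
  n <- 100
  df <- data.frame(
    year = sample(2014:2016, n, TRUE), site_id = "s",
    habitat = sample(habitatClasses(), n, TRUE),
    species = sample(paste0("Taxon", letters[1:6]), n, TRUE),
    count = sample(0:20, n, TRUE), water_level_m = runif(n, 0, 3))
  cm <- buildCommunityMatrix(SurveyTable(df), by = c("year", "habitat"))
  g <- groupInfo(cm)
  for (i in seq_len(nrow(g))) {
    sel <- df$year == g$year[i] & df$habitat == g$habitat[i]
    expect_equal(unname(groupTotals(cm)[i]), sum(df$count[sel]))
    for (sp in unique(df$species[sel]))
      expect_equal(unname(abundanceMatrix(cm)[i, sp]),
                   sum(df$count[sel & df$species == sp]))
  }
  expect_equal(sum(abundanceMatrix(cm)), sum(df$count))

  # empty table -> empty matrix, not an error
  cm0 <- buildCommunityMatrix(SurveyTable(smallSurveyDf()[0, ]))
  expect_equal(dim(cm0), c(0, 0))
})

test_that("ASCII grid write-then-read is the identity including NODATA", {
  g <- LandCoverGrid(matrix(3L, 2, 2))
  expect_equal(unname(classAreas(g)["water"]), 4)

  p <- withr::local_tempfile(fileext = ".asc")
  # 1x1 grid
  writeAsciiGrid(LandCoverGrid(matrix(5L, 1, 1)), p)
  expect_identical(gridCodes(readAsciiGrid(p)), matrix(5L, 1, 1))

  # NODATA round-trip
  m <- matrix(c(1L, NA, 2L, 4L), 2, 2)
  writeAsciiGrid(LandCoverGrid(m), p)
  expect_identical(gridCodes(readAsciiGrid(p)), m)

  # random 50x50 with NODATA, exact round-trip
  g <- randomGrid(50, 50, seed = 3, nodataFrac = 0.1)
  writeAsciiGrid(g, p)
  g2 <- readAsciiGrid(p)
  expect_identical(gridCodes(g2), gridCodes(g))
})

test_that("ASCII grid parser rejects ragged and mislabelled input", {
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 3", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999", "1 2"), p)
  expect_error(readAsciiGrid(p), "ragged")

  writeLines(c("ncols 1", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999", "9"), p)
  expect_error(readAsciiGrid(p), "legend")
})
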