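test_that("Berger-Parker proportions and classes follow the threshold rule", {
  r <- bergerParker(c(A = 50, B = 50))
  expect_equal(r$proportion, c(0.5, 0.5))
  expect_equal(r$class, c("dominant", "dominant"))

  r <- bergerParker(c(A = 1, B = 999))
  expect_equal(r$proportion[r$species == "A"], 0.001)
  expect_equal(r$class[r$species == "A"], "occasional")

  # boundary I = 0.1 exactly: the stronger (>=) rule wins -> dominant
  r <- bergerParker(c(A = 10, B = 90))
  expect_equal(r$proportion[r$species == "A"], 0.1)
  expect_equal(r$class[r$species == "A"], "dominant")

  expect_equal(sum(bergerParker(c(3, 9, 88, 400))$proportion), 1,
               tolerance = 1e-12)
  expect_error(bergerParker(c(A = 0, B = 0)), "empty group")
})

test_that("scalar indices match their closed-form worked examples", {
  expect_equal(shannonIndex(c(10, 10)), log(2), tolerance = 1e-12)
  expect_equal(shannonIndex(7), 0)
  expect_equal(shannonIndex(c(5, 3, 2)), 1.029653, tolerance = 1e-6)

  expect_equal(pielouEvenness(c(10, 10)), 1, tolerance = 1e-12)
  expect_equal(pielouEvenness(c(5, 3, 2)), 1.029653 / log(3),
               tolerance = 1e-6)
  expect_true(is.na(pielouEvenness(7)))

  expect_equal(simpsonIndex(c(10, 10)), 0.5, tolerance = 1e-12)
  expect_equal(simpsonIndex(7), 1)
  expect_equal(simpsonIndex(c(5, 3, 2)), 0.38, tolerance = 1e-12)
})

test_that("G and F indices match hand-computed taxonomic entropies", {
  mk <- function(genus, family) {
    n <- length(genus)
    Checklist(data.frame(
      species = paste0("Sp s", seq_len(n)), genus = genus, family = family,
      order = "Ord", guild = "none", iucn_status = "LC", protected = FALSE))
  }
  # all species in one genus -> 0
  expect_equal(gIndex(mk(rep("Ga", 3), rep("Fa", 3))), 0)
  # two genera with 2 + 2 species -> ln 2
  expect_equal(gIndex(mk(c("Ga", "Ga", "Gb", "Gb"), rep("Fa", 4))), log(2),
               tolerance = 1e-12)
  # genera sizes (3, 1) -> -(0.75 ln 0.75 + 0.25 ln 0.25)
  expect_equal(gIndex(mk(c("Ga", "Ga", "Ga", "Gb"), rep("Fa", 4))),
               0.562335, tolerance = 1e-6)

  # monotypic family contributes 0
  expect_equal(fIndex(mk("Ga", "Fa")), 0)
  expect_equal(fIndex(mk(c("Ga", "Ga", "Gb", "Gb"), rep("Fa", 4))), log(2),
               tolerance = 1e-12)
  # (2,2)-family plus a monotypic family -> ln 2 total
  expect_equal(fIndex(mk(c("Ga", "Ga", "Gb", "Gb", "Gc"),
                         c(rep("Fa", 4), "Fb"))), log(2), tolerance = 1e-12)
})

test_that("G-F index handles direct, undefined and out-of-range cases", {
  expect_equal(gfIndex(0.5, 1.0), 0.5)
  expect_equal(gfIndex(0.7, 0.7), 0)
  und <- gfIndex(0.3, 0)
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
  oor <- gfIndex(1.2, 0.6)
  expect_equal(as.numeric(oor), -1)
  expect_true(attr(oor, "outOfRange"))
  expect_error(gfIndex(-0.1, 1), "non-negative")
})

test_that("indices agree with vegan on random communities", {
  skip_if_not_installed("vegan")
  set.seed(5)
  for (i in 1:25) {
    x <- sample(1:100, sample(2:12, 1), replace = TRUE)
    expect_equal(shannonIndex(x), unname(vegan::diversity(x, "shannon")),
                 tolerance = 1e-12)
    expect_equal(simpsonIndex(x),
                 1 - unname(vegan::diversity(x, "simpson")),
                 tolerance = 1e-12)
  }
})

test_that("index invariants hold over random communities", {
  set.seed(42)
  for (i in 1:200) {
    s <- sample(2:12, 1)
    x <- sample(1:100, s, replace = TRUE)
    h <- shannonIndex(x); c0 <- simpsonIndex(x); e <- pielouEvenness(x)
    expect_lte(h, log(s) + 1e-12)
    expect_gte(c0, 1 / s - 1e-12); expect_lte(c0, 1)
    expect_gte(e, 0); expect_lte(e, 1 + 1e-12)
    # permutation invariance
    p <- sample(s)
    expect_equal(shannonIndex(x[p]), h, tolerance = 1e-12)
    expect_equal(simpsonIndex(x[p]), c0, tolerance = 1e-12)
    # scale invariance
    k <- sample(2:9, 1)
    expect_equal(shannonIndex(x * k), h, tolerance = 1e-12)
    expect_equal(simpsonIndex(x * k), c0, tolerance = 1e-12)
    expect_equal(pielouEvenness(x * k), e, tolerance = 1e-12)
  }
})

test_that("transfers from rarer to commoner species never increase H", {
  set.seed(7)
  for (i in 1:100) {
    x <- sample(1:100, sample(3:10, 1), replace = TRUE)
    h0 <- shannonIndex(x)
    lo <- which.min(x); hi <- which.max(x)
    if (x[lo] == x[hi]) next
    x[lo] <- x[lo] - 1L; x[hi] <- x[hi] + 1L
    expect_lte(shannonIndex(x[x > 0]), h0 + 1e-12)
  }
})

test_that("diversityTable composes the scalar indices per group", {
  # single group, 2 species in different genera and families
  df <- data.frame(year = 2020L, site_id = "s", habitat = "water",
                   species = c("Anas acuta", "Tringa totanus"),
                   count = c(10L, 10L), water_level_m = 1)
  cl <- Checklist(smallTaxa())
  dt <- diversityTable(buildCommunityMatrix(SurveyTable(df)), cl)
  expect_equal(dt$H, log(2), tolerance = 1e-12)
  expect_equal(dt$E, 1)
  expect_equal(dt$C, 0.5)
  expect_equal(dt$DG, log(2), tolerance = 1e-12)
  expect_equal(dt$DF, 0)
  expect_true(dt$gfUndefined)
  expect_true(is.na(dt$DGF))

  # per-group results equal independent scalar calls on each row
  cl45 <- exampleChecklist()
  sv <- generateSurveys(cl45, 2018:2020, 10, truth = defaultTruth(seed = 9))
  cm <- buildCommunityMatrix(sv, by = c("year", "habitat"))
  dt <- diversityTable(cm, cl45)
  m <- abundanceMatrix(cm)
  for (i in sample(nrow(dt), 5)) {
    x <- m[i, ]; x <- x[x > 0]
    expect_equal(dt$H[i], shannonIndex(x), tolerance = 1e-12)
    expect_equal(dt$C[i], simpsonIndex(x), tolerance = 1e-12)
    sub <- Checklist(taxa(cl45)[taxa(cl45)$species %in% names(x), ])
    expect_equal(dt$DG[i], gIndex(sub), tolerance = 1e-12)
    expect_equal(dt$DF[i], fIndex(sub), tolerance = 1e-12)
  }
  expect_true(all(dt$H <= log(dt$S) + 1e-12))
})
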