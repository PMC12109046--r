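test_that("transition cross-tabulation counts cells exactly", {
  g <- randomGrid(8, 8, seed = 1)
  m <- crosstabTransitions(g, g)
  expect_equal(unname(transitionProbabilities(m)), diag(5))

  # hand enumeration on a 2-cell grid: water->crops, crops->crops
  g0 <- LandCoverGrid(matrix(c(3L, 1L), 2, 1))
  g1 <- LandCoverGrid(matrix(c(1L, 1L), 2, 1))
  m <- crosstabTransitions(g0, g1)
  expect_equal(transitionCounts(m)["water", "crops"], 1L)
  expect_equal(transitionCounts(m)["crops", "crops"], 1L)

  # full-enumeration oracle on a random pair with NODATA
  a <- randomGrid(100, 100, seed = 2, nodataFrac = 0.05)
  b <- randomGrid(100, 100, seed = 3, nodataFrac = 0.05)
  m <- crosstabTransitions(a, b)
  ok <- !is.na(gridCodes(a)) & !is.na(gridCodes(b))
  expect_equal(sum(transitionCounts(m)), sum(ok))
  for (i in 1:5) for (j in 1:5)
    expect_equal(unname(transitionCounts(m)[i, j]),
                 sum(gridCodes(a)[ok] == i & gridCodes(b)[ok] == j))
  expect_equal(unname(rowSums(transitionProbabilities(m))), rep(1, 5),
               tolerance = 1e-12)

  expect_error(crosstabTransitions(a, randomGrid(50, 50, seed = 4)),
               "dimensions")
})

test_that("scenarios modify rows as documented", {
  tm <- TransitionModel(defaultTransitionMatrix())
  expect_identical(applyScenario(tm, "business_as_usual"), tm)
  expect_equal(transitionProbabilities(applyScenario(tm, "restoration",
                                                     boost = 1)),
               transitionProbabilities(tm), tolerance = 1e-12)

  # hand renormalisation: (0.5 crops, 0.25 water, 0.25 flooded), boost 2
  p <- matrix(0, 5, 5, dimnames = list(habitatClasses(), habitatClasses()))
  diag(p) <- 1
  p["crops", ] <- c(0.5, 0.25, 0.25, 0, 0)
  m2 <- applyScenario(TransitionModel(p), "restoration", boost = 2)
  expect_equal(unname(transitionProbabilities(m2)["crops", 1:3]),
               rep(1 / 3, 3), tolerance = 1e-12)
  expect_error(applyScenario(tm, "restoration", boost = -1), "boost")
})

test_that("area projection matches matrix-power and eigenvector oracles", {
  tm <- TransitionModel(defaultTransitionMatrix())
  a0 <- setNames(c(30, 25, 20, 15, 10), habitatClasses())

  # identity model -> constant trajectory
  idm <- TransitionModel(
    matrix(diag(5), 5, 5, dimnames = list(habitatClasses(),
                                          habitatClasses())))
  tr <- projectAreas(idm, a0, nSteps = 3)
  for (i in 2:4) expect_equal(unname(tr[i, ]), unname(a0))

  # two steps equal one application of P^2
  tr <- projectAreas(tm, a0, nSteps = 2, baseYear = 2020)
  p2 <- defaultTransitionMatrix() %*% defaultTransitionMatrix()
  expect_equal(unname(tr[3, ]), unname(as.numeric(a0 %*% p2)),
               tolerance = 1e-12)
  expect_equal(rownames(tr), c("2020", "2030", "2040"))

  # area conservation at every horizon
  expect_equal(unname(rowSums(tr)), rep(sum(a0), 3), tolerance = 1e-9)

  # long-run limit matches the stationary left eigenvector
  tr <- projectAreas(tm, a0, nSteps = 100)
  ev <- eigen(t(defaultTransitionMatrix()))
  k <- which.min(abs(ev$values - 1))
  st <- Re(ev$vectors[, k]); st <- st / sum(st) * sum(a0)
  expect_equal(unname(tr[101, ]), st, tolerance = 1e-6)

  expect_error(projectAreas(tm, -a0, 1), "negative")
})

test_that("quota allocation is exact, conservative and convergent", {
  # identity model returns the input
  idm <- TransitionModel(
    matrix(diag(5), 5, 5, dimnames = list(habitatClasses(),
                                          habitatClasses())))
  g <- randomGrid(20, 20, seed = 5, nodataFrac = 0.05)
  expect_identical(gridCodes(allocateMap(g, idm)), gridCodes(g))

  # single-class 4-cell grid, P(crops) = (0.5, 0.5, 0, 0, 0)
  p <- matrix(0, 5, 5, dimnames = list(habitatClasses(), habitatClasses()))
  diag(p) <- 1
  p["crops", ] <- c(0.5, 0.5, 0, 0, 0)
  out <- allocateMap(LandCoverGrid(matrix(1L, 2, 2)), TransitionModel(p))
  expect_equal(sum(gridCodes(out) == 2L), 2)
  expect_equal(sum(gridCodes(out) == 1L), 2)

  # per-class output counts equal an independent quota computation
  set.seed(9)
  for (rep in 1:3) {
    g <- randomGrid(40, 40, seed = 20 + rep)
    tm <- TransitionModel(defaultTransitionMatrix())
    out <- allocateMap(g, tm)
    expected <- rep(0, 5)
    for (i in 1:5) {
      ni <- sum(gridCodes(g) == i)
      q <- floor(ni * defaultTransitionMatrix()[i, ])
      rem <- ni * defaultTransitionMatrix()[i, ] - q
      short <- ni - sum(q)
      if (short > 0) {
        ord <- order(rem, decreasing = TRUE)
        q[ord[seq_len(short)]] <- q[ord[seq_len(short)]] + 1
      }
      expected <- expected + q
    }
    got <- vapply(1:5, function(k) sum(gridCodes(out) == k), numeric(1))
    expect_equal(got, unname(expected))
    expect_equal(sum(!is.na(gridCodes(out))), sum(!is.na(gridCodes(g))))
  }

  # empirical transition frequencies approach P on a large grid
  g <- randomGrid(200, 200, seed = 31)
  tm <- TransitionModel(defaultTransitionMatrix())
  est <- transitionProbabilities(crosstabTransitions(g, allocateMap(g, tm)))
  expect_lt(max(abs(est - defaultTransitionMatrix())), 0.02)

  # suitability steers which cells convert first
  g <- LandCoverGrid(matrix(1L, 1, 4))
  suit <- matrix(c(4, 3, 2, 1), 1, 4)
  out <- allocateMap(g, TransitionModel(p), suitability = suit)
  expect_equal(as.integer(gridCodes(out)), c(1L, 1L, 2L, 2L))
  expect_error(allocateMap(g, TransitionModel(p),
                           suitability = matrix(1, 2, 2)), "shape")
})

test_that("confusion metrics match the kappa formula oracle", {
  g <- randomGrid(10, 10, seed = 6)
  perfect <- confusionMetrics(g, g)
  expect_equal(perfect$overallAccuracy, 1)
  expect_equal(perfect$kappa, 1)

  # balanced 2-class worked case [[45,5],[5,45]]: p_o 0.9, p_e 0.5
  ref <- LandCoverGrid(matrix(rep(c(1L, 2L), each = 50), 10, 10))
  pred <- ref
  codes <- gridCodes(pred)
  codes[1:5] <- 2L          # 5 of class 1 predicted as 2
  codes[51:55] <- 1L        # 5 of class 2 predicted as 1
  pred <- LandCoverGrid(codes)
  cm <- confusionMetrics(ref, pred)
  expect_equal(cm$overallAccuracy, 0.9)
  expect_equal(cm$kappa, 0.8, tolerance = 1e-12)

  # constant prediction vs 50/50 reference -> kappa 0
  pred0 <- LandCoverGrid(matrix(1L, 10, 10))
  cm <- confusionMetrics(ref, pred0)
  expect_equal(cm$kappa, 0)

  # kappa <= accuracy; undefined when both maps are constant and equal
  skip_if_not_installed("e1071")
  for (s in 1:5) {
    a <- randomGrid(30, 30, seed = 40 + s)
    b <- randomGrid(30, 30, seed = 50 + s)
    cm <- confusionMetrics(a, b)
    expect_lte(cm$kappa, cm$overallAccuracy + 1e-12)
    expect_equal(cm$kappa, e1071::classAgreement(cm$matrix)$kappa,
                 tolerance = 1e-9)
  }
  cst <- LandCoverGrid(matrix(2L, 4, 4))
  cm <- confusionMetrics(cst, cst)
  expect_true(cm$kappaUndefined)
  expect_true(is.na(cm$kappa))
})
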