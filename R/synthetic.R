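# Synthetic-data generator: checklists, survey tables and land-cover raster
# series with known ground truth for parameter-recovery testing.

#' Default ground truth for the synthetic wetland
#'
#' The "restored-wetland" preset emulated by the generator: four foraging
#' guilds with distinct water-level optima (dabbling 1.2 m, small waders
#' 1.0 m, diving birds 2.5 m, large waders 2.4 m) and a common Gaussian
#' response breadth; flooded vegetation the most attractive habitat; a
#' sevenfold expected increase in total abundance between the first and
#' last survey years; and a decadal land-cover transition matrix in which
#' bare ground converts mainly to flooded vegetation and water
#' (restoration-like dynamics).
#'
#' @param seed integer RNG seed; drives every stochastic draw derived from
#'   this truth.
#' @param guildOptima,guildBreadth named numeric per guild (metres).
#' @param optimumJitterSd SD (m) of the per-species deviation from its
#'   guild optimum; gives guild members individual depth niches so that
#'   community composition, not just abundance, shifts along the gradient.
#' @param habitatWeights named numeric, relative habitat attraction.
#' @param trendFactor expected last-year / first-year total abundance.
#' @param transitionMatrix 5 x 5 row-stochastic matrix over
#'   `habitatClasses()`.
#' @param baseAbundance expected individuals per species per survey before
#'   habitat, water-level and trend modifiers.
#' @param waterRange numeric length 2, water-level range (m) spanned by the
#'   survey sites.
#' @return a [SyntheticTruth-class].
#' @examples
#' truth <- defaultTruth(seed = 42)
#' truth
#' @export
defaultTruth <- function(seed = 1L,
                         guildOptima = c(dabbling = 1.2, diving = 2.5,
                                         large_wader = 2.4, small_wader = 1.0),
                         guildBreadth = c(dabbling = 0.4, diving = 0.4,
                                          large_wader = 0.4, small_wader = 0.4),
                         optimumJitterSd = 0.2,
                         habitatWeights = c(crops = 0.10,
                                            flooded_vegetation = 0.40,
                                            water = 0.25, range_land = 0.18,
                                            bare_ground = 0.07),
                         trendFactor = 7,
                         transitionMatrix = defaultTransitionMatrix(),
                         baseAbundance = 12,
                         waterRange = c(0.2, 3.2)) {
  new("SyntheticTruth", seed = as.integer(seed), guildOptima = guildOptima,
      guildBreadth = guildBreadth, optimumJitterSd = optimumJitterSd,
      habitatWeights = habitatWeights, trendFactor = trendFactor,
      transitionMatrix = transitionMatrix, baseAbundance = baseAbundance,
      waterRange = waterRange)
}

#' @rdname defaultTruth
#' @return `defaultTransitionMatrix()`: the preset 5 x 5 decadal transition
#'   matrix (rows and columns ordered as `habitatClasses()`).
#' @export
defaultTransitionMatrix <- function() {
  m <- matrix(c(0.85, 0.05, 0.02, 0.05, 0.03,
                0.05, 0.80, 0.10, 0.03, 0.02,
                0.02, 0.08, 0.88, 0.01, 0.01,
                0.10, 0.08, 0.04, 0.75, 0.03,
                0.05, 0.25, 0.15, 0.10, 0.45),
              nrow = 5, byrow = TRUE,
              dimnames = list(HABITAT_CLASSES, HABITAT_CLASSES))
  m
}

#' @rdname SyntheticTruth-class
#' @param object a SyntheticTruth.
#' @export
setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth (seed", object@seed, ")\n")
  cat("guild optima (m):",
      paste(sprintf("%s=%.2f", names(object@guildOptima), object@guildOptima),
            collapse = " "), "\n")
  cat(sprintf("trend factor %.2f | base abundance %.1f | water range %.1f-%.1f m\n",
              object@trendFactor, object@baseAbundance,
              object@waterRange[1], object@waterRange[2]))
})

#' Generate a synthetic checklist with an exact taxonomic shape
#'
#' Builds a checklist with exactly the requested numbers of species,
#' genera, families and orders (the default mirrors a rich South-East Asian
#' wetland checklist: 45 species, 38 genera, 20 families, 11 orders). The
#' hierarchy is proper by construction: genera are partitioned over
#' families and families over orders, every level non-empty. Guilds are
#' apportioned by `guildMix` via largest-remainder rounding; a small number
#' of species receive threatened IUCN categories (about 15% across EN, VU
#' and NT) and roughly a quarter carry the protected-area flag. Output is
#' deterministic given `seed`.
#'
#' @param nSpecies,nGenera,nFamilies,nOrders requested distinct-value
#'   counts; must satisfy `nSpecies >= nGenera >= nFamilies >= nOrders >= 1`.
#' @param guildMix named numeric proportions over `guildLevels()`.
#' @param seed integer RNG seed.
#' @return list with elements `checklist` (a [Checklist-class]) and `truth`
#'   (a [SyntheticTruth-class] seeded with `seed`).
#' @examples
#' sim <- generateChecklist(seed = 42)
#' nGenera(sim$checklist)  # 38
#' @export
generateChecklist <- function(nSpecies = 45, nGenera = 38, nFamilies = 20,
                              nOrders = 11,
                              guildMix = c(dabbling = 7, diving = 3,
                                           large_wader = 10, small_wader = 8,
                                           none = 17),
                              seed = 1L) {
  .stopIfNot(nSpecies >= nGenera && nGenera >= nFamilies &&
               nFamilies >= nOrders && nOrders >= 1,
             "counts must satisfy nSpecies >= nGenera >= nFamilies >= nOrders >= 1")
  badMix <- setdiff(names(guildMix), GUILD_LEVELS)
  .stopIfNot(!length(badMix),
             paste("unknown guild in guildMix:", paste(badMix, collapse = ", ")))
  set.seed(seed)

  # surjective parent assignment: each parent receives at least one child
  assignParents <- function(nChild, nParent) {
    extra <- if (nChild > nParent)
      sample.int(nParent, nChild - nParent, replace = TRUE) else integer()
    p <- c(seq_len(nParent), extra)
    p[sample.int(nChild)]
  }
  famOrder <- assignParents(nFamilies, nOrders)
  genFamily <- assignParents(nGenera, nFamilies)
  spGenus <- assignParents(nSpecies, nGenera)

  guildCounts <- largestRemainder(guildMix, nSpecies)
  guild <- sample(rep(names(guildMix), guildCounts))

  nThreat <- largestRemainder(c(EN = 2, VU = 3, NT = 2),
                              max(0L, round(0.156 * nSpecies)))
  iucn <- rep("LC", nSpecies)
  flagged <- sample.int(nSpecies, sum(nThreat))
  iucn[flagged] <- rep(names(nThreat), nThreat)
  protected <- rep(FALSE, nSpecies)
  protected[sample.int(nSpecies, round(0.25 * nSpecies))] <- TRUE

  taxa <- data.frame(
    species = sprintf("Genus%02d sp%03d", spGenus, seq_len(nSpecies)),
    genus = sprintf("Genus%02d", spGenus),
    family = sprintf("Family%02d", genFamily[spGenus]),
    order = sprintf("Order%02d", famOrder[genFamily[spGenus]]),
    guild = guild, iucn_status = iucn, protected = protected,
    stringsAsFactors = FALSE)
  list(checklist = Checklist(taxa), truth = defaultTruth(seed = seed))
}

# flock-size quantisation tiers: point counts below 50 are exact; larger
# congregations are estimated in groups of 10 (50-199), 20 (200-499) or
# 50 (>= 500), rounding half up
quantizeFlock <- function(count) {
  g <- ifelse(count >= 500, 50L, ifelse(count >= 200, 20L,
                                        ifelse(count >= 50, 10L, 1L)))
  as.integer(floor(count / g + 0.5) * g)
}

#' Generate synthetic survey records
#'
#' Simulates point-count surveys over a year x site design. Each site has a
#' fixed habitat (cycled over `habitats`) and a characteristic water depth
#' along an even gradient spanning `truth@waterRange`, perturbed by yearly
#' and site-year hydrological noise. The expected count of species `s` at
#' water level `w` in year `y` and habitat `h` is
#' \deqn{\lambda = \mathrm{base} \times w_h \times
#'   \exp\{-(w - o_s)^2 / (2 b_g^2)\} \times f^{(y - y_1)/(y_Y - y_1)}}
#' where \eqn{o_s} is the species' depth optimum (its guild optimum plus a
#' per-species jitter), \eqn{b_g} the guild breadth, \eqn{w_h} the habitat
#' weight and \eqn{f} the trend factor; guild-less species take no water
#' term. Counts are Poisson draws; zero-count records are omitted (surveys
#' record detections). With `flockQuantize = TRUE`, counts are reported at
#' the flock-estimation granularity (nearest 10 for 50-199, 20 for 200-499,
#' 50 for 500+). Deterministic given `truth@seed`.
#'
#' @param checklist a [Checklist-class] (non-empty).
#' @param years integer vector of survey years.
#' @param nSites number of survey sites.
#' @param truth a [SyntheticTruth-class].
#' @param flockQuantize logical, apply flock-size quantisation.
#' @param habitats habitat classes cycled over sites.
#' @return a [SurveyTable-class].
#' @examples
#' sim <- generateChecklist(seed = 42)
#' sv <- generateSurveys(sim$checklist, years = 2014:2023, nSites = 20,
#'                       truth = sim$truth)
#' sv
#' @export
generateSurveys <- function(checklist, years, nSites = 20,
                            truth = defaultTruth(), flockQuantize = FALSE,
                            habitats = habitatClasses()) {
  stopifnot(is(checklist, "Checklist"), is(truth, "SyntheticTruth"))
  .stopIfNot(length(years) >= 1, "'years' must be non-empty")
  .stopIfNot(nSpecies(checklist) >= 1, "empty checklist")
  years <- sort(unique(as.integer(years)))
  set.seed(truth@seed + 1L)

  t <- checklist@taxa
  nSp <- nrow(t)
  wmin <- truth@waterRange[1]; wmax <- truth@waterRange[2]

  siteHab <- rep(habitats, length.out = nSites)
  siteBase <- wmin + ((seq_len(nSites) - 0.5) / nSites) * (wmax - wmin)

  hasGuild <- t$guild %in% names(truth@guildOptima)
  spOpt <- rep(NA_real_, nSp)
  # per-species depth niches spread around the guild optimum; centred within
  # each guild so the guild optimum is exactly the mean of its members
  jit <- rnorm(sum(hasGuild), 0, truth@optimumJitterSd)
  jit <- unsplit(lapply(split(jit, t$guild[hasGuild]),
                        function(j) j - mean(j)), t$guild[hasGuild])
  spOpt[hasGuild] <- truth@guildOptima[t$guild[hasGuild]] + jit
  spBreadth <- rep(NA_real_, nSp)
  spBreadth[hasGuild] <- truth@guildBreadth[t$guild[hasGuild]]

  nY <- length(years)
  span <- if (nY > 1) years[nY] - years[1] else 1
  trend <- truth@trendFactor^((years - years[1]) / span)
  yearEffect <- rnorm(nY, 0, 0.10)
  diversion <- if (nY > 1) seq(15, 12, length.out = nY) else 15

  # design rows: year-major, site within year
  yearIdx <- rep(seq_len(nY), each = nSites)
  siteIdx <- rep(seq_len(nSites), times = nY)
  w <- siteBase[siteIdx] + yearEffect[yearIdx] +
    rnorm(length(siteIdx), 0, 0.10)
  w <- pmin(pmax(w, wmin), wmax)

  # lambda matrix: (year-site rows) x species
  waterTerm <- outer(w, seq_len(nSp), function(wi, si) {
    ifelse(is.na(spOpt[si]), 1,
           exp(-(wi - spOpt[si])^2 / (2 * spBreadth[si]^2)))
  })
  lambda <- truth@baseAbundance *
    truth@habitatWeights[siteHab[siteIdx]] *
    trend[yearIdx] * waterTerm
  counts <- matrix(rpois(length(lambda), lambda), nrow = length(w))

  rec <- data.frame(
    year = rep(years[yearIdx], nSp),
    site_id = rep(sprintf("site_%02d", siteIdx), nSp),
    habitat = rep(siteHab[siteIdx], nSp),
    species = rep(t$species, each = length(w)),
    count = as.integer(counts),
    water_level_m = rep(round(w, 3), nSp),
    water_diversion_Mm3 = rep(round(diversion[yearIdx], 2), nSp),
    stringsAsFactors = FALSE)
  rec <- rec[rec$count > 0, , drop = FALSE]
  if (flockQuantize) rec$count <- quantizeFlock(rec$count)
  rec <- rec[order(rec$year, rec$site_id, rec$species), , drop = FALSE]
  rownames(rec) <- NULL
  new("SurveyTable", records = rec)
}

#' Generate a synthetic land-cover raster series
#'
#' Draws an initial categorical grid with cell classes sampled i.i.d. from
#' `initialProportions`, then advances it `nSteps` times: at each step
#' every cell independently transitions to a class drawn from its current
#' class's row of `transitionMatrix`. Cell count is conserved across the
#' series, and with an identity matrix the series is constant.
#' Deterministic given `seed`.
#'
#' @param nrows,ncols grid dimensions.
#' @param initialProportions length-5 proportions over `habitatClasses()`
#'   (must sum to 1).
#' @param transitionMatrix 5 x 5 row-stochastic matrix.
#' @param nSteps number of transition steps (`>= 0`).
#' @param seed integer RNG seed.
#' @param legend code -> class-name legend.
#' @param cellArea per-cell area.
#' @param startYear year attached to the first grid.
#' @param stepSpanYears years per step (default 10, a decadal interval).
#' @return list of `nSteps + 1` [LandCoverGrid-class] objects.
#' @examples
#' ser <- generateLandcoverSeries(20, 20,
#'   initialProportions = rep(0.2, 5),
#'   transitionMatrix = defaultTransitionMatrix(), nSteps = 1, seed = 7)
#' classAreas(ser[[2]])
#' @export
generateLandcoverSeries <- function(nrows, ncols,
                                    initialProportions = rep(0.2, 5),
                                    transitionMatrix = defaultTransitionMatrix(),
                                    nSteps = 1, seed = 1L,
                                    legend = defaultLegend(), cellArea = 1,
                                    startYear = 2010L, stepSpanYears = 10L) {
  k <- length(legend)
  .stopIfNot(length(initialProportions) == k &&
               abs(sum(initialProportions) - 1) < 1e-9,
             "initialProportions must match the legend and sum to 1")
  .stopIfNot(is.matrix(transitionMatrix) &&
               all(dim(transitionMatrix) == k) &&
               all(transitionMatrix >= 0) &&
               all(abs(rowSums(transitionMatrix) - 1) < 1e-9),
             "transitionMatrix must be row-stochastic over the legend")
  .stopIfNot(nSteps >= 0, "nSteps must be >= 0")
  set.seed(seed)
  codes <- as.integer(names(legend))
  g <- matrix(sample(codes, nrows * ncols, replace = TRUE,
                     prob = initialProportions), nrows, ncols)
  out <- vector("list", nSteps + 1)
  out[[1]] <- LandCoverGrid(g, legend = legend, cellArea = cellArea,
                            year = startYear)
  if (nSteps > 0) for (s in seq_len(nSteps)) {
    gNew <- g
    for (i in seq_len(k)) {
      idx <- which(g == codes[i])
      if (length(idx))
        gNew[idx] <- codes[sample.int(k, length(idx), replace = TRUE,
                                      prob = transitionMatrix[i, ])]
    }
    g <- gNew
    out[[s + 1]] <- LandCoverGrid(g, legend = legend, cellArea = cellArea,
                                  year = startYear + s * stepSpanYears)
  }
  out
}
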