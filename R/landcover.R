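# Markov land-cover change model: calibration, scenarios, projection,
# spatial allocation and accuracy assessment.

#' Calibrate a transition model from a raster pair
#'
#' Cross-tabulates cell classes between two co-registered categorical
#' rasters: `counts[i, j]` is the number of cells in class `i` at the first
#' date and class `j` at the second. Probabilities are row-normalised
#' counts; classes never observed as a source default to self-transition
#' (absorbing), the least-surprising prior for unobserved classes. Cells
#' that are NODATA in either raster are excluded pairwise.
#'
#' @param grid0,grid1 [LandCoverGrid-class] objects with identical
#'   dimensions and legend.
#' @param stepSpanYears years between the two dates; taken from the grids'
#'   `year` slots when both are set.
#' @return a [TransitionModel-class].
#' @examples
#' g <- LandCoverGrid(matrix(c(3L, 1L), 2, 1))
#' m <- crosstabTransitions(g, LandCoverGrid(matrix(c(1L, 1L), 2, 1)))
#' transitionCounts(m)["water", "crops"]  # 1
#' @export
crosstabTransitions <- function(grid0, grid1, stepSpanYears = 10L) {
  stopifnot(is(grid0, "LandCoverGrid"), is(grid1, "LandCoverGrid"))
  .stopIfNot(identical(dim(grid0@codes), dim(grid1@codes)),
             "raster dimensions differ")
  .stopIfNot(identical(grid0@legend, grid1@legend), "raster legends differ")
  if (!is.na(grid0@year) && !is.na(grid1@year) && grid1@year > grid0@year)
    stepSpanYears <- grid1@year - grid0@year
  codes <- as.integer(names(grid0@legend))
  ok <- !is.na(grid0@codes) & !is.na(grid1@codes)
  counts <- table(factor(grid0@codes[ok], levels = codes),
                  factor(grid1@codes[ok], levels = codes))
  counts <- matrix(as.integer(counts), length(codes), length(codes),
                   dimnames = list(unname(grid0@legend), unname(grid0@legend)))
  probs <- counts / pmax(rowSums(counts), 1)
  zero <- rowSums(counts) == 0
  if (any(zero)) probs[zero, ] <- diag(length(codes))[zero, , drop = FALSE]
  new("TransitionModel", counts = counts, probabilities = probs,
      stepSpanYears = as.integer(stepSpanYears),
      classes = unname(grid0@legend))
}

#' Construct a TransitionModel from a probability matrix
#'
#' @param probabilities row-stochastic matrix with class names on both
#'   dimensions.
#' @param stepSpanYears years per Markov step.
#' @return a [TransitionModel-class] (counts zeroed).
#' @export
TransitionModel <- function(probabilities, stepSpanYears = 10L) {
  cls <- rownames(probabilities)
  .stopIfNot(!is.null(cls) && identical(cls, colnames(probabilities)),
             "probability matrix needs matching row/column class names")
  counts <- matrix(0L, nrow(probabilities), ncol(probabilities),
                   dimnames = dimnames(probabilities))
  new("TransitionModel", counts = counts, probabilities = probabilities,
      stepSpanYears = as.integer(stepSpanYears), classes = cls)
}

#' @rdname accessors
#' @export
setMethod("transitionCounts", "TransitionModel", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("transitionProbabilities", "TransitionModel",
          function(x) x@probabilities)

#' @rdname TransitionModel-class
#' @param object a TransitionModel.
#' @export
setMethod("show", "TransitionModel", function(object) {
  cat(sprintf("TransitionModel: %d classes, %d calibration cells, %d-year step\n",
              length(object@classes), sum(object@counts),
              object@stepSpanYears))
  print(round(object@probabilities, 3))
})

#' Apply a management scenario to a transition model
#'
#' `business_as_usual` returns the calibrated model unchanged.
#' `restoration` multiplies every row's transition probabilities into the
#' wetland classes (`water` and `flooded_vegetation` by default) by
#' `boost` and renormalises each row, shifting dynamics toward wetland
#' recovery while preserving row-stochasticity. `boost = 1` is the
#' identity.
#'
#' @param model a [TransitionModel-class].
#' @param scenario `"business_as_usual"` or `"restoration"`.
#' @param boost multiplier (> 0) applied to wetland-class transitions under
#'   restoration.
#' @param wetlandClasses classes favoured by restoration.
#' @return a [TransitionModel-class].
#' @export
applyScenario <- function(model,
                          scenario = c("business_as_usual", "restoration"),
                          boost = 1.5,
                          wetlandClasses = c("water", "flooded_vegetation")) {
  stopifnot(is(model, "TransitionModel"))
  scenario <- match.arg(scenario)
  .stopIfNot(boost > 0, "boost must be > 0")
  if (scenario == "business_as_usual") return(model)
  .stopIfNot(all(wetlandClasses %in% model@classes),
             "wetland classes missing from the model legend")
  p <- model@probabilities
  p[, wetlandClasses] <- p[, wetlandClasses] * boost
  rs <- rowSums(p)
  .stopIfNot(all(rs > 0), "scenario left a degenerate all-zero row")
  p <- p / rs
  new("TransitionModel", counts = model@counts, probabilities = p,
      stepSpanYears = model@stepSpanYears, classes = model@classes)
}

#' Project class areas forward
#'
#' Advances an area vector through the Markov chain: \eqn{a_{t+1} = a_t P},
#' applied `nSteps` times. Each step spans the model's calibration interval
#' (a model calibrated on a 2010-2020 pair reaches 2030 in one step and
#' 2040 in two). Total area is conserved at every horizon.
#'
#' @param model a [TransitionModel-class].
#' @param initial named numeric of current class areas (names = model
#'   classes, all `>= 0`).
#' @param nSteps number of steps (`>= 0`).
#' @param baseYear year of the initial areas; horizon years are
#'   `baseYear + stepSpanYears * (0:nSteps)`.
#' @return numeric matrix, horizons x classes, rownames = horizon years.
#' @examples
#' m <- TransitionModel(defaultTransitionMatrix())
#' projectAreas(m, setNames(rep(20, 5), habitatClasses()), nSteps = 2,
#'              baseYear = 2020)
#' @export
projectAreas <- function(model, initial, nSteps = 2, baseYear = 2020L) {
  stopifnot(is(model, "TransitionModel"))
  .stopIfNot(nSteps >= 0, "nSteps must be >= 0")
  .stopIfNot(all(initial >= 0), "negative areas")
  .stopIfNot(!is.null(names(initial)) && setequal(names(initial), model@classes),
             "initial areas must be named by the model classes")
  a <- as.numeric(initial[model@classes])
  out <- matrix(NA_real_, nSteps + 1, length(a),
                dimnames = list(baseYear + model@stepSpanYears * (0:nSteps),
                                model@classes))
  out[1, ] <- a
  if (nSteps > 0) for (s in seq_len(nSteps)) {
    a <- as.numeric(a %*% model@probabilities)
    out[s + 1, ] <- a
  }
  out
}

#' Allocate a projected map by class quotas
#'
#' Spatial counterpart of [projectAreas()]: converts cells so that the
#' per-class transition counts match the model exactly. For each source
#' class `i`, target quotas are `largest-remainder` roundings of
#' `n_i * P[i, j]` (ties by class order), so cell count is conserved
#' exactly. Cells of class `i` are ranked by `suitability` (descending;
#' uniform or absent suitability ranks row-major) and assigned to target
#' classes in legend order along that ranking. Deterministic given its
#' inputs; `seed`, when supplied, randomises the ranking among
#' equal-suitability cells.
#'
#' @param grid a [LandCoverGrid-class].
#' @param model a [TransitionModel-class] over the grid's legend.
#' @param suitability optional numeric matrix, same shape as the grid;
#'   higher values convert first.
#' @param seed optional integer; breaks suitability ties randomly instead
#'   of row-major.
#' @return a [LandCoverGrid-class] one step ahead (NODATA preserved).
#' @export
allocateMap <- function(grid, model, suitability = NULL, seed = NULL) {
  stopifnot(is(grid, "LandCoverGrid"), is(model, "TransitionModel"))
  .stopIfNot(setequal(unname(grid@legend), model@classes),
             "grid legend and model classes differ")
  if (!is.null(suitability))
    .stopIfNot(identical(dim(suitability), dim(grid@codes)),
               "suitability grid shape mismatch")
  codes <- as.integer(names(grid@legend))
  classOfCode <- setNames(match(unname(grid@legend), model@classes),
                          names(grid@legend))
  g <- grid@codes
  out <- g
  nr <- nrow(g); nc <- ncol(g)
  # row-major rank of each cell (R stores column-major)
  cellRow <- row(g); cellCol <- col(g)
  rowMajor <- (cellRow - 1) * nc + cellCol
  if (!is.null(seed)) {
    set.seed(seed)
    tieBreak <- sample.int(length(g))
  } else tieBreak <- rowMajor
  p <- model@probabilities
  for (ci in seq_along(codes)) {
    idx <- which(!is.na(g) & g == codes[ci])
    if (!length(idx)) next
    i <- classOfCode[ci]
    quota <- largestRemainder(p[i, ], length(idx))
    if (is.null(suitability)) {
      ord <- idx[order(rowMajor[idx])]
    } else {
      ord <- idx[order(-suitability[idx], tieBreak[idx])]
    }
    targets <- rep(seq_along(codes), quota)   # legend order along ranking
    out[ord] <- codes[match(model@classes[targets], unname(grid@legend))]
  }
  LandCoverGrid(out, legend = grid@legend, cellArea = grid@cellArea,
                year = if (is.na(grid@year)) NA_integer_ else
                  grid@year + model@stepSpanYears,
                xll = grid@xll, yll = grid@yll, cellsize = grid@cellsize)
}

#' Confusion matrix, overall accuracy and Cohen's kappa
#'
#' Cross-tabulates a predicted categorical map against a reference map and
#' reports overall accuracy (trace over total) and Cohen's kappa,
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with the expected agreement
#' \eqn{p_e} from the marginal products. When \eqn{p_e = 1} (both maps
#' constant and equal) kappa is undefined and returned as flagged `NA`.
#'
#' @param reference,predicted [LandCoverGrid-class] objects with identical
#'   shape and legend.
#' @return list with `matrix` (reference rows x predicted columns),
#'   `overallAccuracy`, `kappa`, `kappaUndefined`.
#' @examples
#' g <- LandCoverGrid(matrix(c(1L, 2L), 2, 2))
#' confusionMetrics(g, g)$kappa  # 1
#' @export
confusionMetrics <- function(reference, predicted) {
  stopifnot(is(reference, "LandCoverGrid"), is(predicted, "LandCoverGrid"))
  .stopIfNot(identical(dim(reference@codes), dim(predicted@codes)),
             "raster dimensions differ")
  .stopIfNot(identical(reference@legend, predicted@legend),
             "raster legends differ")
  codes <- as.integer(names(reference@legend))
  ok <- !is.na(reference@codes) & !is.na(predicted@codes)
  m <- table(factor(reference@codes[ok], levels = codes),
             factor(predicted@codes[ok], levels = codes))
  m <- matrix(as.integer(m), length(codes), length(codes),
              dimnames = list(unname(reference@legend),
                              unname(reference@legend)))
  n <- sum(m)
  .stopIfNot(n > 0, "no overlapping data cells")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  undefined <- abs(1 - pe) < 1e-12
  kappa <- if (undefined) NA_real_ else (po - pe) / (1 - pe)
  list(matrix = m, overallAccuracy = po, kappa = kappa,
       kappaUndefined = undefined)
}
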