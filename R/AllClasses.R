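HABITAT_CLASSES <- c("crops", "flooded_vegetation", "water", "range_land",
                     "bare_ground")
GUILD_LEVELS <- c("dabbling", "diving", "large_wader", "small_wader", "none")
IUCN_CODES <- c("CR", "EN", "VU", "NT", "LC", "DD")
CHECKLIST_COLUMNS <- c("species", "genus", "family", "order", "guild",
                       "iucn_status", "protected")
SURVEY_COLUMNS <- c("year", "site_id", "habitat", "species", "count",
                    "water_level_m")

#' The five-class wetland habitat legend
#'
#' Habitat / land-cover classes used throughout the package: crops, flooded
#' vegetation, open water, range land and bare ground. Survey records and
#' land-cover rasters are validated against this legend unless a custom one
#' is supplied.
#'
#' @return `habitatClasses()`: character vector of the five class names.
#' @examples
#' habitatClasses()
#' defaultLegend()
#' @export
habitatClasses <- function() HABITAT_CLASSES

#' @rdname habitatClasses
#' @return `defaultLegend()`: named character vector mapping integer raster
#'   codes `1:5` to the five class names.
#' @export
defaultLegend <- function() setNames(HABITAT_CLASSES, as.character(1:5))

#' @rdname habitatClasses
#' @return `guildLevels()`: the four waterbird foraging guilds (dabbling
#'   birds, diving birds, large waders, small waders) plus `"none"` for
#'   species outside the guild system.
#' @export
guildLevels <- function() GUILD_LEVELS

#' @rdname habitatClasses
#' @return `iucnCategories()`: the IUCN Red List category codes carried on a
#'   checklist (CR, EN, VU, NT, LC, DD).
#' @export
iucnCategories <- function() IUCN_CODES

#' Checklist: a validated waterbird taxonomic checklist
#'
#' S4 container for a species checklist with its taxonomic hierarchy
#' (species, genus, family, order), foraging guild and conservation status
#' (IUCN category plus a protected-area designation flag). Validity enforces
#' unique species names and a proper hierarchy: each genus belongs to
#' exactly one family and each family to exactly one order.
#'
#' @slot taxa data.frame with columns `species`, `genus`, `family`, `order`,
#'   `guild`, `iucn_status`, `protected`.
#' @seealso [Checklist()], [readChecklist()], [nSpecies()]
#' @export
setClass("Checklist", slots = c(taxa = "data.frame"))

setValidity("Checklist", function(object) {
  t <- object@taxa
  msgs <- character()
  miss <- setdiff(CHECKLIST_COLUMNS, names(t))
  if (length(miss))
    return(paste("missing checklist columns:", paste(miss, collapse = ", ")))
  if (nrow(t) < 1L)
    return("checklist must contain at least one species")
  dup <- unique(t$species[duplicated(t$species)])
  if (length(dup))
    msgs <- c(msgs, paste0("duplicate species: ", paste(dup, collapse = ", ")))
  badGuild <- setdiff(unique(t$guild), GUILD_LEVELS)
  if (length(badGuild))
    msgs <- c(msgs, paste0("unknown guild token(s): ",
                           paste(badGuild, collapse = ", ")))
  badIucn <- setdiff(unique(t$iucn_status), IUCN_CODES)
  if (length(badIucn))
    msgs <- c(msgs, paste0("unknown IUCN status token(s): ",
                           paste(badIucn, collapse = ", ")))
  if (!is.logical(t$protected) || anyNA(t$protected))
    msgs <- c(msgs, "'protected' must be logical without NA")
  g2f <- unique(t[, c("genus", "family")])
  dupG <- unique(g2f$genus[duplicated(g2f$genus)])
  if (length(dupG))
    msgs <- c(msgs, paste0("genus mapped to more than one family: ",
                           paste(dupG, collapse = ", ")))
  f2o <- unique(t[, c("family", "order")])
  dupF <- unique(f2o$family[duplicated(f2o$family)])
  if (length(dupF))
    msgs <- c(msgs, paste0("family mapped to more than one order: ",
                           paste(dupF, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' SurveyTable: validated waterbird survey records
#'
#' S4 container for point-count survey records. Each record carries the
#' calendar year, site, habitat class, species, individual count and the
#' water level (metres) at the time of survey; an optional water-diversion
#' covariate (million cubic metres per year) may be present.
#'
#' @slot records data.frame with columns `year`, `site_id`, `habitat`,
#'   `species`, `count`, `water_level_m` and optionally
#'   `water_diversion_Mm3`.
#' @seealso [SurveyTable()], [readSurveys()], [buildCommunityMatrix()]
#' @export
setClass("SurveyTable", slots = c(records = "data.frame"))

setValidity("SurveyTable", function(object) {
  r <- object@records
  miss <- setdiff(SURVEY_COLUMNS, names(r))
  if (length(miss))
    return(paste("missing survey columns:", paste(miss, collapse = ", ")))
  msgs <- character()
  if (nrow(r)) {
    if (any(r$count < 0)) msgs <- c(msgs, "negative count")
    if (any(r$water_level_m < 0)) msgs <- c(msgs, "negative water level")
  }
  if (length(msgs)) msgs else TRUE
})

#' CommunityMatrix: grouped species abundance matrix
#'
#' S4 container for a community matrix built from survey records: one row
#' per group (a year, a habitat, or a year-habitat combination) and one
#' column per species, each cell holding the summed individual count.
#'
#' @slot counts numeric matrix, groups x species, all cells `>= 0`.
#' @slot groups data.frame of the grouping-key values, one row per matrix
#'   row, columns a subset of `year` and `habitat`.
#' @slot by character, the grouping keys used.
#' @seealso [buildCommunityMatrix()], [abundanceMatrix()], [diversityTable()]
#' @export
setClass("CommunityMatrix",
         slots = c(counts = "matrix", groups = "data.frame", by = "character"))

setValidity("CommunityMatrix", function(object) {
  msgs <- character()
  if (nrow(object@counts) != nrow(object@groups))
    msgs <- c(msgs, "groups table and count matrix disagree on group number")
  if (length(object@counts) && any(object@counts < 0))
    msgs <- c(msgs, "negative abundance cell")
  if (!all(object@by %in% c("year", "habitat")))
    msgs <- c(msgs, "grouping keys must be a subset of {year, habitat}")
  if (length(msgs)) msgs else TRUE
})

#' LandCoverGrid: a categorical land-cover raster
#'
#' S4 container for a single-date categorical raster over the five-class
#' wetland legend. Cells hold integer class codes; `NA` marks NODATA. The
#' raster is treated as an abstract regular grid: the lower-left corner and
#' cell size are carried through file round-trips but no coordinate
#' reference system is attached, and per-cell area is configured directly.
#'
#' @slot codes integer matrix of class codes, `NA` = NODATA.
#' @slot legend named character, code (as character) -> class name.
#' @slot cellArea numeric, area of one cell (square kilometres by
#'   convention; defaults to 1 unit^2).
#' @slot year integer observation year (`NA` if unknown).
#' @slot xll,yll,cellsize numeric grid geometry as in the Esri ASCII header.
#' @seealso [LandCoverGrid()], [readAsciiGrid()], [crosstabTransitions()]
#' @export
setClass("LandCoverGrid",
         slots = c(codes = "matrix", legend = "character", cellArea = "numeric",
                   year = "integer", xll = "numeric", yll = "numeric",
                   cellsize = "numeric"))

setValidity("LandCoverGrid", function(object) {
  msgs <- character()
  if (!length(object@codes) || nrow(object@codes) < 1L || ncol(object@codes) < 1L)
    msgs <- c(msgs, "grid must be rectangular and non-empty")
  codes <- object@codes[!is.na(object@codes)]
  unknown <- setdiff(unique(codes), as.integer(names(object@legend)))
  if (length(unknown))
    msgs <- c(msgs, paste0("grid codes absent from legend: ",
                           paste(unknown, collapse = ", ")))
  if (length(object@cellArea) != 1L || object@cellArea <= 0)
    msgs <- c(msgs, "cellArea must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' TransitionModel: a row-stochastic land-cover transition model
#'
#' S4 container for a first-order Markov model of land-cover change over a
#' fixed calibration interval. Holds the observed from-class x to-class cell
#' counts and the row-normalised transition probabilities; classes never
#' observed as a source default to self-transition.
#'
#' @slot counts integer matrix of observed cell transitions.
#' @slot probabilities row-stochastic numeric matrix (rows sum to 1).
#' @slot stepSpanYears integer, years spanned by one Markov step.
#' @slot classes character, class names indexing rows and columns.
#' @seealso [crosstabTransitions()], [applyScenario()], [projectAreas()]
#' @export
setClass("TransitionModel",
         slots = c(counts = "matrix", probabilities = "matrix",
                   stepSpanYears = "integer", classes = "character"))

setValidity("TransitionModel", function(object) {
  p <- object@probabilities
  msgs <- character()
  if (!identical(dim(p), dim(object@counts)))
    msgs <- c(msgs, "counts and probabilities must share dimensions")
  if (nrow(p) != length(object@classes))
    msgs <- c(msgs, "class labels must match matrix dimension")
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-9))
    msgs <- c(msgs, "probability rows must be non-negative and sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticTruth: ground-truth parameters of the synthetic-data generator
#'
#' S4 container for the parameters that define a simulated wetland: guild
#' water-level optima and response breadths, habitat attraction weights, the
#' total abundance trend across the simulated period, the land-cover
#' transition matrix and the baseline per-species survey abundance. All
#' parameter-recovery tests compare estimates against this object.
#'
#' @slot seed integer RNG seed driving every stochastic draw.
#' @slot guildOptima named numeric, water level (m) of peak suitability per
#'   guild.
#' @slot guildBreadth named numeric, Gaussian response breadth (m) per guild.
#' @slot optimumJitterSd numeric, SD (m) of per-species deviation from the
#'   guild optimum.
#' @slot habitatWeights named numeric, relative attraction of each habitat.
#' @slot trendFactor numeric, ratio of expected total abundance in the last
#'   simulated year to the first.
#' @slot transitionMatrix 5 x 5 row-stochastic land-cover transition matrix.
#' @slot baseAbundance numeric, baseline expected individuals per species
#'   per survey before habitat/water/trend modifiers.
#' @slot waterRange numeric length 2, range (m) spanned by site water levels.
#' @seealso [defaultTruth()], [generateSurveys()]
#' @export
setClass("SyntheticTruth",
         slots = c(seed = "integer", guildOptima = "numeric",
                   guildBreadth = "numeric", optimumJitterSd = "numeric",
                   habitatWeights = "numeric", trendFactor = "numeric",
                   transitionMatrix = "matrix", baseAbundance = "numeric",
                   waterRange = "numeric"))

setValidity("SyntheticTruth", function(object) {
  msgs <- character()
  tm <- object@transitionMatrix
  if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-9))
    msgs <- c(msgs, "transitionMatrix rows must be non-negative and sum to 1")
  if (object@trendFactor <= 0) msgs <- c(msgs, "trendFactor must be > 0")
  if (any(object@guildBreadth <= 0)) msgs <- c(msgs, "breadths must be > 0")
  if (object@baseAbundance <= 0) msgs <- c(msgs, "baseAbundance must be > 0")
  if (length(object@waterRange) != 2L || diff(object@waterRange) <= 0)
    msgs <- c(msgs, "waterRange must be an increasing length-2 range")
  if (length(msgs)) msgs else TRUE
})
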