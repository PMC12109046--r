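#' Build a community matrix from survey records
#'
#' Aggregates survey counts into a [CommunityMatrix-class]: one row per
#' group defined by the grouping keys (`year`, `habitat`, or both), one
#' column per observed species, each cell the summed count over matching
#' records. Individuals are conserved: every group total equals the sum of
#' the survey counts belonging to that group. An empty survey table yields
#' an empty (0-group) matrix, not an error.
#'
#' @param surveys a [SurveyTable-class].
#' @param by character, grouping keys: subset of `c("year", "habitat")`.
#' @return a [CommunityMatrix-class].
#' @examples
#' st <- SurveyTable(data.frame(
#'   year = c(2014, 2014), site_id = "s1", habitat = "water",
#'   species = "Anas acuta", count = c(5, 7), water_level_m = 1))
#' cm <- buildCommunityMatrix(st, by = c("year", "habitat"))
#' abundanceMatrix(cm)  # single cell = 12
#' @export
buildCommunityMatrix <- function(surveys, by = c("year", "habitat")) {
  stopifnot(is(surveys, "SurveyTable"))
  by <- match.arg(by, c("year", "habitat"), several.ok = TRUE)
  r <- surveys@records
  if (!nrow(r)) {
    return(new("CommunityMatrix",
               counts = matrix(numeric(), 0, 0),
               groups = as.data.frame(setNames(rep(list(character(0)), length(by)), by)),
               by = by))
  }
  keyCols <- lapply(by, function(k) r[[k]])
  key <- do.call(paste, c(keyCols, sep = "\r"))
  species <- sort(unique(r$species))
  groups <- unique(data.frame(setNames(keyCols, by), .key = key,
                              stringsAsFactors = FALSE))
  ord <- do.call(order, groups[by])
  groups <- groups[ord, , drop = FALSE]
  counts <- matrix(0, nrow(groups), length(species),
                   dimnames = list(groups$.key, species))
  agg <- tapply(r$count, list(key, r$species), sum)
  agg[is.na(agg)] <- 0
  counts[rownames(agg), colnames(agg)] <- agg
  rownames(counts) <- NULL
  groups$.key <- NULL
  rownames(groups) <- NULL
  new("CommunityMatrix", counts = counts, groups = groups, by = by)
}

#' @rdname accessors
#' @export
setMethod("abundanceMatrix", "CommunityMatrix", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("groupInfo", "CommunityMatrix", function(x) x@groups)

#' @rdname accessors
#' @export
setMethod("groupTotals", "CommunityMatrix", function(x) {
  if (!nrow(x@counts)) return(numeric(0))
  rowSums(x@counts)
})

#' @rdname CommunityMatrix-class
#' @param x,object a CommunityMatrix.
#' @export
setMethod("dim", "CommunityMatrix", function(x) dim(x@counts))

#' @rdname CommunityMatrix-class
#' @export
setMethod("show", "CommunityMatrix", function(object) {
  cat(sprintf("CommunityMatrix: %d group(s) [by %s] x %d species, %d individuals\n",
              nrow(object@counts), paste(object@by, collapse = ", "),
              ncol(object@counts), sum(object@counts)))
})

#' @export
as.data.frame.CommunityMatrix <- function(x, ...) {
  cbind(x@groups, as.data.frame(x@counts))
}
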