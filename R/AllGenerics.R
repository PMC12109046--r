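#' Accessors for wetlandDiv data objects
#'
#' Accessor generics for the package's S4 containers: taxon counts and the
#' taxa table of a [Checklist-class], the record table of a
#' [SurveyTable-class], the abundance matrix and group keys of a
#' [CommunityMatrix-class], and the legend, codes and class areas of a
#' [LandCoverGrid-class].
#'
#' @param x a wetlandDiv S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @rdname accessors
#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))

#' @rdname accessors
#' @export
setGeneric("nGenera", function(x) standardGeneric("nGenera"))

#' @rdname accessors
#' @export
setGeneric("nFamilies", function(x) standardGeneric("nFamilies"))

#' @rdname accessors
#' @export
setGeneric("nOrders", function(x) standardGeneric("nOrders"))

#' @rdname accessors
#' @export
setGeneric("surveyRecords", function(x) standardGeneric("surveyRecords"))

#' @rdname accessors
#' @export
setGeneric("abundanceMatrix", function(x) standardGeneric("abundanceMatrix"))

#' @rdname accessors
#' @export
setGeneric("groupInfo", function(x) standardGeneric("groupInfo"))

#' @rdname accessors
#' @export
setGeneric("groupTotals", function(x) standardGeneric("groupTotals"))

#' @rdname accessors
#' @export
setGeneric("gridCodes", function(x) standardGeneric("gridCodes"))

#' @rdname accessors
#' @export
setGeneric("classLegend", function(x) standardGeneric("classLegend"))

#' @rdname accessors
#' @export
setGeneric("cellArea", function(x) standardGeneric("cellArea"))

#' @rdname accessors
#' @export
setGeneric("classAreas", function(x) standardGeneric("classAreas"))

#' @rdname accessors
#' @export
setGeneric("transitionCounts", function(x) standardGeneric("transitionCounts"))

#' @rdname accessors
#' @export
setGeneric("transitionProbabilities",
           function(x) standardGeneric("transitionProbabilities"))
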