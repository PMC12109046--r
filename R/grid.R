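#' Construct a LandCoverGrid
#'
#' Wraps an integer matrix of class codes as a validated
#' [LandCoverGrid-class]. `NA` cells are NODATA and are excluded from area
#' tallies and transition cross-tabulations.
#'
#' @param codes integer matrix of class codes (`NA` = NODATA).
#' @param legend named character mapping codes (as character names) to class
#'   names; defaults to the five-class wetland legend.
#' @param cellArea area of one cell (km^2 by convention); default 1.
#' @param year observation year (`NA` if unknown).
#' @param xll,yll,cellsize grid geometry carried into the Esri ASCII header.
#' @return a [LandCoverGrid-class].
#' @examples
#' g <- LandCoverGrid(matrix(3L, 2, 2))
#' classAreas(g)  # 4 cells of water
#' @export
LandCoverGrid <- function(codes, legend = defaultLegend(), cellArea = 1,
                          year = NA_integer_, xll = 0, yll = 0, cellsize = 1) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  new("LandCoverGrid", codes = codes, legend = legend, cellArea = cellArea,
      year = as.integer(year), xll = xll, yll = yll, cellsize = cellsize)
}

#' @rdname accessors
#' @export
setMethod("gridCodes", "LandCoverGrid", function(x) x@codes)

#' @rdname accessors
#' @export
setMethod("classLegend", "LandCoverGrid", function(x) x@legend)

#' @rdname accessors
#' @export
setMethod("cellArea", "LandCoverGrid", function(x) x@cellArea)

#' @rdname accessors
#' @export
setMethod("dim", "LandCoverGrid", function(x) dim(x@codes))

#' @describeIn accessors per-class area of a [LandCoverGrid-class]: cell
#'   counts times `cellArea`, NODATA excluded, named by class name.
#' @export
setMethod("classAreas", "LandCoverGrid", function(x) {
  counts <- table(factor(x@codes[!is.na(x@codes)],
                         levels = as.integer(names(x@legend))))
  setNames(as.numeric(counts) * x@cellArea, unname(x@legend))
})

#' @rdname LandCoverGrid-class
#' @param object a LandCoverGrid.
#' @export
setMethod("show", "LandCoverGrid", function(object) {
  cat(sprintf("LandCoverGrid: %d x %d cells (%d NODATA), year %s\n",
              nrow(object@codes), ncol(object@codes),
              sum(is.na(object@codes)),
              ifelse(is.na(object@year), "?", object@year)))
  a <- classAreas(object)
  cat("areas:", paste(sprintf("%s=%g", names(a), a), collapse = " "), "\n")
})

#' Read an Esri ASCII grid
#'
#' Parses a categorical raster in Esri ASCII grid format (header lines
#' `ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`
#' followed by one space-separated row of integer codes per line). Rows
#' whose value count disagrees with `ncols` raise a format error; codes
#' absent from the legend raise a legend error. NODATA cells become `NA`.
#'
#' @param path path to the `.asc` file.
#' @param legend named character, code -> class name.
#' @param cellArea area of one cell; default 1.
#' @param year observation year to attach.
#' @return a [LandCoverGrid-class].
#' @export
readAsciiGrid <- function(path, legend = defaultLegend(), cellArea = 1,
                          year = NA_integer_) {
  lines <- readLines(path)
  .stopIfNot(length(lines) > 6, "truncated ASCII grid")
  hdr <- list()
  for (i in 1:6) {
    tok <- strsplit(.trimSquish(lines[i]), " ")[[1]]
    .stopIfNot(length(tok) == 2, paste("malformed header line:", lines[i]))
    hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  miss <- setdiff(need, names(hdr))
  .stopIfNot(!length(miss),
             paste("missing ASCII grid header fields:",
                   paste(miss, collapse = ", ")))
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- lines[-(1:6)]
  body <- body[nzchar(.trimSquish(body))]
  .stopIfNot(length(body) == nr,
             sprintf("header declares %d rows but file has %d", nr,
                     length(body)))
  rows <- lapply(body, function(l) {
    v <- as.numeric(strsplit(.trimSquish(l), " ")[[1]])
    .stopIfNot(length(v) == nc,
               sprintf("ragged row: expected %d values, found %d", nc,
                       length(v)))
    v
  })
  codes <- do.call(rbind, rows)
  codes[codes == hdr$nodata_value] <- NA
  storage.mode(codes) <- "integer"
  present <- unique(codes[!is.na(codes)])
  unknown <- setdiff(present, as.integer(names(legend)))
  .stopIfNot(!length(unknown),
             paste0("grid codes absent from legend: ",
                    paste(unknown, collapse = ", ")))
  LandCoverGrid(codes, legend = legend, cellArea = cellArea, year = year,
                xll = hdr$xllcorner, yll = hdr$yllcorner,
                cellsize = hdr$cellsize)
}

#' Write an Esri ASCII grid
#'
#' Writes a [LandCoverGrid-class] in Esri ASCII grid format with bit-exact
#' integer codes, so `readAsciiGrid(writeAsciiGrid(g, p))` is the identity
#' on codes including NODATA.
#'
#' @param grid a [LandCoverGrid-class].
#' @param path output path.
#' @param nodata integer written for NODATA cells (default -9999).
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(grid, path, nodata = -9999L) {
  stopifnot(is(grid, "LandCoverGrid"))
  codes <- grid@codes
  .stopIfNot(!nodata %in% codes[!is.na(codes)],
             "nodata sentinel collides with a data code")
  codes[is.na(codes)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(codes)),
           sprintf("nrows %d", nrow(codes)),
           sprintf("xllcorner %.10g", grid@xll),
           sprintf("yllcorner %.10g", grid@yll),
           sprintf("cellsize %.10g", grid@cellsize),
           sprintf("NODATA_value %d", nodata))
  body <- apply(codes, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
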