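#' Construct a SurveyTable from raw records
#'
#' Validates a data frame of point-count survey records and wraps it in a
#' [SurveyTable-class]. Counts must be non-negative integers, water levels
#' non-negative, and habitats drawn from the five-class legend (or a custom
#' legend if supplied). When a checklist is given, species membership is
#' checked: under `strict = TRUE` (the default) unknown species abort with
#' an error listing them; under `strict = FALSE` they are kept with a
#' warning.
#'
#' @param records data.frame with columns `year`, `site_id`, `habitat`,
#'   `species`, `count`, `water_level_m` and optionally
#'   `water_diversion_Mm3`.
#' @param checklist optional [Checklist-class] used to validate species
#'   names.
#' @param strict logical; reject (`TRUE`) or warn on (`FALSE`) species
#'   absent from the checklist.
#' @param habitats character vector of admissible habitat classes.
#' @return a [SurveyTable-class].
#' @examples
#' st <- SurveyTable(data.frame(
#'   year = 2020, site_id = "s1", habitat = "water",
#'   species = "Anas acuta", count = 12, water_level_m = 1.4))
#' length(st)
#' @export
SurveyTable <- function(records, checklist = NULL, strict = TRUE,
                        habitats = habitatClasses()) {
  .stopIfNot(is.data.frame(records), "'records' must be a data.frame")
  miss <- setdiff(SURVEY_COLUMNS, names(records))
  .stopIfNot(!length(miss),
             paste("missing survey columns:", paste(miss, collapse = ", ")))
  r <- as.data.frame(records)
  if (is.null(r$water_diversion_Mm3))
    r$water_diversion_Mm3 <- rep(NA_real_, nrow(r))
  r <- r[c(SURVEY_COLUMNS, "water_diversion_Mm3")]
  r$year <- as.integer(r$year)
  r$site_id <- .trimSquish(r$site_id)
  r$habitat <- tolower(.trimSquish(r$habitat))
  r$species <- .capFirst(r$species)
  r$count <- as.numeric(r$count)
  r$water_level_m <- as.numeric(r$water_level_m)

  .stopIfNot(!anyNA(r$count) && all(r$count >= 0) && all(r$count == floor(r$count)),
             "'count' must be a non-negative integer in every record")
  r$count <- as.integer(r$count)
  .stopIfNot(!anyNA(r$water_level_m) && all(r$water_level_m >= 0),
             "'water_level_m' must be non-negative in every record")
  badHab <- setdiff(unique(r$habitat), habitats)
  .stopIfNot(!length(badHab),
             paste0("habitat outside the legend: ",
                    paste(badHab, collapse = ", ")))
  if (!is.null(checklist)) {
    stopifnot(is(checklist, "Checklist"))
    unknown <- setdiff(unique(r$species), checklist@taxa$species)
    if (length(unknown)) {
      msg <- paste0("species absent from checklist: ",
                    paste(unknown, collapse = ", "))
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
  }
  rownames(r) <- NULL
  new("SurveyTable", records = r)
}

#' Read a survey CSV
#'
#' Reads point-count survey records from CSV (header columns `year`,
#' `site_id`, `habitat`, `species`, `count`, `water_level_m`, optionally
#' `water_diversion_Mm3`) into a validated [SurveyTable-class].
#'
#' @inheritParams SurveyTable
#' @param path path to the CSV file.
#' @return a [SurveyTable-class].
#' @export
readSurveys <- function(path, checklist = NULL, strict = TRUE,
                        habitats = habitatClasses()) {
  SurveyTable(read.csv(path, stringsAsFactors = FALSE), checklist = checklist,
              strict = strict, habitats = habitats)
}

#' Write a survey CSV
#'
#' @param surveys a [SurveyTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSurveys <- function(surveys, path) {
  stopifnot(is(surveys, "SurveyTable"))
  write.csv(surveys@records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname accessors
#' @export
setMethod("surveyRecords", "SurveyTable", function(x) x@records)

#' @rdname SurveyTable-class
#' @param x,object a SurveyTable.
#' @export
setMethod("length", "SurveyTable", function(x) nrow(x@records))

#' @rdname SurveyTable-class
#' @export
setMethod("show", "SurveyTable", function(object) {
  r <- object@records
  cat(sprintf("SurveyTable: %d records", nrow(r)))
  if (nrow(r))
    cat(sprintf(" | years %d-%d | %d sites | %d species | %d individuals",
                min(r$year), max(r$year), length(unique(r$site_id)),
                length(unique(r$species)), sum(r$count)))
  cat("\n")
})

#' @export
as.data.frame.SurveyTable <- function(x, ...) x@records

#' Total abundance per year
#'
#' Sums survey counts by calendar year, the series fed to [foldChange()].
#'
#' @param surveys a [SurveyTable-class].
#' @return named numeric vector of yearly totals, names = years, sorted.
#' @export
totalAbundanceByYear <- function(surveys) {
  stopifnot(is(surveys, "SurveyTable"))
  r <- surveys@records
  tot <- tapply(r$count, r$year, sum)
  out <- as.numeric(tot)
  names(out) <- names(tot)
  out[order(as.integer(names(out)))]
}
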