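#' Construct a Checklist from a taxa table
#'
#' Builds a validated [Checklist-class] from a data frame of taxon records.
#' Names are normalised before validation: whitespace is trimmed and
#' collapsed, and species, genus, family and order names are case-normalised
#' (first letter capitalised, remainder lower-case, the usual binomial
#' convention). Matching elsewhere in the package is exact-string on these
#' normalised names; no fuzzy matching is ever attempted, so typos surface
#' as unknown species rather than silent taxonomic merges.
#'
#' @param taxa data.frame with columns `species`, `genus`, `family`,
#'   `order`, `guild`, `iucn_status`, `protected`. `guild` must be one of
#'   `guildLevels()`, `iucn_status` one of `iucnCategories()`, `protected`
#'   logical (or "true"/"false" text, as read from CSV).
#' @return a [Checklist-class] object.
#' @examples
#' cl <- Checklist(data.frame(
#'   species = "Anas acuta", genus = "Anas", family = "Anatidae",
#'   order = "Anseriformes", guild = "dabbling", iucn_status = "LC",
#'   protected = TRUE))
#' nSpecies(cl)
#' @export
Checklist <- function(taxa) {
  .stopIfNot(is.data.frame(taxa), "'taxa' must be a data.frame")
  miss <- setdiff(CHECKLIST_COLUMNS, names(taxa))
  .stopIfNot(!length(miss),
             paste("missing checklist columns:", paste(miss, collapse = ", ")))
  taxa <- as.data.frame(taxa)[CHECKLIST_COLUMNS]
  for (col in c("species", "genus", "family", "order"))
    taxa[[col]] <- .capFirst(taxa[[col]])
  taxa$guild <- tolower(.trimSquish(taxa$guild))
  taxa$iucn_status <- toupper(.trimSquish(taxa$iucn_status))
  if (!is.logical(taxa$protected))
    taxa$protected <- as.logical(toupper(.trimSquish(taxa$protected)))
  rownames(taxa) <- NULL
  new("Checklist", taxa = taxa)
}

#' Read a checklist CSV
#'
#' Reads a species checklist from CSV (header columns `species`, `genus`,
#' `family`, `order`, `guild`, `iucn_status`, `protected`) into a validated
#' [Checklist-class]. Duplicate species, a genus appearing under two
#' families, or unknown guild/status tokens raise errors naming the
#' offending value.
#'
#' @param path path to the CSV file.
#' @return a [Checklist-class].
#' @examples
#' path <- system.file("extdata", "waterbird_checklist.csv",
#'                     package = "wetlandDiv")
#' cl <- readChecklist(path)
#' nOrders(cl)
#' @export
readChecklist <- function(path) {
  Checklist(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a checklist CSV
#'
#' @param checklist a [Checklist-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeChecklist <- function(checklist, path) {
  stopifnot(is(checklist, "Checklist"))
  write.csv(checklist@taxa, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname accessors
#' @export
setMethod("taxa", "Checklist", function(x) x@taxa)

#' @rdname accessors
#' @export
setMethod("nSpecies", "Checklist", function(x) nrow(x@taxa))

#' @rdname accessors
#' @export
setMethod("nGenera", "Checklist", function(x) length(unique(x@taxa$genus)))

#' @rdname accessors
#' @export
setMethod("nFamilies", "Checklist", function(x) length(unique(x@taxa$family)))

#' @rdname accessors
#' @export
setMethod("nOrders", "Checklist", function(x) length(unique(x@taxa$order)))

#' @rdname Checklist-class
#' @param object a Checklist.
#' @export
setMethod("show", "Checklist", function(object) {
  cat(sprintf("Checklist: %d species | %d genera | %d families | %d orders\n",
              nSpecies(object), nGenera(object), nFamilies(object),
              nOrders(object)))
  tg <- table(object@taxa$guild)
  cat("guilds:", paste(sprintf("%s=%d", names(tg), tg), collapse = " "), "\n")
  flagged <- sum(object@taxa$iucn_status %in% c("CR", "EN", "VU", "NT"))
  cat(sprintf("threat-listed (CR/EN/VU/NT): %d | protected: %d\n",
              flagged, sum(object@taxa$protected)))
})

#' @export
as.data.frame.Checklist <- function(x, ...) x@taxa

# restrict a checklist's taxa table to a species subset (order preserved);
# internal: used by the per-group G/F index computations
.taxaSubset <- function(checklist, species) {
  t <- checklist@taxa
  t[t$species %in% species, , drop = FALSE]
}
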