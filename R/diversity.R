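# Community diversity indices.
#
# All indices use the natural logarithm (Shannon values are in nats), treat
# 0 * ln 0 as 0, and drop zero-abundance species before any computation.

# validate an abundance vector; returns it with zero entries dropped
.abund <- function(x, what = "abundance vector") {
  .stopIfNot(is.numeric(x) && length(x) > 0 && !anyNA(x),
             paste(what, "must be non-empty numeric without NA"))
  .stopIfNot(all(x >= 0), paste(what, "must be non-negative"))
  .stopIfNot(sum(x) > 0, "empty group: all abundances are zero")
  x[x > 0]
}

#' Berger-Parker dominance classification
#'
#' Computes each species' proportional abundance \eqn{I_i = N_i / N} and
#' classifies it as `dominant` (\eqn{I \ge 0.1}), `common`
#' (\eqn{0.01 \le I < 0.1}) or `occasional` (\eqn{I < 0.01}). The two
#' published threshold rules overlap at exactly \eqn{I = 0.1}; the stronger
#' claim wins and the boundary is classified dominant (configurable via
#' `dominant`).
#'
#' @param x named numeric abundance vector (zero-abundance species are
#'   dropped; an all-zero vector is an error).
#' @param dominant,common lower thresholds of the dominant and common
#'   classes.
#' @return data.frame with columns `species`, `proportion`, `class`;
#'   proportions sum to 1.
#' @examples
#' bergerParker(c(A = 10, B = 90))  # A exactly at 0.1 -> dominant
#' @export
bergerParker <- function(x, dominant = 0.1, common = 0.01) {
  x <- .abund(x)
  if (is.null(names(x))) names(x) <- paste0("sp", seq_along(x))
  p <- x / sum(x)
  cls <- ifelse(p >= dominant, "dominant",
                ifelse(p >= common, "common", "occasional"))
  data.frame(species = names(x), proportion = unname(p), class = unname(cls),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Shannon-Wiener diversity index
#'
#' \eqn{H' = -\sum_i p_i \ln p_i} with \eqn{p_i = N_i / N}, natural
#' logarithm. Reflects both species richness and evenness; bounded above by
#' \eqn{\ln S}. Values between roughly 1.5 and 3.5 are typical of natural
#' communities (an advisory range, not enforced).
#'
#' @inheritParams bergerParker
#' @return H' in nats.
#' @examples
#' shannonIndex(c(10, 10))          # ln 2
#' shannonIndex(c(A = 5, B = 3, C = 2))
#' @export
shannonIndex <- function(x) {
  x <- .abund(x)
  .entropy(x / sum(x))
}

#' Pielou evenness index
#'
#' \eqn{E = H' / H_{max}} with \eqn{H_{max} = \ln S}. Undefined for a
#' single-species group (\eqn{H_{max} = 0}); returns `NA` in that case
#' rather than a silent zero.
#'
#' @inheritParams bergerParker
#' @return E in `[0, 1]`, or `NA` when fewer than two species are present.
#' @examples
#' pielouEvenness(c(10, 10))  # 1: maximal evenness
#' @export
pielouEvenness <- function(x) {
  x <- .abund(x)
  if (length(x) < 2) return(NA_real_)
  shannonIndex(x) / log(length(x))
}

#' Simpson dominance index
#'
#' \eqn{C = \sum_i p_i^2}, the probability that two randomly drawn
#' individuals are conspecific. Higher values indicate stronger dominance
#' by few species; bounded in \eqn{[1/S, 1]}.
#'
#' @inheritParams bergerParker
#' @return C in `(0, 1]`.
#' @examples
#' simpsonIndex(c(A = 5, B = 3, C = 2))  # 0.38
#' @export
simpsonIndex <- function(x) {
  x <- .abund(x)
  p <- x / sum(x)
  sum(p^2)
}

#' Genus-level taxonomic diversity (G-index)
#'
#' Entropy of the distribution of species over genera:
#' \eqn{D_G = -\sum_j q_j \ln q_j} with \eqn{q_j = S_j / S}, where
#' \eqn{S_j} is the number of species in genus \eqn{j} and \eqn{S} the total
#' species count. Zero iff all species share one genus.
#'
#' @param checklist a [Checklist-class] (typically restricted to the species
#'   observed in one group).
#' @return D_G (nats, `>= 0`).
#' @export
gIndex <- function(checklist) {
  stopifnot(is(checklist, "Checklist"))
  sj <- table(checklist@taxa$genus)
  .entropy(as.numeric(sj) / sum(sj))
}

#' Family-level taxonomic diversity (F-index)
#'
#' For each family \eqn{k}, the entropy of its species over its genera:
#' \eqn{D_{Fk} = -\sum_i p_i \ln p_i} with \eqn{p_i = S_{ki} / S_k}, where
#' \eqn{S_{ki}} counts species of genus \eqn{i} within family \eqn{k} and
#' \eqn{S_k} the family's species total. The F-index is the sum over
#' families, \eqn{D_F = \sum_k D_{Fk}}; a family containing a single genus
#' contributes zero, which makes the index sensitive to monotypic families.
#'
#' @inheritParams gIndex
#' @return D_F (nats, `>= 0`).
#' @export
fIndex <- function(checklist) {
  stopifnot(is(checklist, "Checklist"))
  t <- checklist@taxa
  perFamily <- vapply(split(t$genus, t$family), function(g) {
    ski <- table(g)
    .entropy(as.numeric(ski) / sum(ski))
  }, numeric(1))
  sum(perFamily)
}

#' G-F composite taxonomic diversity index
#'
#' \eqn{D_{G\mbox{-}F} = 1 - D_G / D_F}. Undefined when \eqn{D_F = 0}
#' (all families monotypic): `NA` is returned with attribute
#' `undefined = TRUE`. Values can fall outside `[0, 1]` when
#' \eqn{D_G > D_F}; they are returned unclamped (with attribute
#' `outOfRange = TRUE`) rather than silently truncated.
#'
#' @param dg genus diversity \eqn{D_G \ge 0}.
#' @param df family diversity \eqn{D_F \ge 0}.
#' @return the G-F index, or flagged `NA` when undefined.
#' @examples
#' gfIndex(0.5, 1.0)  # 0.5
#' @export
gfIndex <- function(dg, df) {
  .stopIfNot(is.numeric(dg) && is.numeric(df) && dg >= 0 && df >= 0,
             "dg and df must be non-negative numbers")
  if (df == 0) return(structure(NA_real_, undefined = TRUE))
  v <- 1 - dg / df
  if (v < 0 || v > 1) structure(v, outOfRange = TRUE) else v
}

#' Per-group diversity table
#'
#' Computes the full index bundle for every group of a community matrix:
#' species richness S, abundance N, Shannon-Wiener H' (nats), Pielou
#' evenness E, Simpson dominance C, and the taxonomic G-, F- and G-F
#' indices. Each group uses only its positive-abundance species, and the
#' taxonomic indices use the checklist hierarchy restricted to those
#' species, so per-group G-F values vary with observed composition. Empty
#' groups are skipped with a warning. `E` is `NA` for single-species groups
#' and `DGF` is `NA` (with `gfUndefined = TRUE`) where \eqn{D_F = 0}.
#'
#' @param cm a [CommunityMatrix-class].
#' @param checklist a [Checklist-class] covering every species in `cm`.
#' @return data.frame with the grouping-key columns followed by `S`, `N`,
#'   `H`, `E`, `C`, `DG`, `DF`, `DGF`, `gfUndefined`, `singleSpecies`.
#' @export
diversityTable <- function(cm, checklist) {
  stopifnot(is(cm, "CommunityMatrix"), is(checklist, "Checklist"))
  counts <- cm@counts
  unknown <- setdiff(colnames(counts), checklist@taxa$species)
  .stopIfNot(!length(unknown),
             paste0("matrix species absent from checklist: ",
                    paste(unknown, collapse = ", ")))
  keep <- which(rowSums(counts) > 0)
  if (length(keep) < nrow(counts))
    warning(sprintf("skipping %d empty group(s)", nrow(counts) - length(keep)),
            call. = FALSE)
  rows <- lapply(keep, function(i) {
    x <- counts[i, ]
    x <- x[x > 0]
    sub <- Checklist(.taxaSubset(checklist, names(x)))
    dg <- gIndex(sub); df <- fIndex(sub); dgf <- gfIndex(dg, df)
    data.frame(cm@groups[i, , drop = FALSE],
               S = length(x), N = sum(x),
               H = shannonIndex(x), E = pielouEvenness(x),
               C = simpsonIndex(x), DG = dg, DF = df,
               DGF = as.numeric(dgf),
               gfUndefined = isTRUE(attr(dgf, "undefined")),
               singleSpecies = length(x) == 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
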