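# Share tables, threatened-species summaries, trend and regression utilities.

#' Taxonomic share table
#'
#' Species counts and percentage shares per order (or family) of a
#' checklist. Shares are percentages of the total species count of the
#' supplied checklist, rounded half-up to `digits` decimals (2 by default,
#' matching conventional reporting; 1 on request).
#'
#' @param checklist a [Checklist-class].
#' @param rank `"order"` or `"family"`.
#' @param digits decimals for the printed share (2 or 1).
#' @return data.frame with columns `group`, `count`, `sharePct`, sorted by
#'   decreasing count; counts sum to `nSpecies(checklist)` and shares to
#'   100 within rounding slack.
#' @examples
#' taxonShares(exampleChecklist(), rank = "order")
#' @export
taxonShares <- function(checklist, rank = c("order", "family"), digits = 2) {
  stopifnot(is(checklist, "Checklist"))
  rank <- match.arg(rank)
  tab <- table(checklist@taxa[[rank]])
  out <- data.frame(group = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$sharePct <- roundHalfUp(100 * out$count / sum(out$count), digits)
  out <- out[order(-out$count, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Threatened-species summary
#'
#' Counts checklist species per IUCN category and reports the share of the
#' flagged (threat-listed) set in the total, rounded half-up to one decimal
#' as conventionally printed.
#'
#' @param checklist a [Checklist-class].
#' @param statuses IUCN categories counted as threat-listed (default CR,
#'   EN, VU, NT).
#' @return list with `byStatus` (data.frame `status`, `count` over all six
#'   categories), `threatenedCount`, and `threatenedSharePct` (percent of
#'   `nSpecies`, 1 decimal).
#' @examples
#' threatSummary(exampleChecklist())$threatenedSharePct  # 15.6
#' @export
threatSummary <- function(checklist, statuses = c("CR", "EN", "VU", "NT")) {
  stopifnot(is(checklist, "Checklist"))
  st <- factor(checklist@taxa$iucn_status, levels = IUCN_CODES)
  tab <- table(st)
  flagged <- sum(tab[statuses])
  list(byStatus = data.frame(status = names(tab), count = as.integer(tab),
                             stringsAsFactors = FALSE),
       threatenedCount = as.integer(flagged),
       threatenedSharePct = roundHalfUp(100 * flagged / nSpecies(checklist), 1))
}

#' Per-year habitat share series
#'
#' Percentage share of each habitat in the yearly total, for abundance
#' (summed counts) or richness (species observed per habitat; the
#' denominator is the sum of per-habitat richness values so shares sum to
#' 100). Requires a matrix grouped by year and habitat. Years with a zero
#' total are skipped with a warning.
#'
#' @param cm a [CommunityMatrix-class] built with
#'   `by = c("year", "habitat")`.
#' @param metric `"abundance"` or `"richness"`.
#' @return data.frame with columns `year`, `habitat`, `value`, `sharePct`.
#' @export
habitatShareSeries <- function(cm, metric = c("abundance", "richness")) {
  stopifnot(is(cm, "CommunityMatrix"))
  metric <- match.arg(metric)
  .stopIfNot(all(c("year", "habitat") %in% cm@by),
             "matrix must be grouped by (year, habitat)")
  g <- cm@groups
  value <- switch(metric,
                  abundance = rowSums(cm@counts),
                  richness = rowSums(cm@counts > 0))
  out <- do.call(rbind, lapply(split(seq_len(nrow(g)), g$year), function(idx) {
    tot <- sum(value[idx])
    if (tot == 0) {
      warning(sprintf("year %s has zero total; skipped", g$year[idx[1]]),
              call. = FALSE)
      return(NULL)
    }
    data.frame(year = g$year[idx], habitat = g$habitat[idx],
               value = value[idx], sharePct = 100 * value[idx] / tot,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares fit
#'
#' Simple linear regression `y ~ x` with the coefficient of determination
#' (the squared Pearson correlation for a single predictor), as used for
#' water-diversion / water-body-area / abundance relationships.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`; `x` must not be
#'   constant.
#' @return list with `slope`, `intercept`, `rSquared`, `n`.
#' @examples
#' olsFit(1:5, 2 * (1:5) + 1)$rSquared  # 1
#' @export
olsFit <- function(x, y) {
  .stopIfNot(is.numeric(x) && is.numeric(y) && length(x) == length(y),
             "x and y must be numeric vectors of equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  .stopIfNot(length(x) >= 3, "need at least 3 complete observations")
  .stopIfNot(sd(x) > 0, "degenerate predictor: x is constant")
  fit <- lm(y ~ x)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot == 0) NA_real_ else 1 - sum(residuals(fit)^2) / ssTot
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       rSquared = r2, n = length(x))
}

#' Fold change of an abundance series
#'
#' Ratio of the last to the first value of a yearly total-abundance series
#' (e.g. a sevenfold population increase over a decade gives 7.0).
#'
#' @param series named numeric vector of yearly totals (names = years) as
#'   returned by [totalAbundanceByYear()]; ordered by year if unnamed.
#' @return last / first total.
#' @examples
#' foldChange(c(`2014` = 1000, `2023` = 7000))  # 7
#' @export
foldChange <- function(series) {
  .stopIfNot(is.numeric(series) && length(series) >= 2,
             "series must hold at least two yearly totals")
  if (!is.null(names(series)))
    series <- series[order(as.numeric(names(series)))]
  .stopIfNot(series[1] > 0, "undefined fold change: first-year total is zero")
  unname(series[length(series)] / series[1])
}
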