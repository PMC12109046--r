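# Guild assignment and guild-level diversity along the water-level gradient.

#' Bundled waterbird guild reference table
#'
#' Reference assignment of South-East Asian wetland species to the four
#' foraging guilds (dabbling birds, diving birds, large waders, small
#' waders). *Anhinga melanogaster* forages by diving but is also treated as
#' a large wader in some schemes; here it is assigned `diving`, and callers
#' can override via [assignGuilds()].
#'
#' @return data.frame with columns `species`, `guild`.
#' @examples
#' head(guildReference())
#' @export
guildReference <- function() {
  tab <- rbind(
    cbind(c("Anas acuta", "Anas crecca", "Anas poecilorhyncha",
            "Anas querquedula", "Nettapus coromandelianus",
            "Sarkidiornis melanotos", "Tadorna ferruginea"), "dabbling"),
    cbind(c("Anhinga melanogaster", "Phalacrocorax carbo",
            "Tachybaptus ruficollis"), "diving"),
    cbind(c("Anastomus oscitans", "Ardea cinerea", "Ardea purpurea",
            "Egretta garzetta", "Mesophoyx intermedia",
            "Mycteria leucocephala", "Pelecanus philippensis",
            "Phalacrocorax niger", "Threskiornis melanocephalus"),
          "large_wader"),
    cbind(c("Calidris temminckii", "Charadrius dubius", "Charadrius veredus",
            "Gallinago gallinago", "Limosa limosa", "Tringa ochropus",
            "Tringa glareola", "Tringa totanus"), "small_wader"))
  data.frame(species = tab[, 1], guild = tab[, 2], stringsAsFactors = FALSE)
}

#' Assign foraging guilds to checklist species
#'
#' Populates the checklist's `guild` column from three sources in
#' decreasing precedence: user `overrides`, the bundled reference table
#' ([guildReference()]), and the checklist's own guild column. Species left
#' with no guild from any source are labelled `none` with a warning (an
#' error under `strict = TRUE`).
#'
#' @param checklist a [Checklist-class].
#' @param overrides named character vector, species -> guild; wins over
#'   every other source.
#' @param strict logical; error (rather than warn) on species without any
#'   guild source.
#' @return the checklist with its `guild` column updated.
#' @examples
#' cl <- assignGuilds(exampleChecklist())
#' subset(taxa(cl), species == "Anas acuta")$guild  # dabbling
#' @export
assignGuilds <- function(checklist, overrides = character(), strict = FALSE) {
  stopifnot(is(checklist, "Checklist"))
  t <- checklist@taxa
  ref <- guildReference()
  hit <- match(t$species, ref$species)
  t$guild[!is.na(hit)] <- ref$guild[hit[!is.na(hit)]]
  if (length(overrides)) {
    bad <- setdiff(unname(overrides), GUILD_LEVELS)
    .stopIfNot(!length(bad),
               paste("unknown guild in overrides:", paste(bad, collapse = ", ")))
    ov <- match(t$species, names(overrides))
    t$guild[!is.na(ov)] <- unname(overrides[ov[!is.na(ov)]])
  }
  unassigned <- t$species[t$guild == "none"]
  if (length(unassigned)) {
    msg <- paste0("no guild source for: ", paste(unassigned, collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  new("Checklist", taxa = t)
}

#' Guild response curves along the water-level gradient
#'
#' Partitions survey records into fixed-width water-level bins (edges
#' aligned to multiples of `binWidth` spanning the observed range) and
#' computes, per guild and bin, the Shannon-Wiener index of the pooled
#' abundance vector of that guild's species. Bins holding fewer than
#' `minRecords` records of a guild are merged rightward into their
#' neighbour (the last bin merges leftward), so retained bins satisfy the
#' minimum. With `perSurvey = TRUE` the per-bin statistic is instead the
#' mean over site-year surveys of the within-survey Shannon index -- an
#' alternative reading of "diversity per water level" reported alongside,
#' not instead of, the pooled form.
#'
#' @param surveys a [SurveyTable-class] with water levels on every record.
#' @param checklist a [Checklist-class] whose `guild` column defines the
#'   guilds (see [assignGuilds()]); `none` species are excluded.
#' @param binWidth bin width in metres (default 0.25).
#' @param minRecords minimum records per retained guild-bin (default 30).
#' @param perSurvey logical, use the per-survey averaged statistic.
#' @return data.frame with columns `guild`, `binCenter`, `binLow`,
#'   `binHigh`, `H`, `S`, `nRecords`, bins ascending within guild.
#' @export
guildResponseCurves <- function(surveys, checklist, binWidth = 0.25,
                                minRecords = 30, perSurvey = FALSE) {
  stopifnot(is(surveys, "SurveyTable"), is(checklist, "Checklist"))
  .stopIfNot(binWidth > 0, "binWidth must be positive")
  r <- surveys@records
  .stopIfNot(nrow(r) > 0, "no survey records")
  t <- checklist@taxa
  guildOf <- setNames(t$guild, t$species)
  r$guild <- guildOf[r$species]
  r <- r[!is.na(r$guild) & r$guild != "none", , drop = FALSE]
  .stopIfNot(nrow(r) > 0, "no records belong to a guild")

  lo <- floor(min(r$water_level_m) / binWidth) * binWidth
  hi <- ceiling(max(r$water_level_m) / binWidth) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  edges <- seq(lo, hi, by = binWidth)
  r$bin <- pmin(findInterval(r$water_level_m, edges,
                             rightmost.closed = TRUE), length(edges) - 1)

  binH <- function(rows) {
    if (perSurvey) {
      hs <- vapply(split(rows$count, paste(rows$year, rows$site_id)),
                   function(x) shannonIndex(x), numeric(1))
      mean(hs)
    } else {
      pooled <- tapply(rows$count, rows$species, sum)
      shannonIndex(as.numeric(pooled))
    }
  }

  out <- lapply(split(r, r$guild), function(rg) {
    nrec <- tapply(rep(1L, nrow(rg)), factor(rg$bin, levels = seq_len(length(edges) - 1)),
                   sum)
    nrec[is.na(nrec)] <- 0L
    # merge deficient bins rightward; the trailing remainder merges leftward
    groups <- list(); cur <- integer(); got <- 0L
    for (b in seq_len(length(edges) - 1)) {
      cur <- c(cur, b); got <- got + nrec[b]
      if (got >= minRecords) {
        groups[[length(groups) + 1L]] <- cur
        cur <- integer(); got <- 0L
      }
    }
    if (length(cur)) {
      if (length(groups)) {
        groups[[length(groups)]] <- c(groups[[length(groups)]], cur)
      } else groups[[1L]] <- cur
    }
    rows <- lapply(groups, function(bs) {
      sel <- rg[rg$bin %in% bs, , drop = FALSE]
      if (!nrow(sel)) return(NULL)
      low <- edges[min(bs)]; high <- edges[max(bs) + 1]
      pooledS <- length(unique(sel$species))
      data.frame(guild = rg$guild[1], binCenter = (low + high) / 2,
                 binLow = low, binHigh = high, H = binH(sel), S = pooledS,
                 nRecords = nrow(sel), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$guild, out$binCenter), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Optimal water level from guild response curves
#'
#' Per guild, the bin centre maximising the Shannon index (ties broken
#' toward the lowest level). With `scope = "all_guild"`, the favourable
#' level across the whole assemblage: the bin centre maximising the
#' minimum Shannon index over guilds, computed on bin centres present in
#' every guild's curve.
#'
#' @param curves data.frame from [guildResponseCurves()].
#' @param scope `"per_guild"` or `"all_guild"`.
#' @return named numeric of optima per guild, or a single numeric for
#'   `all_guild`.
#' @export
optimalWaterLevel <- function(curves, scope = c("per_guild", "all_guild")) {
  scope <- match.arg(scope)
  .stopIfNot(is.data.frame(curves) && nrow(curves) > 0, "empty curve set")
  if (scope == "per_guild") {
    res <- vapply(split(curves, curves$guild), function(cg) {
      best <- cg$binCenter[cg$H == max(cg$H)]
      min(best)  # tie -> lowest level
    }, numeric(1))
    return(res)
  }
  common <- Reduce(intersect, lapply(split(curves, curves$guild),
                                     function(cg) cg$binCenter))
  .stopIfNot(length(common) > 0,
             "no common water-level bins across guilds; rebuild curves with minRecords = 0")
  sub <- curves[curves$binCenter %in% common, , drop = FALSE]
  minH <- tapply(sub$H, sub$binCenter, min)
  centers <- as.numeric(names(minH))
  best <- centers[minH == max(minH)]
  min(best)
}
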