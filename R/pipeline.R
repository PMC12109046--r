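# End-to-end pipeline: simulate -> diversity -> trends -> guilds ->
# land-cover change, with a flat key=value config and a JSON report.

PIPELINE_DEFAULTS <- list(
  seed = 1L, out_dir = NULL,
  n_species = 45L, n_genera = 38L, n_families = 20L, n_orders = 11L,
  year_start = 2014L, year_end = 2023L, n_sites = 20L,
  flock_quantize = FALSE,
  bin_width_m = 0.25, min_records = 30L,
  grid_nrows = 80L, grid_ncols = 80L, cell_area_km2 = 0.016,
  scenario = "restoration", boost = 1.5, horizon_steps = 2L,
  strict = TRUE)

#' Read a flat key=value pipeline configuration
#'
#' Parses a plain-text configuration file with one `key = value` pair per
#' line (`#` starts a comment). Unknown keys are an error; missing keys
#' take the documented defaults. Logical values are written `true`/`false`.
#'
#' @param path path to the config file.
#' @return validated named list of configuration values.
#' @seealso [runPipeline()] for the key set and defaults.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lines[vapply(kv, length, 1L) != 2L]
  .stopIfNot(!length(bad), paste("malformed config line(s):",
                                 paste(bad, collapse = "; ")))
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  unknown <- setdiff(keys, names(PIPELINE_DEFAULTS))
  .stopIfNot(!length(unknown), paste("unknown config key(s):",
                                     paste(unknown, collapse = ", ")))
  cfg <- as.list(setNames(vals, keys))
  validatePipelineConfig(cfg)
}

# coerce string/partial configs onto the defaults and validate
validatePipelineConfig <- function(config) {
  unknown <- setdiff(names(config), names(PIPELINE_DEFAULTS))
  .stopIfNot(!length(unknown), paste("unknown config key(s):",
                                     paste(unknown, collapse = ", ")))
  cfg <- PIPELINE_DEFAULTS
  for (k in names(config)) {
    proto <- PIPELINE_DEFAULTS[[k]]
    v <- config[[k]]
    cfg[[k]] <- if (is.null(proto)) as.character(v)
      else if (is.logical(proto)) {
        if (is.character(v)) tolower(v) %in% c("true", "1", "yes") else
          as.logical(v)
      }
      else if (is.integer(proto)) as.integer(v)
      else if (is.numeric(proto)) as.numeric(v)
      else as.character(v)
  }
  .stopIfNot(!is.null(cfg$out_dir) && nzchar(cfg$out_dir),
             "config must set out_dir")
  .stopIfNot(cfg$year_end >= cfg$year_start, "year_end must be >= year_start")
  .stopIfNot(cfg$scenario %in% c("business_as_usual", "restoration"),
             "scenario must be business_as_usual or restoration")
  cfg
}

#' Run the full wetland diversity pipeline
#'
#' Executes the five analysis stages in order -- simulate, diversity,
#' trends, guilds, landchange -- on a synthetic wetland defined by the
#' configuration, writing per-stage CSV/ASCII outputs, a consolidated JSON
#' report and a run log into `out_dir`. A run is fully determined by
#' `(config, package version)`: the single `seed` is fanned out to
#' per-stage sub-seeds by fixed offsets so each stage is reproducible in
#' isolation, and the report carries no timestamps (the log does).
#'
#' Config keys (flat `key = value` file or named list): `seed`, `out_dir`,
#' checklist shape (`n_species`, `n_genera`, `n_families`, `n_orders`),
#' survey design (`year_start`, `year_end`, `n_sites`, `flock_quantize`,
#' `strict`), water-level binning (`bin_width_m`, `min_records`), raster
#' design (`grid_nrows`, `grid_ncols`, `cell_area_km2`) and scenario
#' (`scenario`, `boost`, `horizon_steps`).
#'
#' @param config named list or path to a key=value config file.
#' @return invisibly, the report list (also written to
#'   `out_dir/report.json`).
#' @examples
#' out <- tempfile("run")
#' rep <- runPipeline(list(seed = 42, out_dir = out, grid_nrows = 30,
#'                         grid_ncols = 30))
#' names(rep)
#' @export
runPipeline <- function(config) {
  cfg <- if (is.character(config) && length(config) == 1L)
    readRunConfig(config) else validatePipelineConfig(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(cfg$out_dir, "run.log")
  logLine <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = logPath, append = TRUE)
  cat(sprintf("wetlandDiv %s | R %s.%s | seed %d | started %s\n",
              as.character(utils::packageVersion("wetlandDiv")),
              R.version$major, R.version$minor, cfg$seed,
              format(Sys.time())), file = logPath)

  stage <- function(name, expr) {
    logLine("stage %s: start", name)
    res <- tryCatch(expr, error = function(e) {
      logLine("stage %s: FAILED (%s)", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    logLine("stage %s: done", name)
    res
  }
  report <- list(config = cfg[order(names(cfg))])

  # --- simulate ---------------------------------------------------------
  sim <- stage("simulate", {
    # the named example assemblage drives the analyses (guild reference and
    # taxonomic shares need real names); abundances and rasters are synthetic
    checklist <- exampleChecklist()
    truth <- defaultTruth(seed = cfg$seed)
    surveys <- generateSurveys(checklist, cfg$year_start:cfg$year_end,
                               nSites = cfg$n_sites, truth = truth,
                               flockQuantize = cfg$flock_quantize)
    series <- generateLandcoverSeries(cfg$grid_nrows, cfg$grid_ncols,
                                      initialProportions = c(0.20, 0.25, 0.20,
                                                             0.20, 0.15),
                                      transitionMatrix = truth@transitionMatrix,
                                      nSteps = 1, seed = cfg$seed + 2000L,
                                      cellArea = cfg$cell_area_km2,
                                      startYear = 2010L)
    writeChecklist(checklist, file.path(cfg$out_dir, "checklist.csv"))
    writeSurveys(surveys, file.path(cfg$out_dir, "surveys.csv"))
    writeAsciiGrid(series[[1]], file.path(cfg$out_dir, "landcover_2010.asc"))
    writeAsciiGrid(series[[2]], file.path(cfg$out_dir, "landcover_2020.asc"))
    list(checklist = checklist, surveys = surveys, series = series,
         truth = truth)
  })
  report$simulate <- list(
    n_species = nSpecies(sim$checklist), n_genera = nGenera(sim$checklist),
    n_families = nFamilies(sim$checklist), n_orders = nOrders(sim$checklist),
    n_survey_records = length(sim$surveys),
    total_individuals = sum(surveyRecords(sim$surveys)$count))

  # --- diversity --------------------------------------------------------
  divTab <- stage("diversity", {
    cm <- buildCommunityMatrix(sim$surveys, by = c("year", "habitat"))
    dt <- diversityTable(cm, sim$checklist)
    write.csv(dt, file.path(cfg$out_dir, "diversity.csv"), row.names = FALSE)
    dt
  })
  peak <- divTab[which.max(divTab$H), ]
  report$diversity <- list(
    n_groups = nrow(divTab),
    peak_H = peak$H, peak_H_year = peak$year, peak_H_habitat = peak$habitat,
    advisory_H_range = c(1.5, 3.5),
    groups_within_advisory = sum(divTab$H >= 1.5 & divTab$H <= 3.5))

  # --- trends -----------------------------------------------------------
  trends <- stage("trends", {
    shares <- taxonShares(sim$checklist, rank = "order")
    threat <- threatSummary(sim$checklist)
    cmYH <- buildCommunityMatrix(sim$surveys, by = c("year", "habitat"))
    habShares <- habitatShareSeries(cmYH, metric = "abundance")
    totals <- totalAbundanceByYear(sim$surveys)
    r <- surveyRecords(sim$surveys)
    perYearLevel <- tapply(r$water_level_m, r$year, mean)
    fit <- olsFit(as.numeric(perYearLevel), as.numeric(totals))
    write.csv(shares, file.path(cfg$out_dir, "taxon_shares.csv"),
              row.names = FALSE)
    write.csv(habShares, file.path(cfg$out_dir, "habitat_shares.csv"),
              row.names = FALSE)
    list(shares = shares, threat = threat, habShares = habShares,
         totals = totals, fit = fit)
  })
  topHab <- with(trends$habShares,
                 names(which.max(tapply(sharePct, habitat, mean))))
  report$trends <- list(
    top_order = trends$shares$group[1],
    top_order_share_pct = trends$shares$sharePct[1],
    threatened_count = trends$threat$threatenedCount,
    threatened_share_pct = trends$threat$threatenedSharePct,
    dominant_habitat = topHab,
    fold_change = foldChange(trends$totals),
    abundance_vs_level_r2 = trends$fit$rSquared)

  # --- guilds -----------------------------------------------------------
  guilds <- stage("guilds", {
    cl <- suppressWarnings(assignGuilds(sim$checklist))
    curves <- guildResponseCurves(sim$surveys, cl,
                                  binWidth = cfg$bin_width_m,
                                  minRecords = cfg$min_records)
    write.csv(curves, file.path(cfg$out_dir, "guild_curves.csv"),
              row.names = FALSE)
    allCurves <- guildResponseCurves(sim$surveys, cl,
                                     binWidth = cfg$bin_width_m,
                                     minRecords = 0)
    list(perGuild = optimalWaterLevel(curves, "per_guild"),
         allGuild = optimalWaterLevel(allCurves, "all_guild"))
  })
  report$guilds <- list(optimal_level_m = as.list(guilds$perGuild),
                        favourable_level_all_guilds_m = guilds$allGuild)

  # --- landchange -------------------------------------------------------
  lc <- stage("landchange", {
    g0 <- sim$series[[1]]; g1 <- sim$series[[2]]
    model <- crosstabTransitions(g0, g1)
    scen <- applyScenario(model, cfg$scenario, boost = cfg$boost)
    traj <- projectAreas(scen, classAreas(g1), nSteps = cfg$horizon_steps,
                         baseYear = g1@year)
    predicted <- allocateMap(g0, model)
    acc <- confusionMetrics(g1, predicted)
    write.csv(data.frame(year = as.integer(rownames(traj)), traj,
                         check.names = FALSE),
              file.path(cfg$out_dir, "area_trajectory.csv"),
              row.names = FALSE)
    writeAsciiGrid(allocateMap(g1, scen),
                   file.path(cfg$out_dir, "landcover_projected.asc"))
    jsonlite::write_json(list(overall_accuracy = acc$overallAccuracy,
                              kappa = acc$kappa),
                         file.path(cfg$out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA)
    list(model = model, traj = traj, acc = acc)
  })
  lastRow <- nrow(lc$traj)
  report$landchange <- list(
    scenario = cfg$scenario,
    step_span_years = lc$model@stepSpanYears,
    horizon_years = as.integer(rownames(lc$traj)),
    area_trajectory = apply(lc$traj, 1, as.list),
    flooded_vegetation_change_km2 =
      lc$traj[lastRow, "flooded_vegetation"] - lc$traj[1, "flooded_vegetation"],
    bare_ground_change_km2 =
      lc$traj[lastRow, "bare_ground"] - lc$traj[1, "bare_ground"],
    markov_validation_accuracy = lc$acc$overallAccuracy,
    markov_validation_kappa = lc$acc$kappa)

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  logLine("pipeline complete")
  invisible(report)
}
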