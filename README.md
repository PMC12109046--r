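# wetlandDiv

Waterbird community diversity analysis and wetland habitat projection.

Restored wetlands along the East Asian–Australasian Flyway are monitored
with repeated point counts of waterbirds and decadal land-cover maps.
`wetlandDiv` packages the statistics such an assessment needs, for wetland
ecologists and reserve managers:

* **Community diversity** — Berger–Parker dominance classification
  (*I* = *N<sub>i</sub>*/*N*; dominant ≥ 0.1, common 0.01–0.1, occasional
  < 0.01), Shannon–Wiener *H′* = −Σ *p<sub>i</sub>* ln *p<sub>i</sub>*,
  Pielou *E* = *H′*/ln *S*, Simpson *C* = Σ *p<sub>i</sub>*², and the
  taxonomic G-, F- and G–F indices
  (*D<sub>G–F</sub>* = 1 − *D<sub>G</sub>*/*D<sub>F</sub>*), computed per
  year and habitat from validated checklists and survey tables.
* **Ecological response** — taxonomic and habitat share tables,
  threatened-species summaries, abundance fold change, OLS fits, and
  guild-level Shannon diversity along the water-level gradient with
  optimal-level detection (per guild, and max–min across guilds).
* **Habitat projection** — a row-stochastic Markov transition model
  calibrated from categorical raster pairs (Esri ASCII grid I/O included),
  business-as-usual and ecological-restoration scenarios, area projection
  (*a*<sub>t+1</sub> = *a*<sub>t</sub> *P*), exact quota-based spatial
  allocation, and accuracy/Cohen's-kappa validation.
* **Synthetic data with known truth** — generators for checklists, survey
  tables and raster series, so every estimator is testable in
  parameter-recovery mode.

## Worked example

```r
library(wetlandDiv)

cl <- exampleChecklist()           # bundled 45-species reference assemblage
taxonShares(cl, rank = "order")[1:4, ]
#>             group count sharePct
#> 1 Charadriiformes    13    28.89
#> 2  Pelecaniformes    12    26.67
#> 3    Anseriformes     7    15.56
#> 4      Gruiformes     4     8.89
threatSummary(cl)$threatenedSharePct
#> [1] 15.6
```

Simulate a decade of surveys from the default truth (sevenfold abundance
trend, guild depth optima at 1.2 / 1.0 / 2.4 / 2.5 m) and recover both:

```r
clG <- assignGuilds(cl)
sv  <- generateSurveys(clG, 2014:2023, nSites = 20,
                       truth = defaultTruth(seed = 42))
foldChange(totalAbundanceByYear(sv))
#> [1] 7.309302
optimalWaterLevel(guildResponseCurves(sv, clG))
#>    dabbling      diving large_wader small_wader
#>       1.125       2.375       2.375       1.125
```

The recovered fold change sits within 5% of the programmed 7.0, and every
guild optimum lands within one 0.25 m bin of its true value. Per-group
diversity and a restoration-scenario projection:

```r
cm <- buildCommunityMatrix(sv, by = c("year", "habitat"))
dt <- diversityTable(cm, cl)
dt[which.max(dt$H), c("year", "habitat", "S", "N", "H", "E", "C", "DGF")]
#>    year habitat  S    N        H         E          C       DGF
#> 45 2022   water 45 1387 3.716429 0.9762959 0.02707342 0.5755743

ser   <- generateLandcoverSeries(200, 200, rep(0.2, 5),
                                 defaultTransitionMatrix(), 1, seed = 42)
model <- crosstabTransitions(ser[[1]], ser[[2]])   # 2010 -> 2020 calibration
round(projectAreas(applyScenario(model, "restoration", boost = 1.5),
                   classAreas(ser[[2]]), nSteps = 2, baseYear = 2020))
#>      crops flooded_vegetation water range_land bare_ground
#> 2020  8624              10134  9447       7531        4264
#> 2030  8426              11882 11027       6413        2252
#> 2040  8156              12672 12170       5498        1504
```

Under the restoration scenario flooded vegetation and water expand toward
2040 while bare ground shrinks — the trajectory the transition model was
built to quantify. `runPipeline()` chains all five stages (simulate →
diversity → trends → guilds → landchange) from a flat `key = value`
config and writes CSV/ASCII outputs plus a deterministic JSON report.

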