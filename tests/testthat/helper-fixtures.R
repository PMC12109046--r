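# shared fixtures, all built in code

smallTaxa <- function() {
  data.frame(
    species = c("Anas acuta", "Anas crecca", "Tringa totanus",
                "Ardea cinerea"),
    genus = c("Anas", "Anas", "Tringa", "Ardea"),
    family = c("Anatidae", "Anatidae", "Scolopacidae", "Ardeidae"),
    order = c("Anseriformes", "Anseriformes", "Charadriiformes",
              "Pelecaniformes"),
    guild = c("dabbling", "dabbling", "small_wader", "large_wader"),
    iucn_status = c("LC", "LC", "LC", "VU"),
    protected = c(TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

smallSurveyDf <- function() {
  data.frame(
    year = c(2014L, 2014L, 2015L),
    site_id = c("s1", "s1", "s2"),
    habitat = c("water", "water", "crops"),
    species = c("Anas acuta", "Tringa totanus", "Anas crecca"),
    count = c(5L, 2L, 7L),
    water_level_m = c(1.2, 1.2, 0.8),
    stringsAsFactors = FALSE)
}

# random checklist over a generated proper hierarchy
randomChecklist <- function(nSp, seed) {
  generateChecklist(nSp, max(1, nSp %/% 2), max(1, nSp %/% 3),
                    max(1, nSp %/% 4), seed = seed)$checklist
}

# independent brute-force index oracles: explicit loops, no shared code
oracleShannon <- function(x) {
  x <- x[x > 0]; n <- sum(x); h <- 0
  for (xi in x) h <- h - (xi / n) * log(xi / n)
  h
}
oracleSimpson <- function(x) {
  x <- x[x > 0]; n <- sum(x); c0 <- 0
  for (xi in x) c0 <- c0 + (xi / n)^2
  c0
}
oracleGIndex <- function(taxa) {
  s <- nrow(taxa); d <- 0
  for (g in unique(taxa$genus)) {
    q <- sum(taxa$genus == g) / s
    d <- d - q * log(q)
  }
  d
}
oracleFIndex <- function(taxa) {
  d <- 0
  for (f in unique(taxa$family)) {
    sub <- taxa[taxa$family == f, ]
    for (g in unique(sub$genus)) {
      p <- sum(sub$genus == g) / nrow(sub)
      d <- d - p * log(p)
    }
  }
  d
}

randomGrid <- function(nr, nc, seed, k = 5, nodataFrac = 0) {
  set.seed(seed)
  m <- matrix(sample.int(k, nr * nc, replace = TRUE), nr, nc)
  if (nodataFrac > 0)
    m[sample.int(nr * nc, round(nodataFrac * nr * nc))] <- NA
  LandCoverGrid(m)
}
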