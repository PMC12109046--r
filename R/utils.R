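# internal helpers shared across modules

# round half away from zero, matching printed percentages (e.g. 15.555 -> 15.6)
roundHalfUp <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

.trimSquish <- function(x) gsub("[[:space:]]+", " ", trimws(as.character(x)))

# binomial / rank-name normalisation: lower-case, first letter capitalised
.capFirst <- function(x) {
  x <- tolower(.trimSquish(x))
  substr(x, 1, 1) <- toupper(substr(x, 1, 1))
  x
}

# largest-remainder apportionment of `total` into integer parts proportional
# to `weights`; ties broken by index order. Conserves the total exactly.
largestRemainder <- function(weights, total) {
  stopifnot(total >= 0, all(weights >= 0), sum(weights) > 0)
  quota <- weights / sum(weights) * total
  base <- floor(quota)
  short <- total - sum(base)
  if (short > 0) {
    ord <- order(quota - base, decreasing = TRUE)  # stable: ties by index
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  setNames(as.integer(base), names(weights))
}

.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

.stopIfNot <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
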