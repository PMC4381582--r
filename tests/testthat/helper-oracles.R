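# Independent brute-force oracles, implemented with plain loops so they do
# not share code paths with the package functions they check.

# Hit calling: explicit per-gene loop over siRNA z-scores.
oracleHits <- function(pz, threshold = -2, minConcordant = 2,
                       selectivityMargin = -1) {
  out <- logical(length(pz@genes))
  names(out) <- pz@genes
  for (i in seq_along(pz@genes)) {
    k <- length(pz@sirnas[[i]])
    zo <- pz@zOver[i, seq_len(k)]
    zc <- pz@zCtrl[i, seq_len(k)]
    if (any(is.na(zo)) || any(is.na(zc))) { out[i] <- FALSE; next }
    cnt <- 0
    for (z in zo) if (z < threshold) cnt <- cnt + 1
    sel <- mean(zo) - mean(zc)
    out[i] <- (cnt >= minConcordant) && (sel <= selectivityMargin)
  }
  out
}

# Spreadsheet-style ddCt: explicit per-cell arithmetic.
oracleFolds <- function(records, housekeeping, referenceSample,
                        efficiency = 2) {
  avg <- function(s, g) mean(records$ct[records$sample == s &
                                        records$gene == g])
  samples <- unique(records$sample)
  targets <- setdiff(unique(records$gene), housekeeping)
  res <- list()
  for (g in targets) {
    dct_ref <- avg(referenceSample, g) -
      mean(vapply(housekeeping, function(h) avg(referenceSample, h),
                  numeric(1)))
    for (s in samples) {
      dct <- avg(s, g) -
        mean(vapply(housekeeping, function(h) avg(s, h), numeric(1)))
      res[[paste(s, g)]] <- data.frame(sample = s, gene = g,
                                       fold = efficiency^(-(dct - dct_ref)))
    }
  }
  do.call(rbind, res)
}

# Dense grid search over (logIC50, hill) with bottom/top held fixed.
oracleGrid4PL <- function(conc, response, bottom, top,
                          logGrid, hillGrid) {
  best <- c(rss = Inf, logIC50 = NA, hill = NA)
  for (l in logGrid) for (h in hillGrid) {
    pred <- bottom + (top - bottom) / (1 + 10^((l - log10(conc)) * h))
    rss <- sum((response - pred)^2)
    if (rss < best["rss"]) best <- c(rss = rss, logIC50 = l, hill = h)
  }
  best
}
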