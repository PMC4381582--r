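test_that("surviving fractions normalize to the plate's neg-control median", {
  ds <- handPlate(readings = c(0.5, 1.0, 0.8, 0, 2.0, 1.0, 1.0, 1.0),
                  neg = c(0.8, 1.0, 1.2))
  sf <- survivingFractions(ds)
  s <- sf[sf$role == "sample", ]
  s <- s[order(s$gene), ]
  expect_equal(s$sf[s$gene == "G1"], 0.5)    # median of neg controls is 1.0
  expect_equal(s$sf[s$gene == "G2"], 1)      # reading equal to the median
  expect_equal(s$sf[s$gene == "G4"], 0)      # dead well
  # control wells are emitted too, and their median sf is exactly 1
  expect_equal(median(sf$sf[sf$role == "neg_control"]), 1)
})

test_that("surviving fractions fail informatively on unusable plates", {
  w <- wells(handPlate())
  no_neg <- newScreenDataset(w[w$role != "neg_control", ])
  expect_error(survivingFractions(no_neg), "normalization error.*P1")
  w0 <- w
  w0$reading[w0$role == "neg_control"] <- 0
  expect_error(survivingFractions(newScreenDataset(w0)), "degenerate plate.*P1")
})

test_that("z-scores are median-centered with the documented sd and mad scales", {
  ds <- handPlate(readings = c(0.5, 1.0, 1.0, 1.0, 1.0, 1.5),
                  neg = c(1, 1, 1))
  sf <- survivingFractions(ds)
  z_sd <- medianCenteredZscores(sf, scale = "sd")
  zg1 <- z_sd$zscore[z_sd$gene == "G1"]
  expect_equal(zg1, (0.5 - 1.0) / sd(c(0.5, 1, 1, 1, 1, 1.5)))
  expect_equal(zg1, -1.5811388, tolerance = 1e-6)

  # mad scale on an asymmetric stratum
  x <- c(0.4, 0.9, 1.0, 1.0, 1.1, 1.2, 1.05, 0.95)
  ds2 <- handPlate(readings = x, neg = c(1, 1, 1))
  z_mad <- medianCenteredZscores(survivingFractions(ds2), scale = "mad")
  ctr <- median(x)
  expect_equal(z_mad$zscore[z_mad$gene == "G1"],
               (0.4 - ctr) / (1.4826 * median(abs(x - ctr))))

  # all-identical stratum degenerates to z = 0 with a warning
  ds3 <- handPlate(readings = rep(1, 6), neg = c(1, 1, 1))
  expect_warning(
    expect_warning(z0 <- medianCenteredZscores(survivingFractions(ds3)),
                   "falling back"),
    "zero scale")
  expect_true(all(z0$zscore[z0$role == "sample"] == 0))
})

test_that("z-scores are invariant under per-plate rescaling of readings", {
  sim <- tinyScreen(nGenes = 52, seed = 5)  # two plates per line
  z1 <- medianCenteredZscores(survivingFractions(sim$dataset))
  w <- wells(sim$dataset)
  gain <- ifelse(w$plate_id == unique(w$plate_id)[1], 2.7, 0.4)
  w$reading <- w$reading * gain
  z2 <- medianCenteredZscores(survivingFractions(newScreenDataset(w)))
  expect_equal(z2$zscore, z1$zscore)
})

test_that("per-stratum sample z median is zero for both stratifications", {
  sim <- tinyScreen(nGenes = 300, seed = 9)
  sf <- survivingFractions(sim$dataset)
  for (strat in c("per_plate", "per_cell_line")) {
    z <- medianCenteredZscores(sf, stratify = strat)
    zs <- z[z$role == "sample", ]
    key <- if (strat == "per_plate") paste(zs$cell_line, zs$plate_id)
           else zs$cell_line
    meds <- tapply(zs$zscore, key, median)
    expect_lt(max(abs(meds)), 1e-9)
  }
})

test_that("gene aggregation pairs lines, reports missing data, rejects unknown lines", {
  sim <- tinyScreen(nGenes = 25, seed = 2)
  z <- medianCenteredZscores(survivingFractions(sim$dataset))
  pz <- aggregateGenes(z, "M2.1", "V11")
  expect_identical(length(pz@genes), 25L)
  expect_identical(dim(pz@zOver), c(25L, 3L))
  expect_identical(nrow(pz@missing), 0L)
  expect_error(aggregateGenes(z, "M2.1", "nope"), "unknown cell line")

  # drop one siRNA from one line -> missing report, gene never a hit
  z2 <- z[!(z$gene == "KIN0003" & z$sirna_id == "KIN0003_si2" &
            z$cell_line == "V11"), ]
  pz2 <- aggregateGenes(z2, "M2.1", "V11")
  expect_identical(pz2@missing,
                   data.frame(gene = "KIN0003", sirna_id = "KIN0003_si2",
                              missing_in = "V11", stringsAsFactors = FALSE))
  hits2 <- callHits(pz2)
  expect_false(hits2$hit[hits2$gene == "KIN0003"])
  expect_false(hits2$complete[hits2$gene == "KIN0003"])

  # empty input -> empty output
  pz0 <- aggregateGenes(z[z$role != "sample", ], "M2.1", "V11")
  expect_identical(length(pz0@genes), 0L)
})

test_that("hit rule: >= 2 concordant siRNAs below -2 plus selectivity margin", {
  mk <- function(zo, zc) {
    g <- "G1"
    new("PairedScreenZ", genes = g, sirnas = setNames(list(paste0("s", 1:3)), g),
        zOver = matrix(zo, 1, dimnames = list(g, paste0("si", 1:3))),
        zCtrl = matrix(zc, 1, dimnames = list(g, paste0("si", 1:3))),
        missing = data.frame(), lineOver = "A", lineCtrl = "B")
  }
  h <- callHits(mk(c(-2.5, -2.1, -0.3), c(-0.1, 0.2, 0.0)))
  expect_true(h$hit)
  expect_identical(h$n_sirnas_below, 2L)
  expect_equal(h$selectivity, -1.6333333 - 0.0333333, tolerance = 1e-6)

  # only one siRNA strictly below -2 -> no hit
  expect_false(callHits(mk(c(-2.5, -1.9, -1.9), c(0, 0, 0)))$hit)
  # boundary: z exactly -2 does not count (strict inequality)
  expect_identical(callHits(mk(c(-2, -2, -2.5), c(0, 0, 0)))$n_sirnas_below, 1L)
  # flat gene -> no hit
  expect_false(callHits(mk(c(0, 0, 0), c(0, 0, 0)))$hit)
  # concordant but unselective (equally lethal in control line) -> no hit
  expect_false(callHits(mk(c(-3, -3, -3), c(-3, -3, -3)))$hit)
  # argument contracts
  expect_error(callHits(mk(c(0, 0, 0), c(0, 0, 0)), threshold = 1), "negative")
  expect_error(callHits(mk(c(0, 0, 0), c(0, 0, 0)), minConcordant = 4), "\\[1, 3\\]")
})

test_that("hit set shrinks monotonically in threshold and concordance", {
  sim <- tinyScreen(nGenes = 120, seed = 13, offtargetRate = 0.1)
  res <- screenPipeline(sim$dataset, "M2.1", "V11")
  base <- res$hits$gene[res$hits$hit]
  for (thr in c(-2.5, -3, -4)) {
    h <- callHits(res$paired, threshold = thr)
    expect_true(all(h$gene[h$hit] %in% base))
  }
  h2 <- callHits(res$paired, minConcordant = 3)
  expect_true(all(h2$gene[h2$hit] %in% base))
  h3 <- callHits(res$paired, selectivityMargin = -2)
  expect_true(all(h3$gene[h3$hit] %in% base))
})

test_that("callHits agrees with the brute-force oracle on small screens", {
  for (seed in 1:6) {
    sim <- tinyScreen(nGenes = 20, seed = seed, offtargetRate = 0.15,
                      wellNoiseSd = 0.3)
    res <- screenPipeline(sim$dataset, "M2.1", "V11",
                          stratify = "per_cell_line")
    got <- setNames(res$hits$hit, res$hits$gene)
    want <- oracleHits(res$paired)
    expect_identical(got[names(want)], want)
  }
})

test_that("hit matrix mirrors the z-score records in hit-table order", {
  sim <- tinyScreen(nGenes = 60, seed = 21)
  res <- screenPipeline(sim$dataset, "M2.1", "V11")
  hm <- res$hitMatrix
  hit_genes <- res$hits$gene[res$hits$hit]
  expect_identical(rownames(hm), hit_genes)
  expect_identical(ncol(hm), 6L)
  # entries equal the underlying per-siRNA z records
  z <- res$z
  for (g in hit_genes) for (j in 1:3) {
    rec <- z$zscore[z$gene == g & z$cell_line == "M2.1" &
                    z$sirna_id == paste0(g, "_si", j)]
    expect_equal(unname(hm[g, paste0("M2.1.si", j)]), rec)
  }
  # no hits -> 0-row matrix with the same columns
  none <- callHits(res$paired, selectivityMargin = -1000)
  hm0 <- hitMatrix(none, res$paired)
  expect_identical(nrow(hm0), 0L)
  expect_identical(colnames(hm0), colnames(hm))
})
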