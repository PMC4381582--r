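test_that("residual activity interpolates between the assay controls", {
  expect_equal(residualActivity(1000, 100, 1000), 100)
  expect_equal(residualActivity(100, 100, 1000), 0)
  expect_equal(residualActivity(550, 100, 1000), 50)
  # affine invariance: scaling all counts by k > 0 changes nothing
  for (k in c(0.25, 3, 117)) {
    expect_equal(residualActivity(550 * k, 100 * k, 1000 * k), 50)
  }
  # noisy counts may leave [0, 100]; clipping is opt-in
  expect_equal(residualActivity(1100, 100, 1000), 111.1111, tolerance = 1e-6)
  expect_equal(residualActivity(1100, 100, 1000, clip = TRUE), 100)
  expect_equal(residualActivity(50, 100, 1000, clip = TRUE), 0)
  expect_error(residualActivity(500, 1000, 1000), "degenerate assay")
  expect_error(residualActivity(500, 1200, 1000), "degenerate assay")
})

test_that("4PL fit recovers exact-model parameters to < 1e-6 relative", {
  doses <- 10^seq(-9, -5, by = 0.5)
  for (truth in list(c(bottom = 0, top = 100, hill = 1, ic50 = 1e-7),
                     c(bottom = 5, top = 98, hill = 1.7, ic50 = 53e-9),
                     c(bottom = -2, top = 110, hill = 0.6, ic50 = 2e-6))) {
    y <- truth["bottom"] + (truth["top"] - truth["bottom"]) /
      (1 + 10^((log10(truth["ic50"]) - log10(doses)) * truth["hill"]))
    fit <- fit4PL(doses, y)
    p <- coefficients4PL(fit)
    for (nm in c("bottom", "top", "hill", "ic50")) {
      expect_equal(unname(p[nm]), unname(truth[nm]),
                   tolerance = 1e-6, info = nm)
    }
    expect_lt(fit@rss, 1e-10)
  }
})

test_that("4PL fit matches a dense grid-search oracle on a 6-point series", {
  doses <- 10^c(-8.5, -8, -7.5, -7, -6.5, -6)
  y <- 100 / (1 + 10^((log10(8e-8) - log10(doses)) * 1.3)) +
    c(1.2, -0.8, 0.5, -1.5, 0.9, -0.3)  # fixed perturbation
  # oracle: bottom/top pinned at the plateaus, exhaustive (logIC50, hill) grid
  grid <- oracleGrid4PL(doses, y, bottom = 0, top = 100,
                        logGrid = seq(-9, -5.5, by = 0.01),
                        hillGrid = seq(0.3, 3, by = 0.01))
  fit <- fit4PL(doses, y,
                constraints = list(bottom = c(0, 0),      # held fixed
                                   top = c(100, 100),     # held fixed
                                   hill = c(0.05, 5)))
  expect_equal(fit@logIC50, unname(grid["logIC50"]), tolerance = 0.011)
  expect_equal(fit@hill, unname(grid["hill"]), tolerance = 0.011)
  expect_lte(fit@rss, unname(grid["rss"]) + 1e-9)
})

test_that("4PL fit enforces its data contract", {
  expect_error(fit4PL(10^c(-8, -7, -6), c(90, 50, 10)), "insufficient data")
  expect_error(fit4PL(c(-1e-8, 1e-7, 1e-6, 1e-5), c(90, 70, 30, 10)),
               "> 0")
  expect_error(fit4PL(10^seq(-9, -5), seq(100, 0, length.out = 5),
                      nBoot = 100), "seed")
})

test_that("mean fitted IC50 over seeded noisy series reproduces the truth", {
  doses <- 10^seq(-9, -5, by = 0.5)
  series <- simulateDoseResponse(bottom = 0, top = 100, hill = 1,
                                 ic50 = 53e-9, doses = doses, noiseSd = 3,
                                 nSeries = 60, seed = 401)
  fits <- vapply(split(series, series$series), function(s)
    ic50(fit4PL(s$concentration, s$response)), numeric(1))
  expect_equal(mean(fits), 53e-9, tolerance = 0.1)
})

test_that("bootstrap CI is seeded, reproducible, and covers the truth", {
  doses <- 10^seq(-9, -5, by = 0.5)
  s <- simulateDoseResponse(ic50 = 53e-9, doses = doses, noiseSd = 3,
                            nSeries = 1, seed = 77)
  f1 <- fit4PL(s$concentration, s$response, nBoot = 199, seed = 5)
  f2 <- fit4PL(s$concentration, s$response, nBoot = 199, seed = 5)
  expect_identical(c(f1@ciLow, f1@ciHigh), c(f2@ciLow, f2@ciHigh))
  expect_true(f1@ciLow < f1@ciHigh)

  # coverage at nominal 95% stays above the 85% floor (scaled-down check)
  n_rep <- 40
  covered <- vapply(seq_len(n_rep), function(i) {
    si <- simulateDoseResponse(ic50 = 53e-9, doses = doses, noiseSd = 3,
                               nSeries = 1, seed = 1000 + i)
    f <- fit4PL(si$concentration, si$response, nBoot = 199, seed = 2000 + i)
    !is.na(f@ciLow) && f@ciLow <= 53e-9 && 53e-9 <= f@ciHigh
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("titration comparison reports per-dose deltas, IC50 ratio, rescue index", {
  doses <- 10^seq(-8.5, -5, by = 0.5)
  base <- data.frame(concentration = doses,
                     response = 100 / (1 + 10^((log10(2e-7) - log10(doses)))))
  # identical curves
  same <- compareTitrations(base, base)
  expect_equal(same$perDose$delta, rep(0, length(doses)))
  expect_equal(same$ic50Ratio, 1)
  expect_equal(same$rescueIndex, 0)
  # uniform +20 shift in curve B (within top constraint reach)
  up <- base
  up$response <- up$response + 20
  shifted <- compareTitrations(base, up,
                               constraints = list(bottom = c(-10, 60),
                                                  top = c(50, 140),
                                                  hill = c(1e-3, 5)))
  expect_equal(shifted$rescueIndex, 20)
  expect_equal(shifted$perDose$delta, rep(20, length(doses)))
  # 2-fold IC50 shift, seeded noise
  a <- simulateDoseResponse(ic50 = 1e-7, doses = doses, noiseSd = 2,
                            nSeries = 1, seed = 31)
  b <- simulateDoseResponse(ic50 = 2e-7, doses = doses, noiseSd = 2,
                            nSeries = 1, seed = 32)
  cmp <- compareTitrations(a[c("concentration", "response")],
                           b[c("concentration", "response")])
  expect_equal(cmp$ic50Ratio, 0.5, tolerance = 0.1)
  # disjoint grids refused
  off <- base
  off$concentration <- off$concentration * 1.5
  expect_error(compareTitrations(base, off), "grid mismatch")
})
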