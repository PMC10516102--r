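test_that("land-cover masking keeps presence only on permitted classes", {
  b <- rasterGrid(matrix(c(1, 1, 0, 1, NA, 1), 2, 3))
  lcAll <- rasterGrid(matrix(2, 2, 3))
  expect_equal(gridValues(maskLandcover(b, lcAll, allowed = 1:5)),
               gridValues(b))
  lcNone <- rasterGrid(matrix(9, 2, 3))
  expect_equal(sum(gridValues(maskLandcover(b, lcNone, 1:5)) == 1,
                   na.rm = TRUE), 0)
  # cell-by-cell oracle on random inputs
  set.seed(10)
  b2 <- rasterGrid(matrix(rbinom(100, 1, 0.5), 10, 10))
  lc <- rasterGrid(matrix(sample(1:7, 100, TRUE), 10, 10))
  got <- gridValues(maskLandcover(b2, lc, allowed = c(1, 3, 5)))
  for (i in 1:10) for (j in 1:10) {
    expect_equal(got[i, j],
                 as.numeric(gridValues(b2)[i, j] == 1 &
                            gridValues(lc)[i, j] %in% c(1, 3, 5)))
  }
  expect_error(maskLandcover(b, rasterGrid(matrix(1, 3, 3)), 1),
               "co-registered")
})

test_that("range area sums per-cell areas over presence cells", {
  b <- rasterGrid(matrix(0, 5, 5))
  v <- gridValues(b); v[1:10] <- 1
  b <- withValues(b, v)
  expect_equal(rangeArea(b, cellAreas(b, 100)), 1000)
  expect_equal(rangeArea(withValues(b, matrix(0, 5, 5)), cellAreas(b, 100)), 0)
  # latitude-varying areas match the per-cell summation oracle
  geo <- rasterGrid(matrix(rbinom(100, 1, 0.4), 10, 10), ymin = 30,
                    cellsize = 0.5)
  a <- cellAreas(geo)
  oracle <- sum(a[gridValues(geo) == 1])
  expect_equal(rangeArea(geo, a), oracle)
})

test_that("range change classifies loss, stability and gain at the 5% band", {
  expect_equal(rangeChange(100, 74)$pct_change, -26)
  expect_equal(rangeChange(100, 74)$change_class, "loss")
  expect_equal(rangeChange(100, 96)$change_class, "stable")
  expect_equal(rangeChange(100, 105.1)$change_class, "gain")
  expect_equal(rangeChange(100, 104.9)$change_class, "stable")
  expect_equal(rangeChange(100, 95.1)$change_class, "stable")
  expect_equal(rangeChange(100, 94.9)$change_class, "loss")
  expect_error(rangeChange(0, 50), "positive")
})

test_that("suitability change is the percent change in summed suitability", {
  p <- rasterGrid(matrix(runif(64), 8, 8))
  expect_equal(suitabilityChange(p, p), 0)
  expect_equal(suitabilityChange(p, withValues(p, gridValues(p) * 0.5)), -50)
  set.seed(6)
  f <- withValues(p, matrix(runif(64), 8, 8))
  oracle <- 100 * (sum(gridValues(f)) - sum(gridValues(p))) / sum(gridValues(p))
  expect_equal(suitabilityChange(p, f), oracle)
  expect_error(suitabilityChange(withValues(p, matrix(0, 8, 8)), f), "zero")
  # the within-range alternative restricts the comparison
  b <- withValues(p, matrix(rep(c(1, 0), 32), 8, 8))
  keep <- gridValues(b) == 1
  oracleWithin <- 100 * (sum(gridValues(f)[keep]) - sum(gridValues(p)[keep])) /
    sum(gridValues(p)[keep])
  expect_equal(suitabilityChange(p, f, statistic = "mean_within_range",
                                 present_binary = b), oracleWithin)
})

test_that("richness stacking is an order-invariant cell-wise sum", {
  set.seed(12)
  maps <- lapply(1:16, function(i)
    rasterGrid(matrix(rbinom(36, 1, 0.5), 6, 6)))
  rich <- stackRichness(maps)
  expect_equal(gridValues(rich),
               Reduce(`+`, lapply(maps, gridValues)))  # conservation
  expect_true(max(gridValues(rich)) <= 16)
  allOn <- lapply(1:16, function(i) rasterGrid(matrix(1, 2, 2)))
  expect_equal(gridValues(stackRichness(allOn))[1, 1], 16)
  empty <- stackRichness(lapply(1:3, function(i) rasterGrid(matrix(0, 2, 2))))
  expect_equal(unique(as.vector(gridValues(empty))), 0)
  expect_equal(gridValues(stackRichness(rev(maps))), gridValues(rich))
})

test_that("masking never increases area and richness never exceeds species count", {
  set.seed(19)
  for (i in 1:5) {
    b <- rasterGrid(matrix(rbinom(64, 1, 0.6), 8, 8))
    lc <- rasterGrid(matrix(sample(1:6, 64, TRUE), 8, 8))
    a <- cellAreas(b, 100)
    expect_lte(rangeArea(maskLandcover(b, lc, 1:5), a), rangeArea(b, a))
  }
})

test_that("the range-change table pairs each future with its present", {
  areas <- data.frame(species = rep(c("a", "b"), each = 3),
                      scenario = rep(c("present", "rcp45", "rcp85"), 2),
                      area_km2 = c(100, 96, 74, 200, 220, 150))
  tab <- rangeChangeTable(areas)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$change_class, c("stable", "loss", "gain", "loss"))
  expect_equal(tab$pct_change, c(-4, -26, 10, -25))
})
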