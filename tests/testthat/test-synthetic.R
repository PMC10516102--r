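test_that("the same config yields bit-identical landscapes", {
  cfg <- syntheticConfig(grid_rows = 12, grid_cols = 12, n_climate_vars = 4,
                         seed = 11)
  a <- generateClimate(cfg)
  b <- generateClimate(cfg)
  expect_identical(stackValues(a), stackValues(b))
})

test_that("identity mixing with no spatial smoothing gives independent layers", {
  # Monte-Carlo independence check at 10,000 cells
  cfg <- syntheticConfig(grid_rows = 100, grid_cols = 100, n_climate_vars = 4,
                         spatial_range = 0, mixing = diag(4), seed = 3)
  X <- stackValues(generateClimate(cfg))
  r <- cor(X)
  expect_true(all(abs(r[upper.tri(r)]) < 0.1))
})

test_that("the default landscape carries 19 bioclimatic-style layers", {
  st <- generateClimate(syntheticConfig(grid_rows = 10, grid_cols = 10, seed = 1))
  expect_equal(nLayers(st), 19L)
})

test_that("a non-positive-definite mixing matrix is rejected by name", {
  bad <- matrix(1, 3, 3)          # rank 1, not PD
  cfg <- syntheticConfig(grid_rows = 8, grid_cols = 8, n_climate_vars = 3,
                         mixing = bad)
  expect_error(generateClimate(cfg), "mixing")
})

test_that("scenario shifts transform layers exactly and tag the scenario", {
  st <- tinyStack(8, 8, 3)
  none <- scenarioShift("rcp45", "gcm1",
                        additive = c(bio01 = 0),
                        multiplicative = c(bio02 = 1))
  expect_equal(stackValues(generateFuture(st, none)), stackValues(st))
  plus2 <- scenarioShift("rcp85", "gcm2", additive = c(bio02 = 2))
  fut <- generateFuture(st, plus2)
  expect_equal(mean(gridValues(getLayer(fut, "bio02"))),
               mean(gridValues(getLayer(st, "bio02"))) + 2)
  expect_equal(scenarioTag(fut), "rcp85:gcm2")
  expect_error(generateFuture(st, scenarioShift("x", "y",
                                                additive = c(nope = 1))),
               "unknown")
})

test_that("two pathways times five models yield ten future stacks", {
  st <- tinyStack(8, 8, 4)
  shifts <- defaultScenarioShifts(st)
  expect_length(shifts, 10L)
  expect_equal(sort(unique(vapply(shifts, `[[`, "", "scenario_id"))),
               c("rcp45", "rcp85"))
  expect_equal(sum(vapply(shifts, `[[`, "", "scenario_id") == "rcp45"), 5L)
})

test_that("virtual-species suitability peaks at the optimum and flattens as breadth grows", {
  st <- tinyStack(10, 10, 2)
  vs <- virtualSpecies("v", c("bio01", "bio02"),
                       optima = c(bio01 = 1, bio02 = 2),
                       breadths = c(bio01 = 0.5, bio02 = 0.5))
  suit <- trueSuitability(st, vs)
  expect_equal(max(gridValues(suit)), 1)
  wide <- virtualSpecies("v", c("bio01", "bio02"),
                         optima = c(bio01 = 1, bio02 = 2),
                         breadths = c(bio01 = 1e9, bio02 = 1e9))
  expect_equal(diff(range(gridValues(trueSuitability(st, wide)))), 0,
               tolerance = 1e-9)
  expect_error(virtualSpecies("v", character(), numeric(), numeric()),
               "nonempty")
  expect_error(virtualSpecies("v", "bio01", c(bio01 = 0), c(bio01 = -1)),
               "positive")
})

test_that("halving a breadth never increases suitability off the optimum", {
  st <- tinyStack(15, 15, 2, seed = 9)
  mk <- function(b) trueSuitability(st, virtualSpecies(
    "v", "bio01", optima = c(bio01 = 1), breadths = c(bio01 = b)))
  narrow <- gridValues(mk(0.4))
  wideV <- gridValues(mk(0.8))
  # both rescale their maximum to 1; ratio ordering must hold everywhere
  expect_true(all(narrow <= wideV + 1e-12))
})

test_that("presence sampling is suitability-weighted and seeded", {
  st <- tinyStack(10, 10, 1)
  one <- matrix(0, 10, 10); one[4, 7] <- 1
  suit <- withValues(getLayer(st, "bio01"), one)
  pts <- samplePresences(suit, 25, seed = 5)
  expect_equal(nPoints(pts), 25L)
  expect_true(all(cellFromXY(suit, pointCoords(pts))[, 1] == 4))
  expect_true(all(cellFromXY(suit, pointCoords(pts))[, 2] == 7))
  expect_identical(pointCoords(samplePresences(suit, 25, seed = 5)),
                   pointCoords(pts))
  expect_error(samplePresences(withValues(suit, matrix(0, 10, 10)), 5),
               "all-zero")
})

test_that("uniform suitability gives multinomially uniform cell counts", {
  suit <- rasterGrid(matrix(1, 10, 10))
  pts <- samplePresences(suit, 10000, seed = 2)
  cells <- cellFromXY(suit, pointCoords(pts))
  counts <- tabulate(cells[, 1] + (cells[, 2] - 1) * 10, nbins = 100)
  expect_gt(chisq.test(counts)$p.value, 0.001)
})

test_that("protected-area footprints are connected, inside the mask, and labelled", {
  mask <- rasterGrid(matrix(1, 20, 20))
  expect_length(generateProtectedAreas(mask, 0, c(3, 6)), 0L)
  pas <- generateProtectedAreas(mask, 10, c(4, 12), seed = 8, cell_area = 50)
  expect_length(pas, 10L)
  for (pa in pas) {
    cells <- paCells(pa)
    expect_true(all(cells >= 1 & cells[, 1] <= 20 & cells[, 2] <= 20))
    expect_true(paCategory(pa) %in% c("IPA", "SUA", "IL"))
    expect_equal(paArea(pa), nrow(cells) * 50)
    # connectivity: flood fill from the first cell reaches all cells
    key <- paste(cells[, 1], cells[, 2])
    seen <- key[1]; frontier <- key[1]
    while (length(frontier)) {
      rc <- do.call(rbind, strsplit(frontier, " "))
      r <- as.integer(rc[, 1]); c <- as.integer(rc[, 2])
      nb <- paste(c(r - 1, r + 1, r, r), c(c, c, c - 1, c + 1))
      frontier <- setdiff(intersect(nb, key), seen)
      seen <- union(seen, frontier)
    }
    expect_setequal(seen, key)
  }
  expect_error(generateProtectedAreas(mask, 1, c(500, 500)), "size_range")
})

test_that("land cover covers the declared classes and responds to warming", {
  st <- tinyStack(30, 30, 2, seed = 4)
  expect_error(generateLandcover(st, classes = "forest"), "2")
  classes <- c(allowedLandcoverClasses(), "Cropland/grassland mosaic")
  lc <- generateLandcover(st, classes, seed = 1)
  codes <- gridValues(lc)
  expect_true(all(codes[!is.na(codes)] %in% seq_along(classes)))
  # warmer-shifted climate converts forest monotonically with the shift
  openFrac <- vapply(c(0, 1, 2, 4), function(delta) {
    fut <- generateFuture(st, scenarioShift("s", "g",
                                            additive = c(bio01 = delta)))
    mean(gridValues(generateLandcover(fut, classes, seed = 1,
                                      reference = st)) > 5)
  }, numeric(1))
  expect_true(all(diff(openFrac) >= 0))
  expect_gt(openFrac[4], openFrac[1])
})
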