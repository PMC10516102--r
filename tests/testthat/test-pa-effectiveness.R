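paFromCells <- function(cells, id = "pa1", category = "IPA", area = NULL) {
  cells <- matrix(as.integer(cells), ncol = 2)
  new("PAUnit", id = id, category = category, cells = cells,
      area = if (is.null(area)) nrow(cells) * 100 else area)
}

test_that("PA filtering clips to the biome first, then applies the 50 km2 floor", {
  mask <- rasterGrid(matrix(c(rep(1, 50), rep(NA, 50)), 10, 10))  # left half
  areas <- cellAreas(mask, 10)
  small <- paFromCells(cbind(1:4, 1))            # 40 km2 < 50 -> dropped
  ok <- paFromCells(cbind(1:6, 2), id = "pa2")   # 60 km2 -> kept
  straddle <- paFromCells(cbind(rep(3, 6), 3:8), id = "pa3")  # 30 km2 inside
  kept <- filterPAs(list(small, ok, straddle), mask, min_area = 50, areas)
  expect_equal(vapply(kept, paId, ""), "pa2")
  expect_equal(paArea(kept[[1]]), 60)
  # a 49 km2 PA is excluded at the default threshold
  almost <- paFromCells(cbind(1:5, 4), area = 49)
  expect_length(filterPAs(list(almost), mask, cell_areas = matrix(9.8, 10, 10)),
                0L)
  expect_equal(formals(filterPAs)$min_area, 50)
})

test_that("representation targets hit their anchors and interpolate in log area", {
  expect_equal(representationTarget(800), 100)
  expect_equal(representationTarget(1000), 100)
  expect_equal(representationTarget(250000), 10)
  expect_equal(representationTarget(500000), 10)
  # independent oracle at the geometric-mean midpoint: halfway in log space
  expect_equal(representationTarget(sqrt(1000 * 250000)), 55, tolerance = 1e-9)
  # continuity and monotonicity across 10^2..10^7 km2
  areas <- 10^seq(2, 7, length.out = 400)
  t <- representationTarget(areas)
  expect_true(all(diff(t) <= 0))
  expect_true(all(abs(diff(t)) < 2))        # no jumps on a fine grid
  expect_true(all(t >= 10 & t <= 100))
  expect_error(representationTarget(0), "positive")
})

test_that("achieved protection uses union semantics over overlapping PAs", {
  b <- rasterGrid(matrix(0, 6, 6))
  v <- gridValues(b); v[1:3, 1:4] <- 1
  b <- withValues(b, v)
  areas <- cellAreas(b, 100)
  inside <- paFromCells(as.matrix(expand.grid(1:3, 1:4)))
  expect_equal(achievedProtection(b, list(inside), areas), 100)
  outside <- paFromCells(as.matrix(expand.grid(5:6, 5:6)), "pa2")
  expect_equal(achievedProtection(b, list(outside), areas), 0)
  # two overlapping PAs never double count: cell-set oracle
  paA <- paFromCells(as.matrix(expand.grid(1:2, 1:3)), "A")
  paB <- paFromCells(as.matrix(expand.grid(2:3, 2:4)), "B")
  unionCells <- unique(rbind(paCells(paA), paCells(paB)))
  pres <- which(gridValues(b) == 1, arr.ind = TRUE)
  oracle <- 100 * nrow(merge(as.data.frame(unionCells),
                             as.data.frame(pres),
                             by.x = c("V1", "V2"),
                             by.y = c("row", "col"))) / nrow(pres)
  expect_equal(achievedProtection(b, list(paA, paB), areas), oracle)
  expect_error(achievedProtection(withValues(b, matrix(0, 6, 6)),
                                  list(paA), areas), "empty")
})

test_that("gap classification reproduces the 90/70/20 attainment rule", {
  cases <- list(
    # achieved, target, expected category
    list(100, 100, "P"), list(90, 100, "P"), list(89.9, 100, "PP"),
    list(70, 100, "PP"), list(69.9, 100, "G"), list(20, 100, "G"),
    list(19.9, 100, "NP"), list(0, 100, "NP"),
    list(10, 10, "P"), list(9, 10, "P"), list(7.5, 10, "PP"),
    list(7, 10, "PP"), list(6.9, 10, "G"), list(2, 10, "G"),
    list(1.9, 10, "NP"), list(15, 100, "NP"),
    list(45, 50, "P"), list(36, 50, "PP"), list(11, 50, "G"),
    list(9, 50, "NP"))
  for (cs in cases) {
    got <- classifyGap(cs[[1]], cs[[2]])
    expect_equal(got$category, cs[[3]],
                 label = sprintf("achieved=%g target=%g", cs[[1]], cs[[2]]))
    expect_equal(got$attainment, cs[[1]] / cs[[2]] * 100)
  }
  # invariance under common rescaling of achieved and target
  expect_equal(classifyGap(36, 50)$category, classifyGap(72, 100)$category)
})

test_that("randomization preserves the footprint and stays in the domain", {
  mask <- rasterGrid(matrix(1, 12, 12))
  pa <- paFromCells(rbind(c(1, 1), c(1, 2), c(2, 1)))
  for (s in 1:20) {
    moved <- randomizePA(pa, mask, seed = s)
    expect_equal(nrow(paCells(moved)), 3L)
    cells <- paCells(moved)
    expect_true(all(cells >= 1 & cells <= 12))
    # shape preserved: relative offsets unchanged
    rel <- sweep(cells, 2, c(min(cells[, 1]), min(cells[, 2])))
    expect_equal(rel[order(rel[, 1], rel[, 2]), ],
                 rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L)), ignore_attr = TRUE)
  }
  # a domain exactly the PA's size admits only the identity placement
  tight <- rasterGrid(matrix(c(1, 1, 1, NA), 2, 2))
  paL <- paFromCells(rbind(c(1, 1), c(1, 2), c(2, 1)))
  moved <- randomizePA(paL, tight, seed = 3)
  expect_equal(paCells(moved)[order(paCells(moved)[, 1]), ],
               paCells(paL)[order(paCells(paL)[, 1]), ])
  none <- rasterGrid(matrix(c(1, NA, NA, 1), 2, 2))
  expect_error(randomizePA(paL, none), "fit")
})

test_that("random placements are uniform over the open domain", {
  mask <- rasterGrid(matrix(1, 10, 10))
  pa <- paFromCells(rbind(c(1, 1), c(1, 2)))   # 1x2 domino: 90 placements
  draws <- vapply(1:2000, function(s)
    paste(paCells(randomizePA(pa, mask, seed = s))[1, ], collapse = ","),
    character(1))
  counts <- table(draws)
  expect_equal(length(counts), 90L)
  expect_gt(chisq.test(as.vector(counts))$p.value, 0.001)
})

test_that("the null model flags hotspots and not flat landscapes", {
  mask <- rasterGrid(matrix(1, 15, 15))
  flat <- rasterGrid(matrix(4, 15, 15))
  pa <- paFromCells(rbind(c(3, 3), c(3, 4), c(4, 3), c(4, 4)))
  resFlat <- nullModelTest(pa, flat, mask, n = 199, seed = 1)
  expect_equal(resFlat$p_value, 1)
  expect_false(resFlat$effective)
  hot <- matrix(0, 15, 15); hot[3:4, 3:4] <- 5
  resHot <- nullModelTest(pa, rasterGrid(hot), mask, n = 999, seed = 1)
  expect_equal(resHot$p_value, 1 / 1000)
  expect_true(resHot$effective)
  expect_length(resHot$null_stats, 999L)
  # summed-richness variant agrees on the hotspot
  expect_true(nullModelTest(pa, rasterGrid(hot), mask, n = 199, seed = 2,
                            statistic = "sum")$effective)
})

test_that("protected richness proportion matches the cell-sum oracle", {
  set.seed(9)
  rich <- rasterGrid(matrix(rpois(100, 3), 10, 10))
  mask <- onesMask(rich)
  paA <- paFromCells(as.matrix(expand.grid(1:3, 1:3)), "A")
  paB <- paFromCells(as.matrix(expand.grid(3:5, 3:5)), "B")
  got <- protectedRichnessProportion(rich, list(paA, paB), mask)
  u <- unique(rbind(paCells(paA), paCells(paB)))
  oracle <- 100 * sum(gridValues(rich)[u]) / sum(gridValues(rich))
  expect_equal(got, oracle)
  whole <- paFromCells(as.matrix(expand.grid(1:10, 1:10)))
  expect_equal(protectedRichnessProportion(rich, list(whole), mask), 100)
  zeroCells <- which(gridValues(rich) == 0, arr.ind = TRUE)
  if (nrow(zeroCells) > 0) {
    expect_equal(protectedRichnessProportion(
      rich, list(paFromCells(zeroCells[1, , drop = FALSE])), mask), 0)
  }
  expect_error(protectedRichnessProportion(rasterGrid(matrix(0, 2, 2)),
                                           list(paA)), "zero")
})

test_that("PA rasters and sidecars round-trip", {
  mask <- rasterGrid(matrix(1, 8, 8))
  pas <- generateProtectedAreas(mask, 3, c(3, 6), seed = 5, cell_area = 25)
  rf <- tempfile(fileext = ".asc"); cf <- tempfile(fileext = ".csv")
  writePAs(pas, mask, rf, cf)
  back <- readPAs(rf, cf)
  expect_length(back, 3L)
  expect_equal(vapply(back, paCategory, ""), vapply(pas, paCategory, ""))
  expect_equal(vapply(back, paArea, 1), vapply(pas, paArea, 1))
})
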