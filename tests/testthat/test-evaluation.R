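test_that("confusion counts match an exhaustive tally", {
  obs <- c(rep("presence", 6), rep("pseudo_absence", 4))
  pred <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE)
  cc <- confusionCounts(pred, obs)
  # brute-force count
  expect_equal(unname(cc["TP"]), sum(pred & obs == "presence"))
  expect_equal(unname(cc["FP"]), sum(pred & obs != "presence"))
  expect_equal(unname(cc["FN"]), sum(!pred & obs == "presence"))
  expect_equal(unname(cc["TN"]), sum(!pred & obs != "presence"))
  expect_equal(sum(cc), 10)
  perfect <- confusionCounts(obs == "presence", obs)
  expect_equal(unname(perfect[c("FP", "FN")]), c(0L, 0L))
  inverted <- confusionCounts(obs != "presence", obs)
  expect_equal(unname(inverted[c("TP", "TN")]), c(0L, 0L))
  expect_error(confusionCounts(logical(0), character(0)), "empty")
})

test_that("Jaccard follows TP/(TP+FP+FN)", {
  expect_equal(jaccardIndex(c(TP = 5, FP = 0, FN = 0)), 1)
  expect_equal(jaccardIndex(c(TP = 3, FP = 1, FN = 1)), 0.6)
  expect_equal(jaccardIndex(c(TP = 0, FP = 2, FN = 3)), 0)
  expect_error(jaccardIndex(c(TP = 0, FP = 0, FN = 0)), "undefined")
})

test_that("AUC handles separation, ties, and the enumerated toy", {
  lab <- c("presence", "presence", "pseudo_absence", "pseudo_absence")
  expect_equal(aucScore(c(0.9, 0.8, 0.2, 0.1), lab), 1)
  expect_equal(aucScore(rep(0.5, 4), lab), 0.5)
  # presences {0.9, 0.4} vs absences {0.8, 0.1}: 3 wins of 4 pairs
  expect_equal(aucScore(c(0.9, 0.4, 0.8, 0.1), lab), 0.75)
  expect_error(aucScore(1:3, rep("presence", 3)), "both classes")
})

test_that("AUC equals the normalized Mann-Whitney U on random test sets", {
  set.seed(33)
  for (i in 1:100) {
    n1 <- sample(3:20, 1); n0 <- sample(3:20, 1)
    s <- c(rnorm(n1, 0.5), rnorm(n0))
    if (i %% 3 == 0) s <- round(s, 1)  # force ties regularly
    lab <- rep(c("presence", "pseudo_absence"), c(n1, n0))
    u <- suppressWarnings(wilcox.test(s[lab == "presence"],
                                      s[lab != "presence"])$statistic)
    expect_equal(aucScore(s, lab), unname(u) / (n1 * n0))
  }
})

test_that("max-Jaccard threshold matches the exhaustive scan", {
  set.seed(44)
  for (i in 1:60) {
    n <- sample(6:14, 1)
    s <- round(runif(n), 2)
    lab <- sample(rep(c("presence", "pseudo_absence"), length.out = n))
    if (length(unique(lab)) < 2) next
    got <- maxJaccardThreshold(s, lab)
    want <- bruteMaxJaccard(s, lab)
    expect_equal(got$jaccard, want$jaccard)
    expect_equal(got$threshold, want$threshold)
  }
  # separable scores: the lowest presence score achieves J = 1
  s <- c(0.7, 0.8, 0.9, 0.1, 0.2, 0.3)
  lab <- rep(c("presence", "pseudo_absence"), each = 3)
  got <- maxJaccardThreshold(s, lab)
  expect_equal(got$jaccard, 1)
  expect_equal(got$threshold, 0.7)
  # anti-separated scores still match the brute-force maximum
  gotInv <- maxJaccardThreshold(s, rev(lab))
  expect_equal(gotInv$jaccard, bruteMaxJaccard(s, rev(lab))$jaccard)
})

test_that("binarization respects the threshold, nodata, and round-trips", {
  m <- rasterGrid(matrix(c(0.1, 0.5, 0.9, NA), 2, 2))
  expect_equal(sum(gridValues(binarizeMap(m, 0)) == 1, na.rm = TRUE), 3)
  expect_equal(sum(gridValues(binarizeMap(m, 0.95)) == 1, na.rm = TRUE), 0)
  expect_true(is.na(gridValues(binarizeMap(m, 0.5))[2, 2]))
  # thresholding at the max-Jaccard cutoff reproduces its confusion counts
  set.seed(2)
  s <- runif(20)
  lab <- rep(c("presence", "pseudo_absence"), 10)
  mj <- maxJaccardThreshold(s, lab)
  cc <- confusionCounts(s >= mj$threshold, lab)
  expect_equal(jaccardIndex(cc), mj$jaccard)
})

test_that("the above-mean rule selects members and averages their maps", {
  maps <- list(a = rasterGrid(matrix(0.9, 2, 2)),
               b = rasterGrid(matrix(0.5, 2, 2)),
               c = rasterGrid(matrix(0.1, 2, 2)))
  ens <- buildEnsemble(maps, c(a = 0.9, b = 0.8, c = 0.4), "sp")
  expect_equal(ens@meanScore, 0.7)
  expect_setequal(ens@members, c("a", "b"))
  expect_equal(gridValues(ens@map)[1, 1], 0.7)  # mean of 0.9 and 0.5
  # all-equal scores: everyone is a member
  all3 <- buildEnsemble(maps, c(a = 0.5, b = 0.5, c = 0.5), "sp")
  expect_setequal(all3@members, c("a", "b", "c"))
  solo <- buildEnsemble(maps["a"], c(a = 0.8), "sp")
  expect_equal(solo@members, "a")
  expect_equal(gridValues(solo@map), gridValues(maps$a))
})

test_that("cross-validation produces per-fold scores and a thresholded ensemble", {
  set.seed(71)
  st <- climateStack(list(axis1 = rasterGrid(matrix(rnorm(400), 20, 20)),
                          axis2 = rasterGrid(matrix(rnorm(400), 20, 20))))
  cells <- cbind(sample(1:20, 60, TRUE), sample(1:20, 60, TRUE))
  x1 <- gridValues(getLayer(st, "axis1"))[cells]
  lab <- ifelse(x1 + rnorm(60, 0, 0.4) > 0, "presence", "pseudo_absence")
  pts <- extractEnv(labeledPoints("sp", cellCenters(st@layers[[1]], cells),
                                  label = lab), st)
  pts <- initialize(pts, fold = rep(1:3, 20))
  run <- runSDM(pts, st, algorithms = c("glm", "rf"), seed = 5)
  expect_equal(nrow(run$evaluation), 6)  # 2 algorithms x 3 folds
  expect_true(all(run$evaluation$auc >= 0 & run$evaluation$auc <= 1,
                  na.rm = TRUE))
  ens <- run$ensemble
  expect_true(all(gridValues(ens@map) >= 0 & gridValues(ens@map) <= 1))
  expect_true(all(gridValues(ens@binaryMap) %in% c(0, 1)))
  expect_equal(gridValues(ens@binaryMap),
               gridValues(binarizeMap(ens@map, ens@threshold)))
  # scores are the mean per-algorithm test Jaccard
  agg <- tapply(run$evaluation$jaccard, run$evaluation$algorithm, mean)
  expect_equal(run$scores[names(agg)], c(agg))
  # projection onto another stack reuses members and threshold
  st2 <- climateStack(list(axis1 = rasterGrid(matrix(rnorm(400), 20, 20)),
                           axis2 = rasterGrid(matrix(rnorm(400), 20, 20))),
                      scenario = "rcp85:gcm1")
  fut <- projectEnsemble(run, st2)
  expect_equal(fut@threshold, ens@threshold)
  expect_equal(fut@members, ens@members)
  expect_equal(scenarioTag(st2), fut@scenario)
})
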