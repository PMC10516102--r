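#' Confusion counts at test points
#'
#' @param pred logical (or 0/1) predicted presence per test point.
#' @param labels observed labels (`"presence"`/`"pseudo_absence"`, or
#'   logical/0-1).
#' @return named vector `c(TP, FP, FN, TN)`.
#' @export
confusionCounts <- function(pred, labels) {
  if (length(pred) == 0) stop("empty test set", call. = FALSE)
  if (length(pred) != length(labels)) stop("length mismatch", call. = FALSE)
  obs <- if (is.character(labels)) labels == "presence" else as.logical(labels)
  pred <- as.logical(pred)
  c(TP = sum(pred & obs), FP = sum(pred & !obs),
    FN = sum(!pred & obs), TN = sum(!pred & !obs))
}

#' Jaccard similarity from confusion counts
#'
#' `J = TP / (TP + FP + FN)`: the overlap between predicted and observed
#' presences, penalizing both false presences and false absences; 1 is
#' perfect correspondence.
#'
#' @param counts output of [confusionCounts()] (or any vector with named
#'   `TP`, `FP`, `FN` entries).
#' @return Jaccard index in \[0, 1\].
#' @export
jaccardIndex <- function(counts) {
  denom <- counts[["TP"]] + counts[["FP"]] + counts[["FN"]]
  if (denom == 0)
    stop("Jaccard undefined: no predicted or observed presences", call. = FALSE)
  unname(counts[["TP"]] / denom)
}

#' Rank-based AUC
#'
#' The area under the ROC curve computed as the probability that a random
#' presence outscores a random absence, with ties counting one half — the
#' normalized Mann-Whitney U statistic.
#'
#' @param scores continuous suitability at test points.
#' @param labels observed labels (as in [confusionCounts()]).
#' @return AUC in \[0, 1\].
#' @export
aucScore <- function(scores, labels) {
  obs <- if (is.character(labels)) labels == "presence" else as.logical(labels)
  n1 <- sum(obs); n0 <- sum(!obs)
  if (n1 == 0 || n0 == 0)
    stop("AUC needs both classes in the test set", call. = FALSE)
  r <- rank(scores)
  (sum(r[obs]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold maximizing the Jaccard index
#'
#' Scans the unique observed scores as candidate cutoffs and returns the
#' one whose induced binary prediction (`score >= threshold`) maximizes
#' Jaccard against the labels; ties break to the lowest threshold.
#'
#' @inheritParams aucScore
#' @return list with `threshold` and `jaccard` (the maximum achieved).
#' @export
maxJaccardThreshold <- function(scores, labels) {
  obs <- if (is.character(labels)) labels == "presence" else as.logical(labels)
  if (all(obs) || !any(obs))
    stop("threshold selection needs both classes", call. = FALSE)
  cand <- sort(unique(scores))
  js <- vapply(cand, function(t) {
    cc <- confusionCounts(scores >= t, obs)
    if (cc[["TP"]] + cc[["FP"]] + cc[["FN"]] == 0) 0 else jaccardIndex(cc)
  }, numeric(1))
  best <- which(js == max(js))[1]   # lowest threshold among ties
  list(threshold = cand[best], jaccard = js[best])
}

#' Binarize a suitability map
#'
#' @param map continuous [RasterGrid-class].
#' @param threshold cutoff; cells with `suitability >= threshold` become 1,
#'   others 0, nodata stays nodata.
#' @return a 0/1 [RasterGrid-class].
#' @export
binarizeMap <- function(map, threshold) {
  stopifnot(is.finite(threshold))
  withValues(map, ifelse(is.na(map@values), NA,
                         as.numeric(map@values >= threshold)))
}

#' Build the above-mean ensemble
#'
#' The selection cutoff is the simple mean of the per-algorithm scores;
#' algorithms scoring strictly above it become ensemble members and the
#' ensemble map is the unweighted cell-wise mean of their suitability maps.
#' If no algorithm exceeds the mean (all scores equal), every algorithm is
#' a member.
#'
#' @param maps named list of per-algorithm suitability
#'   [RasterGrid-class] maps.
#' @param scores named per-algorithm selection scores (here: mean test
#'   Jaccard).
#' @param species,scenario identifiers recorded in the result.
#' @return An [EnsembleResult-class] (threshold/binary map unset; see
#'   [thresholdEnsemble()]).
#' @export
buildEnsemble <- function(maps, scores, species = "species",
                          scenario = "present") {
  stopifnot(length(maps) >= 1, identical(sort(names(maps)), sort(names(scores))))
  cutoff <- mean(scores)
  members <- names(scores)[scores > cutoff]
  if (length(members) == 0) members <- names(scores)
  acc <- Reduce(`+`, lapply(maps[members], gridValues))
  ens <- withValues(maps[[1]], acc / length(members))
  new("EnsembleResult", species = species, scenario = scenario,
      members = members, memberScores = scores, meanScore = cutoff,
      map = ens, threshold = NA_real_, binaryMap = ens)
}

#' Set the ensemble's max-Jaccard threshold and binary map
#'
#' The species-specific threshold maximizes the Jaccard index of the
#' ensemble suitability at the evaluation points; future-scenario ensembles
#' reuse the present-day threshold (the future has no test data).
#'
#' @param ensemble an [EnsembleResult-class].
#' @param points evaluation [LabeledPoints-class]; ignored when
#'   `threshold` is given.
#' @param threshold optional fixed threshold (present-day reuse).
#' @return the ensemble with `threshold` and `binaryMap` filled.
#' @export
thresholdEnsemble <- function(ensemble, points = NULL, threshold = NULL) {
  if (is.null(threshold)) {
    cells <- cellFromXY(ensemble@map, pointCoords(points))
    s <- ensemble@map@values[cells]
    threshold <- maxJaccardThreshold(s, pointLabels(points))$threshold
  }
  initialize(ensemble, threshold = threshold,
             binaryMap = binarizeMap(ensemble@map, threshold))
}

setMethod("show", "EnsembleResult", function(object) {
  cat(sprintf("EnsembleResult '%s' (%s): %d/%d members above mean score %.3f\n",
              object@species, object@scenario, length(object@members),
              length(object@memberScores), object@meanScore))
  cat("  members:", paste(object@members, collapse = ", "), "\n")
  if (!is.na(object@threshold))
    cat(sprintf("  threshold %.3f -> %d presence cells\n", object@threshold,
                sum(object@binaryMap@values == 1, na.rm = TRUE)))
})

#' Cross-validate all algorithms and assemble the present-day ensemble
#'
#' For each algorithm: fit on every training fold, score the held-out fold
#' (max-Jaccard threshold, Jaccard, AUC), and average the per-fold
#' prediction maps into one suitability map. Per-algorithm selection scores
#' (mean test Jaccard) then drive the above-mean ensemble, and the
#' species-specific max-Jaccard threshold — computed from the ensemble
#' suitability at all evaluation points — yields the binary range.
#'
#' @param points presence/pseudo-absence [LabeledPoints-class] with env and
#'   folds.
#' @param stack predictor [ClimateStack-class] (present day).
#' @param algorithms algorithm ids (default all five).
#' @param seed integer seed.
#' @return list of class `SDMRun`: `species`, `evaluation` (data.frame:
#'   species, algorithm, fold, jaccard, auc, threshold), `scores`,
#'   `fits` (per algorithm, per fold), `maps` (per algorithm), and
#'   `ensemble` (present-day [EnsembleResult-class], thresholded).
#' @export
runSDM <- function(points, stack, algorithms = sdmAlgorithms(), seed = 1) {
  folds <- sort(unique(pointFolds(points)))
  bg <- drawBackground(stack, seed = deriveSeed(seed, "background"))
  evalRows <- list(); fits <- list(); maps <- list(); scores <- numeric()
  for (alg in algorithms) {
    algFits <- fitAlgorithmFolds(alg, points, seed = deriveSeed(seed, alg),
                                 background = bg)
    foldMaps <- list(); jacc <- numeric()
    for (f in names(algFits)) {
      fit <- algFits[[f]]
      test <- points[pointFolds(points) == as.integer(f)]
      s <- predictSuitability(fit, pointEnv(test))
      lab <- pointLabels(test)
      if (length(unique(lab)) < 2L) {
        evalRows[[length(evalRows) + 1L]] <- data.frame(
          species = speciesId(points), algorithm = alg, fold = as.integer(f),
          jaccard = NA_real_, auc = NA_real_, threshold = NA_real_)
      } else {
        mj <- maxJaccardThreshold(s, lab)
        evalRows[[length(evalRows) + 1L]] <- data.frame(
          species = speciesId(points), algorithm = alg, fold = as.integer(f),
          jaccard = mj$jaccard, auc = aucScore(s, lab),
          threshold = mj$threshold)
        jacc <- c(jacc, mj$jaccard)
      }
      foldMaps[[f]] <- predictMap(fit, stack)
    }
    fits[[alg]] <- algFits
    maps[[alg]] <- withValues(foldMaps[[1]],
      Reduce(`+`, lapply(foldMaps, gridValues)) / length(foldMaps))
    scores[alg] <- if (length(jacc)) mean(jacc) else 0
  }
  ens <- buildEnsemble(maps, scores, species = speciesId(points),
                       scenario = scenarioTag(stack))
  ens <- thresholdEnsemble(ens, points)
  structure(list(species = speciesId(points),
                 evaluation = do.call(rbind, evalRows),
                 scores = scores, fits = fits, maps = maps, ensemble = ens),
            class = "SDMRun")
}

#' Project a fitted run onto another (future) climate stack
#'
#' Member algorithms and the binarization threshold are those of the
#' present-day run: per member, fold fits are predicted on the new stack
#' and averaged; members are averaged into the ensemble map; the present
#' threshold produces the binary range.
#'
#' @param run an `SDMRun` from [runSDM()].
#' @param stack a future [ClimateStack-class] (same predictors).
#' @return an [EnsembleResult-class] tagged with the stack's scenario.
#' @export
projectEnsemble <- function(run, stack) {
  memberMaps <- lapply(run$fits[run$ensemble@members], function(algFits) {
    fm <- lapply(algFits, predictMap, stack = stack)
    withValues(fm[[1]], Reduce(`+`, lapply(fm, gridValues)) / length(fm))
  })
  acc <- Reduce(`+`, lapply(memberMaps, gridValues))
  map <- withValues(memberMaps[[1]], acc / length(memberMaps))
  ens <- new("EnsembleResult", species = run$species,
             scenario = scenarioTag(stack), members = run$ensemble@members,
             memberScores = run$ensemble@memberScores,
             meanScore = run$ensemble@meanScore, map = map,
             threshold = NA_real_, binaryMap = map)
  thresholdEnsemble(ens, threshold = run$ensemble@threshold)
}
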