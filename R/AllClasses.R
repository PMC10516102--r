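#' @import methods
NULL

#' RasterGrid: a single-band raster layer
#'
#' Minimal raster container used throughout the package: a numeric matrix of
#' cell values plus a geotransform (lower-left corner and square cell size).
#' Row 1 is the top (northernmost) row, matching the usual on-screen raster
#' orientation. Missing cells (nodata) are `NA`.
#'
#' @slot values numeric matrix of cell values; `NA` = nodata.
#' @slot xmin,ymin coordinates of the lower-left corner of the grid.
#' @slot cellsize side length of a (square) cell, in map units.
#'
#' @seealso [rasterGrid()], [readAsciiGrid()], [writeAsciiGrid()]
#' @export
setClass("RasterGrid",
  representation(values = "matrix", xmin = "numeric", ymin = "numeric",
                 cellsize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@values)) msg <- c(msg, "values must be numeric")
    if (length(object@cellsize) != 1L || !is.finite(object@cellsize) ||
        object@cellsize <= 0)
      msg <- c(msg, "cellsize must be a single positive number")
    if (length(object@xmin) != 1L || length(object@ymin) != 1L)
      msg <- c(msg, "xmin and ymin must be scalars")
    if (length(msg)) msg else TRUE
  })

#' ClimateStack: named, co-registered raster layers with a scenario tag
#'
#' A set of [RasterGrid-class] layers sharing one grid, tagged with the
#' climate scenario they represent (e.g. `"present"`, `"rcp45:gcm1"`).
#'
#' @slot layers named list of `RasterGrid` objects, all co-registered.
#' @slot scenario single character scenario tag.
#' @export
setClass("ClimateStack",
  representation(layers = "list", scenario = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@layers) == 0L) msg <- c(msg, "stack has no layers")
    if (is.null(names(object@layers)) || anyDuplicated(names(object@layers)) ||
        any(!nzchar(names(object@layers))))
      msg <- c(msg, "layers must have unique non-empty names")
    if (!all(vapply(object@layers, is, logical(1), "RasterGrid")))
      msg <- c(msg, "all layers must be RasterGrid objects")
    if (length(object@layers) > 1L) {
      ref <- object@layers[[1L]]
      same <- vapply(object@layers[-1L], function(l) isCoRegistered(ref, l),
                     logical(1))
      if (!all(same)) msg <- c(msg, "layers are not co-registered")
    }
    if (length(object@scenario) != 1L)
      msg <- c(msg, "scenario must be a single string")
    if (length(msg)) msg else TRUE
  })

#' LabeledPoints: occurrence and pseudo-absence coordinates
#'
#' Point records for one species: coordinates, a presence/pseudo-absence
#' label, an optional cross-validation fold, and (optionally) the predictor
#' values extracted at each point.
#'
#' @slot species single species identifier.
#' @slot coords n x 2 matrix with columns `x`, `y`.
#' @slot label character vector, `"presence"` or `"pseudo_absence"`.
#' @slot fold integer fold labels (`NA` when unassigned).
#' @slot env n x p matrix of predictor values (0 columns when unset).
#' @export
setClass("LabeledPoints",
  representation(species = "character", coords = "matrix",
                 label = "character", fold = "integer", env = "matrix"),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@coords)
    if (ncol(object@coords) != 2L) msg <- c(msg, "coords must be n x 2")
    if (length(object@label) != n) msg <- c(msg, "label length != point count")
    if (!all(object@label %in% c("presence", "pseudo_absence")))
      msg <- c(msg, "labels must be 'presence' or 'pseudo_absence'")
    if (length(object@fold) != n) msg <- c(msg, "fold length != point count")
    if (nrow(object@env) != n && ncol(object@env) > 0L)
      msg <- c(msg, "env row count != point count")
    if (length(object@species) != 1L) msg <- c(msg, "species must be scalar")
    if (length(msg)) msg else TRUE
  })

#' PCATransform: fitted principal-component reduction of the climate layers
#'
#' Stores everything needed to project any (present or future) climate stack
#' into the axis space fitted on present-day data: per-variable means and
#' standard deviations, orthonormal loadings, the per-axis explained-variance
#' fractions, and the number of retained axes.
#'
#' @slot variableNames ordered predictor names the transform expects.
#' @slot means,sds per-variable standardization constants (present data).
#' @slot loadings variables x axes orthonormal loading matrix.
#' @slot explained per-axis fraction of total variance, non-increasing.
#' @slot nAxes number of axes retained to reach `varianceThreshold`.
#' @slot varianceThreshold cumulative explained-variance target (default 0.95).
#' @export
setClass("PCATransform",
  representation(variableNames = "character", means = "numeric",
                 sds = "numeric", loadings = "matrix", explained = "numeric",
                 nAxes = "integer", varianceThreshold = "numeric"),
  validity = function(object) {
    p <- length(object@variableNames)
    msg <- character()
    if (length(object@means) != p || length(object@sds) != p)
      msg <- c(msg, "means/sds length mismatch")
    if (any(object@sds <= 0)) msg <- c(msg, "sds must be positive")
    if (nrow(object@loadings) != p) msg <- c(msg, "loadings rows != variables")
    if (is.unsorted(rev(object@explained)))
      msg <- c(msg, "explained fractions must be non-increasing")
    if (object@nAxes < 1L || object@nAxes > ncol(object@loadings))
      msg <- c(msg, "nAxes out of range")
    if (length(msg)) msg else TRUE
  })

#' SDMFit: one fitted suitability algorithm
#'
#' @slot algorithm one of `"glm"`, `"maxent_like"`, `"rf"`, `"svm"`, `"gau"`.
#' @slot species species identifier.
#' @slot model the fitted backend object (opaque).
#' @slot predictorNames predictors the model expects, in order.
#' @slot fold training fold the model was fitted on (`NA` = all data).
#' @export
setClass("SDMFit",
  representation(algorithm = "character", species = "character",
                 model = "ANY", predictorNames = "character",
                 fold = "integer"),
  validity = function(object) {
    if (!object@algorithm %in% sdmAlgorithms())
      return(sprintf("unknown algorithm '%s'; valid: %s", object@algorithm,
                     paste(sdmAlgorithms(), collapse = ", ")))
    TRUE
  })

#' EnsembleResult: the above-mean ensemble for one species and scenario
#'
#' @slot species,scenario identifiers.
#' @slot members algorithms whose score exceeded the mean score.
#' @slot memberScores named per-algorithm selection scores (all algorithms).
#' @slot meanScore the selection cutoff (mean of all algorithm scores).
#' @slot map cell-wise mean of the member suitability maps.
#' @slot threshold max-Jaccard binarization threshold.
#' @slot binaryMap `map >= threshold` as a 0/1 [RasterGrid-class].
#' @export
setClass("EnsembleResult",
  representation(species = "character", scenario = "character",
                 members = "character", memberScores = "numeric",
                 meanScore = "numeric", map = "RasterGrid",
                 threshold = "numeric", binaryMap = "RasterGrid"),
  validity = function(object) {
    if (length(object@members) == 0L) return("ensemble has no members")
    TRUE
  })

#' PAUnit: one protected area as a connected set of grid cells
#'
#' @slot id protected-area identifier.
#' @slot category management category: `"IPA"` (integral protection),
#'   `"SUA"` (sustainable use) or `"IL"` (indigenous land).
#' @slot cells n x 2 integer matrix of (row, col) grid cells.
#' @slot area total area in km2.
#' @export
setClass("PAUnit",
  representation(id = "character", category = "character", cells = "matrix",
                 area = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@category %in% c("IPA", "SUA", "IL"))
      msg <- c(msg, "category must be one of IPA, SUA, IL")
    if (ncol(object@cells) != 2L) msg <- c(msg, "cells must be n x 2")
    if (nrow(object@cells) > 0L && object@area <= 0)
      msg <- c(msg, "area must be positive")
    if (length(msg)) msg else TRUE
  })
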