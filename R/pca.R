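#' Fit a principal-component reduction of the climate layers
#'
#' Correlation-matrix PCA (each variable centred and scaled, since
#' bioclimatic layers mix degrees Celsius and millimetres) on the cell
#' values inside the study mask. The number of retained axes is the
#' smallest `k` whose cumulative explained variance reaches
#' `variance_threshold` (default 0.95). For reproducibility across linear
#' algebra backends, the sign of each axis is fixed so its
#' largest-magnitude loading is positive.
#'
#' Future stacks must be projected with [projectStack()], which reuses the
#' present-day means, standard deviations and loadings, keeping present and
#' future scores in one common space.
#'
#' @param present present-day [ClimateStack-class].
#' @param mask study-area [RasterGrid-class] (`NULL` = all cells); cells
#'   that are `NA` or 0 in the mask are excluded from fitting.
#' @param variance_threshold cumulative explained-variance target.
#' @return A [PCATransform-class].
#' @export
fitPCA <- function(present, mask = NULL, variance_threshold = 0.95) {
  X <- stackValues(present)
  keep <- stats::complete.cases(X)
  if (!is.null(mask)) keep <- keep & as.vector(maskInterior(mask))
  if (!any(keep)) stop("mask excludes every cell", call. = FALSE)
  X <- X[keep, , drop = FALSE]
  if (ncol(X) < 2) stop("need at least 2 layers", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat))
    stop("constant layer(s) cannot be standardized: ",
         paste(colnames(X)[flat], collapse = ", "), call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  # sign convention: dominant loading of each axis positive
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  loadings <- sweep(pc$rotation, 2, flip, "*")
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  nAxes <- which(cumsum(explained) >= variance_threshold - 1e-12)[1]
  new("PCATransform", variableNames = colnames(X), means = pc$center,
      sds = pc$scale, loadings = loadings, explained = explained,
      nAxes = as.integer(nAxes), varianceThreshold = variance_threshold)
}

#' @rdname fitPCA
#' @param x,object a `PCATransform`.
#' @export
nAxes <- function(x) x@nAxes

#' @rdname fitPCA
#' @export
explainedVariance <- function(x) x@explained

setMethod("show", "PCATransform", function(object) {
  cat(sprintf("PCATransform: %d variables -> %d axes (%.1f%% of variance, threshold %.0f%%)\n",
              length(object@variableNames), object@nAxes,
              100 * sum(object@explained[seq_len(object@nAxes)]),
              100 * object@varianceThreshold))
})

#' Project a climate stack onto fitted axes
#'
#' Scores are `((x - means) / sds) %*% loadings`, truncated to the retained
#' axes. The standardization constants and loadings are always those fitted
#' on present-day data, so future anomalies appear as displacements in the
#' same axis space rather than re-rotating it. Nodata cells project to
#' nodata.
#'
#' @param stack a [ClimateStack-class] containing every fitted variable.
#' @param transform a [PCATransform-class] from [fitPCA()].
#' @return a [ClimateStack-class] of axis layers `axis1 ... axisK`, keeping
#'   the input's scenario tag.
#' @export
projectStack <- function(stack, transform) {
  missing <- setdiff(transform@variableNames, layerNames(stack))
  if (length(missing))
    stop("stack is missing fitted variables: ",
         paste(missing, collapse = ", "), call. = FALSE)
  X <- stackValues(stack, transform@variableNames)
  Z <- sweep(sweep(X, 2, transform@means), 2, transform@sds, "/")
  S <- Z %*% transform@loadings[, seq_len(transform@nAxes), drop = FALSE]
  ref <- stack@layers[[1]]
  layers <- lapply(seq_len(ncol(S)), function(k)
    withValues(ref, matrix(S[, k], nrow(ref@values), ncol(ref@values))))
  names(layers) <- sprintf("axis%d", seq_len(ncol(S)))
  climateStack(layers, scenario = stack@scenario)
}

#' Serialize / restore a PCATransform as JSON
#'
#' @param transform a [PCATransform-class].
#' @param file JSON path.
#' @export
writePCATransform <- function(transform, file) {
  jsonlite::write_json(list(
    variable_names = transform@variableNames,
    means = unname(transform@means), sds = unname(transform@sds),
    loadings = unname(transform@loadings),
    explained = transform@explained, n_axes = transform@nAxes,
    variance_threshold = transform@varianceThreshold),
    file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname writePCATransform
#' @export
readPCATransform <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  new("PCATransform", variableNames = j$variable_names,
      means = stats::setNames(j$means, j$variable_names),
      sds = stats::setNames(j$sds, j$variable_names),
      loadings = j$loadings, explained = j$explained,
      nAxes = as.integer(j$n_axes),
      varianceThreshold = j$variance_threshold)
}
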