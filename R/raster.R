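#' Create a RasterGrid
#'
#' @param values numeric matrix (row 1 = top row); `NA` marks nodata.
#' @param xmin,ymin lower-left corner coordinates.
#' @param cellsize square cell side length in map units.
#' @return A [RasterGrid-class].
#' @examples
#' r <- rasterGrid(matrix(1:12, 3, 4))
#' gridDim(r)
#' @export
rasterGrid <- function(values, xmin = 0, ymin = 0, cellsize = 1) {
  storage.mode(values) <- "double"
  new("RasterGrid", values = values, xmin = as.numeric(xmin),
      ymin = as.numeric(ymin), cellsize = as.numeric(cellsize))
}

#' @rdname rasterGrid
#' @param x,object a `RasterGrid`.
#' @export
gridValues <- function(x) x@values

#' @rdname rasterGrid
#' @export
gridDim <- function(x) dim(x@values)

#' @rdname rasterGrid
#' @export
cellSize <- function(x) x@cellsize

#' Test whether two grids share the same geometry
#'
#' @param a,b `RasterGrid` objects.
#' @return `TRUE` if dimensions, origin and cell size all match.
#' @export
isCoRegistered <- function(a, b) {
  identical(dim(a@values), dim(b@values)) &&
    isTRUE(all.equal(c(a@xmin, a@ymin, a@cellsize),
                     c(b@xmin, b@ymin, b@cellsize)))
}

stopIfNotCoRegistered <- function(a, b, what = "rasters") {
  if (!isCoRegistered(a, b))
    stop(what, " are not co-registered (grid geometry mismatch)", call. = FALSE)
  invisible(TRUE)
}

#' Replace the value matrix of a grid, keeping its geometry
#' @param x a `RasterGrid` template.
#' @param values replacement matrix of the same dimensions.
#' @export
withValues <- function(x, values) {
  stopifnot(identical(dim(values), dim(x@values)))
  storage.mode(values) <- "double"
  initialize(x, values = values)
}

#' Cell-center coordinates
#'
#' @param x a `RasterGrid`.
#' @param cells optional n x 2 (row, col) matrix; default all cells in
#'   column-major order.
#' @return n x 2 matrix with columns `x`, `y`.
#' @export
cellCenters <- function(x, cells = NULL) {
  d <- dim(x@values)
  if (is.null(cells)) {
    cells <- cbind(rep(seq_len(d[1]), d[2]), rep(seq_len(d[2]), each = d[1]))
  }
  cbind(x = x@xmin + (cells[, 2] - 0.5) * x@cellsize,
        y = x@ymin + (d[1] - cells[, 1] + 0.5) * x@cellsize)
}

#' Locate points on the grid
#'
#' @param x a `RasterGrid`.
#' @param xy n x 2 matrix of x/y coordinates.
#' @return n x 2 integer matrix of (row, col); `NA` rows for points outside
#'   the grid extent.
#' @export
cellFromXY <- function(x, xy) {
  d <- dim(x@values)
  col <- floor((xy[, 1] - x@xmin) / x@cellsize) + 1L
  rowFromBottom <- floor((xy[, 2] - x@ymin) / x@cellsize) + 1L
  row <- d[1] - rowFromBottom + 1L
  bad <- col < 1L | col > d[2] | row < 1L | row > d[1]
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Per-cell areas
#'
#' Uniform synthetic grids carry one area per cell; geographic (degree)
#' grids weight by the cosine of cell-center latitude, the usual equal-angle
#' approximation.
#'
#' @param x a `RasterGrid`.
#' @param cell_area area of one cell in km2 (uniform grids), or `NULL` to
#'   use cosine-latitude weighting with `km_per_degree`.
#' @param km_per_degree kilometres per degree at the equator (default 111.32).
#' @return matrix of per-cell areas (km2) matching `dim(gridValues(x))`.
#' @export
cellAreas <- function(x, cell_area = NULL, km_per_degree = 111.32) {
  d <- dim(x@values)
  if (!is.null(cell_area)) {
    stopifnot(cell_area > 0)
    return(matrix(cell_area, d[1], d[2]))
  }
  lat <- x@ymin + (d[1] - seq_len(d[1]) + 0.5) * x@cellsize
  rowArea <- (x@cellsize * km_per_degree)^2 * cos(lat * pi / 180)
  matrix(rowArea, d[1], d[2])
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text single-band raster exchange format (`ncols`/`nrows`/
#' `xllcorner`/`yllcorner`/`cellsize`/`NODATA_value` header followed by the
#' value matrix, top row first).
#'
#' @param file path to an `.asc` file.
#' @return `readAsciiGrid` returns a [RasterGrid-class]; `writeAsciiGrid`
#'   returns `file` invisibly.
#' @export
readAsciiGrid <- function(file) {
  hdr <- readLines(file, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  vals <- scan(file, skip = 6L, quiet = TRUE)
  m <- matrix(vals, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
  if (!is.na(h[["nodata_value"]])) m[m == h[["nodata_value"]]] <- NA
  rasterGrid(m, xmin = h[["xllcorner"]], ymin = h[["yllcorner"]],
             cellsize = h[["cellsize"]])
}

#' @rdname readAsciiGrid
#' @param x a `RasterGrid` to write.
#' @param nodata value used to encode `NA` cells on disk.
#' @export
writeAsciiGrid <- function(x, file, nodata = -9999) {
  d <- dim(x@values)
  hdr <- c(sprintf("ncols %d", d[2]), sprintf("nrows %d", d[1]),
           sprintf("xllcorner %.10g", x@xmin),
           sprintf("yllcorner %.10g", x@ymin),
           sprintf("cellsize %.10g", x@cellsize),
           sprintf("NODATA_value %.10g", nodata))
  m <- x@values
  m[is.na(m)] <- nodata
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                        collapse = " "))
  writeLines(c(hdr, body), file)
  invisible(file)
}

setMethod("show", "RasterGrid", function(object) {
  d <- dim(object@values)
  v <- object@values[!is.na(object@values)]
  cat(sprintf("RasterGrid: %d x %d cells, cellsize %g, origin (%g, %g)\n",
              d[1], d[2], object@cellsize, object@xmin, object@ymin))
  if (length(v))
    cat(sprintf("  values: min %.4g, mean %.4g, max %.4g (%d nodata)\n",
                min(v), mean(v), max(v), sum(is.na(object@values))))
  else cat("  values: all nodata\n")
})

# ---- ClimateStack --------------------------------------------------------

#' Create a ClimateStack
#'
#' @param layers named list of co-registered [RasterGrid-class] layers.
#' @param scenario scenario tag, e.g. `"present"` or `"rcp85:gcm3"`.
#' @return A [ClimateStack-class].
#' @export
climateStack <- function(layers, scenario = "present") {
  new("ClimateStack", layers = layers, scenario = scenario)
}

#' @rdname climateStack
#' @param x a `ClimateStack`.
#' @export
nLayers <- function(x) length(x@layers)

#' @rdname climateStack
#' @export
layerNames <- function(x) names(x@layers)

#' @rdname climateStack
#' @param name layer name.
#' @export
getLayer <- function(x, name) {
  if (!name %in% names(x@layers))
    stop("no layer named '", name, "' in stack", call. = FALSE)
  x@layers[[name]]
}

#' @rdname climateStack
#' @export
scenarioTag <- function(x) x@scenario

#' Flatten a stack to a cells-by-variables matrix
#'
#' Cells are taken in column-major order of the underlying matrices, so row
#' `i` of the result corresponds to cell `i` of `gridValues()` seen as a
#' vector.
#'
#' @param x a `ClimateStack`.
#' @param layers subset of layer names (default all).
#' @return numeric matrix, one column per layer.
#' @export
stackValues <- function(x, layers = names(x@layers)) {
  out <- vapply(layers, function(nm) as.vector(getLayer(x, nm)@values),
                numeric(length(x@layers[[1]]@values)))
  colnames(out) <- layers
  out
}

#' Extract stack values at point locations
#'
#' @param points a [LabeledPoints-class].
#' @param stack a [ClimateStack-class].
#' @return `points` with its `env` slot filled from the stack layers.
#' @export
extractEnv <- function(points, stack) {
  cells <- cellFromXY(stack@layers[[1]], points@coords)
  if (anyNA(cells)) stop("some points fall outside the stack extent")
  env <- vapply(names(stack@layers),
                function(nm) stack@layers[[nm]]@values[cells],
                numeric(nrow(cells)))
  if (nrow(points@coords) == 1L) env <- matrix(env, nrow = 1L,
                                               dimnames = list(NULL, names(stack@layers)))
  initialize(points, env = env)
}

setMethod("show", "ClimateStack", function(object) {
  d <- dim(object@layers[[1]]@values)
  cat(sprintf("ClimateStack '%s': %d layers on a %d x %d grid\n",
              object@scenario, length(object@layers), d[1], d[2]))
  cat("  layers:", paste(utils::head(names(object@layers), 8), collapse = ", "),
      if (length(object@layers) > 8) "...", "\n")
})

# ---- LabeledPoints -------------------------------------------------------

#' Create a LabeledPoints set
#'
#' @param species species identifier.
#' @param coords n x 2 matrix (columns x, y) of point coordinates.
#' @param label `"presence"` or `"pseudo_absence"`, recycled if scalar.
#' @param fold optional integer fold labels.
#' @param env optional n x p predictor matrix.
#' @return A [LabeledPoints-class].
#' @export
labeledPoints <- function(species, coords, label = "presence", fold = NULL,
                          env = NULL) {
  coords <- as.matrix(coords)
  colnames(coords) <- c("x", "y")
  n <- nrow(coords)
  if (length(label) == 1L) label <- rep(label, n)
  if (is.null(fold)) fold <- rep(NA_integer_, n)
  if (is.null(env)) env <- matrix(numeric(0), nrow = n, ncol = 0)
  new("LabeledPoints", species = species, coords = coords,
      label = as.character(label), fold = as.integer(fold),
      env = as.matrix(env))
}

#' @rdname labeledPoints
#' @param x a `LabeledPoints`.
#' @export
nPoints <- function(x) nrow(x@coords)

#' @rdname labeledPoints
#' @export
pointCoords <- function(x) x@coords

#' @rdname labeledPoints
#' @export
pointLabels <- function(x) x@label

#' @rdname labeledPoints
#' @export
pointFolds <- function(x) x@fold

#' @rdname labeledPoints
#' @export
pointEnv <- function(x) x@env

#' @rdname labeledPoints
#' @export
speciesId <- function(x) x@species

setMethod("[", "LabeledPoints", function(x, i, j, ..., drop = TRUE) {
  env <- if (ncol(x@env)) x@env[i, , drop = FALSE] else
    matrix(numeric(0), nrow = length(seq_len(nrow(x@coords))[i]), ncol = 0)
  initialize(x, coords = x@coords[i, , drop = FALSE], label = x@label[i],
             fold = x@fold[i], env = env)
})

#' Combine two point sets for the same species
#' @param a,b `LabeledPoints` with identical env columns.
#' @export
bindPoints <- function(a, b) {
  stopifnot(a@species == b@species, ncol(a@env) == ncol(b@env))
  initialize(a, coords = rbind(a@coords, b@coords),
             label = c(a@label, b@label), fold = c(a@fold, b@fold),
             env = rbind(a@env, b@env))
}

setMethod("show", "LabeledPoints", function(object) {
  cat(sprintf("LabeledPoints '%s': %d points (%d presence, %d pseudo-absence)\n",
              object@species, nrow(object@coords),
              sum(object@label == "presence"),
              sum(object@label == "pseudo_absence")))
  if (ncol(object@env))
    cat("  env:", paste(colnames(object@env), collapse = ", "), "\n")
  if (!all(is.na(object@fold)))
    cat("  folds:", paste(sort(unique(stats::na.omit(object@fold))),
                          collapse = ", "), "\n")
})

#' Read / write point sets as CSV
#'
#' CSV columns: `species`, `x`, `y`, `label`, plus `fold` and env columns
#' when present.
#'
#' @param x a `LabeledPoints`.
#' @param file CSV path.
#' @export
writePointsCsv <- function(x, file) {
  df <- data.frame(species = x@species, x = x@coords[, 1], y = x@coords[, 2],
                   label = x@label, fold = x@fold)
  if (ncol(x@env)) df <- cbind(df, as.data.frame(x@env))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writePointsCsv
#' @export
readPointsCsv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  envCols <- setdiff(names(df), c("species", "x", "y", "label", "fold"))
  labeledPoints(species = df$species[1],
                coords = cbind(df$x, df$y),
                label = if ("label" %in% names(df)) df$label else "presence",
                fold = if ("fold" %in% names(df)) df$fold else NULL,
                env = if (length(envCols)) as.matrix(df[envCols]) else NULL)
}
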