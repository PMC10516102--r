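#' Thin occurrences to one record per coarse grid cell
#'
#' Occurrence records are snapped to a thinning grid (by default twice the
#' predictor resolution) and one record per occupied cell is kept, chosen
#' uniformly at random. This removes duplicate and clumped records that
#' would otherwise inflate local sampling density.
#'
#' @param points a [LabeledPoints-class].
#' @param cell_size thinning-cell side length, in map units; use
#'   `2 * cellSize(layer)` to thin at twice the predictor resolution.
#' @param seed integer seed for the per-cell random choice.
#' @param origin thinning-grid origin, default `c(0, 0)`.
#' @return the thinned [LabeledPoints-class] (input order preserved).
#' @export
thinPoints <- function(points, cell_size, seed = 1, origin = c(0, 0)) {
  stopifnot(cell_size > 0)
  ix <- floor((points@coords[, 1] - origin[1]) / cell_size)
  iy <- floor((points@coords[, 2] - origin[2]) / cell_size)
  key <- paste(ix, iy)
  keep <- withSeed(seed, {
    idx <- seq_along(key)
    unlist(lapply(split(idx, key), function(g)
      if (length(g) == 1L) g else g[sample.int(length(g), 1L)]),
      use.names = FALSE)
  })
  points[sort(keep)]
}

#' Rectilinear environmental envelope of the presences
#'
#' Per-variable minimum and maximum over the presence records' predictor
#' values — a BIOCLIM-style box, used here as the "climatically suitable"
#' region when placing pseudo-absences.
#'
#' @param presences a [LabeledPoints-class] with `env` values.
#' @return a list of class `Envelope` with `variable_names`, `lower`,
#'   `upper`.
#' @export
fitEnvelope <- function(presences) {
  pres <- presences[pointLabels(presences) == "presence"]
  env <- pointEnv(pres)
  if (ncol(env) == 0L || nrow(env) == 0L)
    stop("presences carry no env values; call extractEnv() first", call. = FALSE)
  if (anyNA(env)) stop("missing env values among presences", call. = FALSE)
  structure(list(variable_names = colnames(env),
                 lower = apply(env, 2, min),
                 upper = apply(env, 2, max)),
            class = "Envelope")
}

# Logical vector: does each row of X fall inside the envelope on all axes?
insideEnvelope <- function(X, envelope) {
  X <- X[, envelope$variable_names, drop = FALSE]
  ok <- !is.na(rowSums(X))
  inside <- ok
  for (j in seq_along(envelope$variable_names)) {
    inside <- inside & X[, j] >= envelope$lower[j] & X[, j] <= envelope$upper[j]
  }
  inside[!ok] <- NA
  inside
}

#' Sample pseudo-absences under an environmental restriction
#'
#' Draws `ratio` pseudo-absence points per presence from the cells of the
#' predictor stack, restricted by the presence envelope: by default from
#' cells *outside* the envelope (the environmental-restriction rationale —
#' pseudo-absences should sit where the climate is unlike any known
#' occurrence); `inside = TRUE` instead draws from envelope-interior cells.
#' Cells containing a presence are never used. Sampling is uniform without
#' replacement; if fewer eligible cells exist than points required, sampling
#' falls back to with-replacement with a warning.
#'
#' @param presences presence [LabeledPoints-class] (env values optional;
#'   coordinates are used to exclude presence cells).
#' @param env_stack predictor [ClimateStack-class] (the same layers the
#'   envelope was fitted on, e.g. PCA axes).
#' @param envelope an [fitEnvelope()] result.
#' @param ratio pseudo-absences per presence (default 1, the 1:1 design).
#' @param seed integer seed.
#' @param inside draw inside rather than outside the envelope.
#' @return a pseudo-absence [LabeledPoints-class] with env values filled.
#' @export
samplePseudoAbsences <- function(presences, env_stack, envelope, ratio = 1,
                                 seed = 1, inside = FALSE) {
  ref <- env_stack@layers[[1]]
  X <- stackValues(env_stack)
  inEnv <- insideEnvelope(X, envelope)
  eligible <- if (inside) which(inEnv %in% TRUE) else which(inEnv %in% FALSE)
  presCells <- cellFromXY(ref, pointCoords(presences))
  presIdx <- presCells[, 1] + (presCells[, 2] - 1L) * nrow(ref@values)
  eligible <- setdiff(eligible, presIdx)
  if (length(eligible) == 0L)
    stop("no eligible cells ", if (inside) "inside" else "outside",
         " the envelope; relax the envelope or flip `inside`", call. = FALSE)
  nNeed <- round(ratio * sum(pointLabels(presences) == "presence"))
  idx <- withSeed(seed, {
    if (length(eligible) >= nNeed) sample(eligible, nNeed)
    else {
      warning("only ", length(eligible),
              " eligible cells for ", nNeed,
              " pseudo-absences; sampling with replacement")
      sample(eligible, nNeed, replace = TRUE)
    }
  })
  d <- dim(ref@values)
  cells <- cbind(((idx - 1L) %% d[1]) + 1L, ((idx - 1L) %/% d[1]) + 1L)
  pa <- labeledPoints(speciesId(presences), cellCenters(ref, cells),
                      label = "pseudo_absence")
  extractEnv(pa, env_stack)
}
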