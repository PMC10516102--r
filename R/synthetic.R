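#' Configuration for the synthetic landscape generator
#'
#' Describes the simulated study region: grid size, per-cell area, number of
#' bioclimatic-style predictor layers, spatial autocorrelation length, and
#' the target inter-variable correlation structure. The defaults emulate the
#' statistical shape of a ~10 km bioclimatic raster set: 19 strongly
#' inter-correlated layers with smooth spatial structure.
#'
#' @param grid_rows,grid_cols grid dimensions (each at least 8).
#' @param cell_area area of one cell in km2 (default 100, i.e. ~10 km cells).
#' @param n_climate_vars number of predictor layers (default 19).
#' @param spatial_range autocorrelation length in cells (Gaussian smoothing
#'   kernel standard deviation); 0 gives spatially independent noise.
#' @param mixing target inter-variable correlation matrix
#'   (`n_climate_vars` rows); default a three-factor structure so that a
#'   handful of principal axes carries most of the variance, as with real
#'   temperature/precipitation summaries.
#' @param seed integer seed; the same config yields bit-identical landscapes.
#' @return A list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(grid_rows = 60, grid_cols = 60, cell_area = 100,
                            n_climate_vars = 19, spatial_range = 5,
                            mixing = NULL, seed = 1) {
  if (grid_rows < 8 || grid_cols < 8)
    stop("grid must be at least 8 x 8", call. = FALSE)
  if (cell_area <= 0) stop("cell_area must be positive", call. = FALSE)
  if (is.null(mixing)) mixing <- defaultMixing(n_climate_vars)
  if (nrow(mixing) != n_climate_vars)
    stop("mixing must have n_climate_vars rows", call. = FALSE)
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 cell_area = cell_area,
                 n_climate_vars = as.integer(n_climate_vars),
                 spatial_range = spatial_range,
                 mixing = mixing, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Default inter-variable correlation structure
#'
#' A deterministic three-factor model: variables load 0.85 on one of three
#' latent factors (assigned cyclically) and 0.2 on the next, with unit
#' diagonal. This mimics the temperature / precipitation / seasonality
#' blocks of bioclimatic variable sets, whose first few principal axes carry
#' most of the variance.
#'
#' @param n_vars number of variables.
#' @param n_factors number of latent factors (default 3).
#' @return an `n_vars` x `n_vars` correlation matrix.
#' @export
defaultMixing <- function(n_vars, n_factors = 3) {
  L <- matrix(0, n_vars, n_factors)
  f <- ((seq_len(n_vars) - 1L) %% n_factors) + 1L
  L[cbind(seq_len(n_vars), f)] <- 0.85
  L[cbind(seq_len(n_vars), (f %% n_factors) + 1L)] <- 0.2
  C <- L %*% t(L)
  diag(C) <- 1
  C
}

# Separable Gaussian smoothing of a matrix, kernel sd = sigma cells,
# truncated at 3 sigma, edge-renormalized.
gaussianSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  kern1 <- function(n) {
    half <- ceiling(3 * sigma)
    idx <- outer(seq_len(n), seq_len(n), "-")
    K <- exp(-idx^2 / (2 * sigma^2))
    K[abs(idx) > half] <- 0
    K / rowSums(K)
  }
  kern1(nrow(m)) %*% m %*% t(kern1(ncol(m)))
}

# Plausible per-variable location/scale so layers look like a mix of
# temperature (deg C) and precipitation (mm) summaries.
bioclimScales <- function(n) {
  temp <- seq_len(n) <= ceiling(n * 11 / 19)
  list(mu = ifelse(temp, 25 - 1.5 * seq_len(n), 1500 - 80 * seq_len(n)),
       s = ifelse(temp, 3, 300))
}

#' Generate a synthetic present-day climate stack
#'
#' Each layer is a spatially autocorrelated Gaussian random field (white
#' noise smoothed with a Gaussian kernel of width `spatial_range`, then
#' re-standardized); the fields are linearly mixed by the Cholesky factor of
#' the `mixing` correlation matrix so that inter-variable correlations match
#' it, then shifted/scaled to bioclimatic-style units.
#'
#' @param config a [syntheticConfig()].
#' @return A [ClimateStack-class] tagged `"present"` with layers
#'   `bio01 ... bioNN`.
#' @export
generateClimate <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  R <- tryCatch(chol(config$mixing), error = function(e)
    stop("mixing matrix is not positive definite: ", conditionMessage(e),
         call. = FALSE))
  nr <- config$grid_rows; nc <- config$grid_cols
  p <- config$n_climate_vars
  Z <- withSeed(config$seed, {
    vapply(seq_len(p), function(i) {
      f <- gaussianSmooth(matrix(stats::rnorm(nr * nc), nr, nc),
                          config$spatial_range)
      as.vector(scale(as.vector(f)))
    }, numeric(nr * nc))
  })
  X <- Z %*% R
  sc <- bioclimScales(p)
  layers <- lapply(seq_len(p), function(i)
    rasterGrid(matrix(sc$mu[i] + sc$s[i] * X[, i], nr, nc)))
  names(layers) <- sprintf("bio%02d", seq_len(p))
  climateStack(layers, scenario = "present")
}

#' Scenario shift describing one future climate realization
#'
#' @param scenario_id scenario name, e.g. `"rcp45"` or `"rcp85"`.
#' @param gcm_id circulation-model name.
#' @param additive named per-variable additive offsets (original units).
#' @param multiplicative named per-variable factors (must be positive).
#' @return A list of class `ScenarioShift`.
#' @export
scenarioShift <- function(scenario_id, gcm_id, additive = numeric(),
                          multiplicative = numeric()) {
  if (length(multiplicative) && any(multiplicative <= 0))
    stop("multiplicative factors must be positive", call. = FALSE)
  structure(list(scenario_id = scenario_id, gcm_id = gcm_id,
                 additive = additive, multiplicative = multiplicative),
            class = "ScenarioShift")
}

#' Apply a scenario shift to a present-day stack
#'
#' Per variable, `future = present * multiplicative + additive`; variables
#' not named in the shift are carried through unchanged. The returned stack
#' is tagged `"<scenario_id>:<gcm_id>"`.
#'
#' @param present a [ClimateStack-class].
#' @param shift a [scenarioShift()].
#' @return a future [ClimateStack-class].
#' @export
generateFuture <- function(present, shift) {
  stopifnot(inherits(shift, "ScenarioShift"))
  vars <- union(names(shift$additive), names(shift$multiplicative))
  unknown <- setdiff(vars, layerNames(present))
  if (length(unknown))
    stop("shift names unknown variables: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  layers <- present@layers
  for (v in names(shift$multiplicative))
    layers[[v]] <- withValues(layers[[v]],
                              layers[[v]]@values * shift$multiplicative[[v]])
  for (v in names(shift$additive))
    layers[[v]] <- withValues(layers[[v]],
                              layers[[v]]@values + shift$additive[[v]])
  climateStack(layers, scenario = paste(shift$scenario_id, shift$gcm_id,
                                        sep = ":"))
}

#' Default scenario shifts: two emission pathways, five climate models
#'
#' Builds the usual 2 x 5 design — a mitigation pathway (`rcp45`) and a
#' high-emission pathway (`rcp85`), each realized by five circulation
#' models. Temperature-style layers warm (additive, +1.5 deg C under rcp45,
#' +3 under rcp85, at the layer's own scale), precipitation-style layers dry
#' (multiplicative, -7% / -15%), with a small deterministic per-model spread
#' so that models disagree the way AOGCMs do.
#'
#' @param present the present-day [ClimateStack-class].
#' @param n_gcms circulation models per scenario (default 5).
#' @return named list of [scenarioShift()] objects, length `2 * n_gcms`.
#' @export
defaultScenarioShifts <- function(present, n_gcms = 5) {
  nm <- layerNames(present)
  p <- length(nm)
  sc <- bioclimScales(p)
  temp <- seq_len(p) <= ceiling(p * 11 / 19)
  out <- list()
  for (scen in c("rcp45", "rcp85")) {
    warm <- if (scen == "rcp45") 1.5 else 3.0
    dry <- if (scen == "rcp45") 0.93 else 0.85
    for (g in seq_len(n_gcms)) {
      spread <- 1 + 0.15 * (g - (n_gcms + 1) / 2) / n_gcms
      add <- stats::setNames(ifelse(temp, warm * spread * sc$s[seq_len(p)] / 3, 0), nm)
      mult <- stats::setNames(ifelse(temp, 1, 1 - (1 - dry) * spread), nm)
      id <- sprintf("gcm%d", g)
      out[[paste(scen, id, sep = ":")]] <-
        scenarioShift(scen, id, additive = add[temp],
                      multiplicative = mult[!temp])
    }
  }
  out
}

# ---- virtual species -----------------------------------------------------

#' Define a virtual species by a Gaussian niche
#'
#' A virtual species has a known suitability function — here a product of
#' independent Gaussian responses on a subset of the climate variables —
#' so that downstream modelling can be validated against ground truth.
#'
#' @param species_id name.
#' @param niche_vars predictor (layer) names the niche depends on.
#' @param optima named per-variable optimal values.
#' @param breadths named per-variable niche breadths (Gaussian sd, > 0).
#' @param prevalence_threshold suitability cutoff defining the species'
#'   "true" range. The default 0.1 keeps the range consistent with the
#'   sampling model: presences are drawn proportional to suitability, so a
#'   coherent "true range" must contain essentially all occurrence mass,
#'   which requires a low cutoff.
#' @return A list of class `VirtualSpecies`.
#' @export
virtualSpecies <- function(species_id, niche_vars, optima, breadths,
                           prevalence_threshold = 0.1) {
  if (length(niche_vars) == 0) stop("niche_vars must be nonempty", call. = FALSE)
  if (any(breadths <= 0)) stop("breadths must be positive", call. = FALSE)
  structure(list(species_id = species_id, niche_vars = niche_vars,
                 optima = optima, breadths = breadths,
                 prevalence_threshold = prevalence_threshold),
            class = "VirtualSpecies")
}

#' True suitability surface of a virtual species
#'
#' `suit(cell) = prod_v exp(-(x_v - opt_v)^2 / (2 breadth_v^2))`, rescaled
#' so the best cell on the landscape scores 1.
#'
#' @param climate a [ClimateStack-class].
#' @param vs a [virtualSpecies()].
#' @return a [RasterGrid-class] with values in \[0, 1\].
#' @export
trueSuitability <- function(climate, vs) {
  stopifnot(inherits(vs, "VirtualSpecies"))
  missing <- setdiff(vs$niche_vars, layerNames(climate))
  if (length(missing))
    stop("niche variables not in climate stack: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ref <- climate@layers[[1]]
  suit <- matrix(1, nrow(ref@values), ncol(ref@values))
  for (v in vs$niche_vars) {
    x <- getLayer(climate, v)@values
    suit <- suit * exp(-(x - vs$optima[[v]])^2 / (2 * vs$breadths[[v]]^2))
  }
  mx <- max(suit, na.rm = TRUE)
  if (mx > 0) suit <- suit / mx
  withValues(ref, suit)
}

#' Default virtual-species set for a landscape
#'
#' Builds `n` species with Gaussian niches on the first two climate layers.
#' For each species the optimum sits at the landscape mean shifted by half a
#' landscape standard deviation (the direction alternating across species so
#' ranges differ), and the breadth equals one landscape standard deviation —
#' giving intermediate-prevalence ranges of the kind virtual-species studies
#' typically simulate.
#'
#' @param climate a [ClimateStack-class].
#' @param n number of species (default 3).
#' @return list of [virtualSpecies()] objects named `vsp1 ... vspN`.
#' @export
defaultVirtualSpecies <- function(climate, n = 3) {
  vars <- layerNames(climate)[1:2]
  stats <- lapply(vars, function(v) {
    x <- getLayer(climate, v)@values
    c(m = mean(x, na.rm = TRUE), s = stats::sd(as.vector(x), na.rm = TRUE))
  })
  names(stats) <- vars
  lapply(seq_len(n), function(i) {
    signs <- switch(((i - 1) %% 3) + 1, c(1, 1), c(-1, 1), c(1, -1))
    opt <- vapply(seq_along(vars), function(j)
      stats[[j]]["m"] + signs[j] * 0.5 * stats[[j]]["s"], numeric(1))
    br <- vapply(stats, function(s) s[["s"]], numeric(1))
    virtualSpecies(sprintf("vsp%d", i), vars,
                   optima = stats::setNames(opt, vars),
                   breadths = stats::setNames(br, vars))
  }) |> stats::setNames(sprintf("vsp%d", seq_len(n)))
}

#' Sample presence points from a true suitability surface
#'
#' Cells are drawn (with replacement) with probability proportional to
#' suitability; points sit at cell centers, mimicking raster-resolution
#' occurrence records.
#'
#' @param true_suit suitability [RasterGrid-class].
#' @param n number of presence records.
#' @param seed integer seed.
#' @param species_id species name for the returned point set.
#' @return A [LabeledPoints-class] of `n` presences.
#' @export
samplePresences <- function(true_suit, n, seed = 1, species_id = "virtual") {
  stopifnot(n >= 1)
  w <- as.vector(true_suit@values)
  w[is.na(w)] <- 0
  if (all(w == 0)) stop("all-zero suitability: nothing to sample", call. = FALSE)
  idx <- withSeed(seed, sample.int(length(w), n, replace = TRUE, prob = w))
  d <- dim(true_suit@values)
  cells <- cbind(((idx - 1L) %% d[1]) + 1L, ((idx - 1L) %/% d[1]) + 1L)
  labeledPoints(species_id, cellCenters(true_suit, cells), label = "presence")
}

# ---- protected areas and land cover --------------------------------------

#' Generate random protected-area footprints
#'
#' Each footprint grows by random accretion from a random seed cell: at each
#' step one uniformly chosen frontier cell (4-neighbour of the current set,
#' inside the mask) is added, guaranteeing a connected footprint. Sizes are
#' uniform over `size_range`; categories are drawn from the three usual
#' Amazonian classes (integral protection, sustainable use, indigenous land).
#'
#' @param mask study-area [RasterGrid-class] (non-`NA`, non-zero = inside).
#' @param n_pas number of protected areas.
#' @param size_range integer range of footprint sizes, in cells.
#' @param seed integer seed.
#' @param cell_area km2 per cell used for the PA area attribute.
#' @return list of [PAUnit-class] objects (possibly overlapping).
#' @export
generateProtectedAreas <- function(mask, n_pas, size_range = c(5, 40),
                                   seed = 1, cell_area = 100) {
  inside <- maskInterior(mask)
  if (!any(inside)) stop("mask is empty", call. = FALSE)
  if (max(size_range) > sum(inside))
    stop("size_range exceeds the number of mask cells", call. = FALSE)
  if (n_pas == 0) return(list())
  d <- dim(inside)
  insideCells <- which(inside)
  withSeed(seed, {
    lapply(seq_len(n_pas), function(k) {
      target <- sample(seq(size_range[1], size_range[2]), 1L)
      start <- sample(insideCells, 1L)
      taken <- matrix(FALSE, d[1], d[2])
      taken[start] <- TRUE
      cells <- cbind(((start - 1L) %% d[1]) + 1L, ((start - 1L) %/% d[1]) + 1L)
      while (nrow(cells) < target) {
        nb <- rbind(cbind(cells[, 1] - 1L, cells[, 2]),
                    cbind(cells[, 1] + 1L, cells[, 2]),
                    cbind(cells[, 1], cells[, 2] - 1L),
                    cbind(cells[, 1], cells[, 2] + 1L))
        ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] & nb[, 2] >= 1L & nb[, 2] <= d[2]
        nb <- nb[ok, , drop = FALSE]
        free <- inside[nb] & !taken[nb]
        nb <- unique(nb[free, , drop = FALSE])
        if (nrow(nb) == 0L) break   # landlocked: footprint stays smaller
        add <- nb[sample.int(nrow(nb), 1L), , drop = FALSE]
        taken[add] <- TRUE
        cells <- rbind(cells, add)
      }
      new("PAUnit", id = sprintf("pa%03d", k),
          category = sample(c("IPA", "SUA", "IL"), 1L),
          cells = cells, area = nrow(cells) * cell_area)
    })
  })
}

#' The permitted (forest) land-cover classes
#'
#' The five broadleaf tree/shrub classes within which carnivore ranges are
#' retained when climate suitability is overlaid on vegetation cover.
#' @return character vector of five class names.
#' @export
allowedLandcoverClasses <- function() c(
  "Broadleaf evergreen tree, tropical",
  "Broadleaf deciduous tree, tropical",
  "Broadleaf deciduous tree, temperate",
  "Broadleaf deciduous tree, boreal",
  "Broadleaf deciduous shrub, temperate")

#' Generate a categorical land-cover raster from climate
#'
#' Class probabilities vary smoothly with the first climate layer: the
#' probability of non-forest cover increases logistically with that layer's
#' value (so warmer-shifted scenarios convert forest), and the forest
#' probability is split across the permitted classes by smooth weights.
#' Values in the returned raster are integer codes into `classes`.
#'
#' @param climate a [ClimateStack-class].
#' @param classes class names; default the five permitted forest classes
#'   plus `"Cropland/grassland mosaic"`. At least 2 required.
#' @param seed integer seed.
#' @param reference stack whose first layer supplies the standardization
#'   constants (default `climate` itself); future scenarios should pass the
#'   present-day stack so that warming shifts, not re-standardization,
#'   drive cover change.
#' @return a categorical [RasterGrid-class] of codes `1..length(classes)`.
#' @export
generateLandcover <- function(climate,
                              classes = c(allowedLandcoverClasses(),
                                          "Cropland/grassland mosaic"),
                              seed = 1, reference = climate) {
  if (length(classes) < 2) stop("need at least 2 land-cover classes", call. = FALSE)
  x <- climate@layers[[1]]@values
  xr <- reference@layers[[1]]@values
  m <- mean(xr, na.rm = TRUE); s <- stats::sd(as.vector(xr), na.rm = TRUE)
  z <- (x - m) / s
  nNonForest <- max(1L, length(classes) - 5L)
  pOpen <- stats::plogis(2 * (z - 1))     # hot cells lose forest
  d <- dim(x)
  codes <- withSeed(seed, {
    u <- matrix(stats::runif(length(x)), d[1], d[2])
    open <- u < pOpen
    # split forest among the first (up to 5) classes by a smooth gradient
    nForest <- length(classes) - nNonForest
    fIdx <- pmin(nForest, pmax(1L, ceiling((stats::pnorm(z) * 0.999) * nForest)))
    out <- ifelse(open,
                  nForest + 1L + (ceiling(u / pOpen * nNonForest) - 1L) %% nNonForest,
                  fIdx)
    out
  })
  codes[is.na(x)] <- NA
  withValues(climate@layers[[1]], codes)
}
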