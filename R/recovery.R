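#' Virtual-species parameter-recovery experiment
#'
#' The core validation of the modelling chain: simulate a landscape, plant
#' virtual species with known Gaussian niches, sample presence records, run
#' the full present-day modelling path (thinning, environmentally
#' restricted 1:1 pseudo-absences, fold assignment, the five algorithms,
#' above-mean ensemble, max-Jaccard binarization), and measure how well the
#' ensemble binary range recovers the species' true range (cells whose true
#' suitability reaches the prevalence threshold). Recovery is the Jaccard
#' index between the two binary maps over the whole grid.
#'
#' @param seed integer seed (drives landscape, sampling and fitting).
#' @param grid_rows,grid_cols landscape size (default 60 x 60).
#' @param n_species number of virtual species (default 3).
#' @param n_presences presence records per species (default 200).
#' @param algorithms SDM algorithms to use (default all five).
#' @return data.frame with one row per species: `species`, `jaccard`
#'   (recovery), `n_presences_thinned`, `partition` method used; the
#'   stacked-richness conservation check is returned as the attribute
#'   `"richness_exact"` (logical).
#' @export
recoveryExperiment <- function(seed, grid_rows = 60, grid_cols = 60,
                               n_species = 3, n_presences = 200,
                               algorithms = sdmAlgorithms()) {
  syn <- syntheticConfig(grid_rows, grid_cols, seed = deriveSeed(seed, "simulate"))
  climate <- generateClimate(syn)
  mask <- withValues(climate@layers[[1]], matrix(1, grid_rows, grid_cols))
  pca <- fitPCA(climate, mask)
  axes <- projectStack(climate, pca)
  vsList <- defaultVirtualSpecies(climate, n_species)
  binaries <- list()
  rows <- lapply(vsList, function(vs) {
    sp <- vs$species_id
    truth <- trueSuitability(climate, vs)
    trueRange <- binarizeMap(truth, vs$prevalence_threshold)
    pres <- samplePresences(truth, n_presences,
                            seed = deriveSeed(seed, paste0("presences:", sp)),
                            species_id = sp)
    pres <- thinPoints(pres, 2 * cellSize(mask),
                       seed = deriveSeed(seed, paste0("thin:", sp)))
    pres <- extractEnv(pres, axes)
    envp <- fitEnvelope(pres)
    absn <- samplePseudoAbsences(pres, axes, envp,
                                 seed = deriveSeed(seed, paste0("pseudo:", sp)))
    pts <- assignFolds(bindPoints(pres, absn), resolution = cellSize(mask),
                       seed = deriveSeed(seed, paste0("folds:", sp)))
    run <- runSDM(pts, axes, algorithms,
                  seed = deriveSeed(seed, paste0("fit:", sp)))
    binaries[[sp]] <<- run$ensemble@binaryMap
    cc <- confusionCounts(as.vector(gridValues(run$ensemble@binaryMap)) == 1,
                          as.vector(gridValues(trueRange)) == 1)
    data.frame(species = sp, jaccard = jaccardIndex(cc),
               n_presences_thinned = nPoints(pres),
               partition = attr(pts, "method"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  rich <- stackRichness(binaries)
  attr(out, "richness_exact") <- identical(
    gridValues(rich), Reduce(`+`, lapply(binaries, gridValues)))
  out
}
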