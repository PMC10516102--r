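#' Pipeline run configuration
#'
#' One object holding every knob of the end-to-end analysis, with the
#' standard defaults: 95% PCA variance, 15-record checkerboard rule, k = 3
#' random folds, 1:1 pseudo-absence ratio, 5% stability band, 50 km2
#' minimum protected-area size, 999 null-model replicates at alpha = 0.05.
#' Every stochastic stage derives its own seed from the master `seed` and
#' the stage name, so whole runs are bit-reproducible and stages can be
#' re-run in isolation.
#'
#' @param grid_rows,grid_cols,cell_area,n_climate_vars,spatial_range
#'   synthetic-landscape parameters (see [syntheticConfig()]).
#' @param n_species number of virtual species.
#' @param n_presences presence records sampled per species.
#' @param scenarios future scenario ids (default `c("rcp45", "rcp85")`).
#' @param n_gcms circulation models per scenario (default 5).
#' @param algorithms SDM algorithm ids (default all five).
#' @param variance_threshold PCA cumulative-variance target.
#' @param min_records presence count at/above which the checkerboard
#'   partition is used.
#' @param k folds for the random k-fold path.
#' @param pa_ratio pseudo-absences per presence.
#' @param stability_pct range-change stability band (percent).
#' @param n_pas,pa_size_range protected-area generator settings.
#' @param pa_min_area minimum PA area retained (km2).
#' @param null_reps null-model randomizations.
#' @param alpha null-model significance level.
#' @param seed master integer seed.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(grid_rows = 60, grid_cols = 60, cell_area = 100,
                      n_climate_vars = 19, spatial_range = 5,
                      n_species = 3, n_presences = 200,
                      scenarios = c("rcp45", "rcp85"), n_gcms = 5,
                      algorithms = sdmAlgorithms(),
                      variance_threshold = 0.95, min_records = 15, k = 3,
                      pa_ratio = 1, stability_pct = 5, n_pas = 8,
                      pa_size_range = c(5, 40), pa_min_area = 50,
                      null_reps = 999, alpha = 0.05, seed = 1) {
  cfg <- list(grid_rows = grid_rows, grid_cols = grid_cols,
              cell_area = cell_area, n_climate_vars = n_climate_vars,
              spatial_range = spatial_range, n_species = n_species,
              n_presences = n_presences, scenarios = scenarios,
              n_gcms = n_gcms, algorithms = algorithms,
              variance_threshold = variance_threshold,
              min_records = min_records, k = k, pa_ratio = pa_ratio,
              stability_pct = stability_pct, n_pas = n_pas,
              pa_size_range = pa_size_range, pa_min_area = pa_min_area,
              null_reps = null_reps, alpha = alpha, seed = as.integer(seed))
  structure(cfg, class = "RunConfig")
}

#' Read / write a run configuration as YAML
#' @param config a [runConfig()].
#' @param file YAML path.
#' @export
writeRunConfig <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(file) {
  do.call(runConfig, yaml::read_yaml(file))
}

#' Run the full analysis end-to-end
#'
#' Executes, from one config and master seed: landscape simulation
#' (climate, 2 x 5 futures, land cover, protected areas) -> PCA climate
#' space -> occurrence thinning and 1:1 environmentally restricted
#' pseudo-absences -> fold assignment (checkerboard or k-fold) -> the five
#' SDM algorithms -> above-mean ensemble with max-Jaccard binarization ->
#' land-cover masking -> range change, suitability change and richness ->
#' gap analysis -> richness null models. Writes CSV tables, ASCII-grid
#' rasters and a JSON manifest (stage seeds plus per-file MD5 hashes) to
#' `out_dir`, and returns the main objects invisibly.
#'
#' @param config a [runConfig()].
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @return (invisibly) list with `climate`, `pca`, `species` (per-species
#'   run objects), `evaluation`, `range_change`, `richness`, `gap`,
#'   `null_model`, `protected_richness`, `pas`, `manifest`.
#' @export
runPipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  seedFor <- function(stage) deriveSeed(config$seed, stage)

  ## -- simulate -----------------------------------------------------------
  syn <- syntheticConfig(config$grid_rows, config$grid_cols,
                         config$cell_area, config$n_climate_vars,
                         config$spatial_range, seed = seedFor("simulate"))
  climate <- generateClimate(syn)
  mask <- withValues(climate@layers[[1]],
                     matrix(1, config$grid_rows, config$grid_cols))
  areas <- cellAreas(mask, cell_area = config$cell_area)
  shifts <- defaultScenarioShifts(climate, config$n_gcms)
  shifts <- shifts[sub(":.*", "", names(shifts)) %in% config$scenarios]
  futures <- lapply(shifts, generateFuture, present = climate)

  # one land-cover model per climate scenario (present + each future),
  # generated from the scenario's GCM-averaged climate with a shared seed
  # so differences are climate-driven
  scenarioMean <- function(scen) {
    st <- futures[sub(":.*", "", names(futures)) == scen]
    layers <- lapply(layerNames(climate), function(nm)
      withValues(climate@layers[[nm]],
                 Reduce(`+`, lapply(st, function(s) getLayer(s, nm)@values)) /
                   length(st)))
    names(layers) <- layerNames(climate)
    climateStack(layers, scenario = scen)
  }
  lcStacks <- c(list(present = climate),
                stats::setNames(lapply(config$scenarios, scenarioMean),
                                config$scenarios))
  landcover <- lapply(lcStacks, generateLandcover, seed = seedFor("landcover"),
                      reference = climate)
  allowedCodes <- seq_along(allowedLandcoverClasses())

  ## -- climate space ------------------------------------------------------
  pca <- fitPCA(climate, mask, config$variance_threshold)
  axesPresent <- projectStack(climate, pca)
  axesFutures <- lapply(futures, projectStack, transform = pca)

  ## -- species loop -------------------------------------------------------
  vsList <- defaultVirtualSpecies(climate, config$n_species)
  thinSize <- 2 * cellSize(mask)
  speciesRuns <- lapply(vsList, function(vs) {
    sp <- vs$species_id
    truth <- trueSuitability(climate, vs)
    pres <- samplePresences(truth, config$n_presences,
                            seed = seedFor(paste0("presences:", sp)),
                            species_id = sp)
    pres <- thinPoints(pres, thinSize, seed = seedFor(paste0("thin:", sp)))
    pres <- extractEnv(pres, axesPresent)
    envp <- fitEnvelope(pres)
    abs <- samplePseudoAbsences(pres, axesPresent, envp,
                                ratio = config$pa_ratio,
                                seed = seedFor(paste0("pseudo:", sp)))
    pts <- bindPoints(pres, abs)
    pts <- assignFolds(pts, resolution = cellSize(mask),
                       min_records = config$min_records, k = config$k,
                       seed = seedFor(paste0("folds:", sp)))
    run <- runSDM(pts, axesPresent, config$algorithms,
                  seed = seedFor(paste0("fit:", sp)))
    # scenario-level future ensembles: mean of per-GCM ensemble maps,
    # binarized with the present-day threshold
    futureEns <- lapply(config$scenarios, function(scen) {
      gcmMaps <- lapply(axesFutures[sub(":.*", "", names(axesFutures)) == scen],
                        function(ax) projectEnsemble(run, ax)@map)
      m <- withValues(gcmMaps[[1]],
                      Reduce(`+`, lapply(gcmMaps, gridValues)) / length(gcmMaps))
      ens <- initialize(run$ensemble, scenario = scen, map = m,
                        threshold = NA_real_, binaryMap = m)
      thresholdEnsemble(ens, threshold = run$ensemble@threshold)
    })
    names(futureEns) <- config$scenarios
    list(vs = vs, truth = truth, points = pts, run = run,
         ensembles = c(list(present = run$ensemble), futureEns))
  })
  names(speciesRuns) <- names(vsList)

  ## -- range dynamics -----------------------------------------------------
  scens <- c("present", config$scenarios)
  maskedBinary <- lapply(scens, function(scen) {
    lapply(speciesRuns, function(sr)
      maskLandcover(sr$ensembles[[scen]]@binaryMap, landcover[[scen]],
                    allowedCodes))
  })
  names(maskedBinary) <- scens
  areaTab <- do.call(rbind, lapply(names(speciesRuns), function(sp)
    data.frame(species = sp, scenario = scens,
               area_km2 = vapply(scens, function(s)
                 rangeArea(maskedBinary[[s]][[sp]], areas), numeric(1)))))
  changeTab <- rangeChangeTable(areaTab, config$stability_pct)
  changeTab$suitability_change_pct <- mapply(function(sp, scen) {
    sr <- speciesRuns[[sp]]
    suitabilityChange(sr$ensembles$present@map, sr$ensembles[[scen]]@map, mask)
  }, changeTab$species, changeTab$scenario)
  richness <- lapply(maskedBinary, stackRichness)

  ## -- protected areas ----------------------------------------------------
  pas <- generateProtectedAreas(mask, config$n_pas, config$pa_size_range,
                                seed = seedFor("pas"),
                                cell_area = config$cell_area)
  pas <- filterPAs(pas, mask, config$pa_min_area, areas)
  gapTab <- gapAnalysis(maskedBinary, pas, areas)
  nullTab <- do.call(rbind, lapply(scens, function(scen) {
    do.call(rbind, lapply(pas, function(pa) {
      r <- nullModelTest(pa, richness[[scen]], mask, n = config$null_reps,
                         alpha = config$alpha,
                         seed = seedFor(paste0("null:", scen, ":", pa@id)))
      data.frame(scenario = scen, unit = r$unit_id,
                 observed = r$observed_stat,
                 null_mean = mean(r$null_stats), p_value = r$p_value,
                 effective = r$effective)
    }))
  }))
  protRich <- data.frame(scenario = scens,
                         protected_richness_pct = vapply(scens, function(s)
                           protectedRichnessProportion(richness[[s]], pas, mask),
                           numeric(1)))

  evalTab <- do.call(rbind, lapply(speciesRuns, function(sr) sr$run$evaluation))
  rownames(evalTab) <- NULL

  ## -- write outputs ------------------------------------------------------
  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.csv(df, p, row.names = FALSE)
      p
    }
    files <- c(wcsv(evalTab, "evaluation.csv"),
               wcsv(changeTab, "range_change.csv"),
               wcsv(gapTab, "gap.csv"),
               wcsv(nullTab, "null_model.csv"),
               wcsv(protRich, "protected_richness.csv"))
    for (scen in scens) {
      p <- file.path(out_dir, sprintf("richness_%s.asc", scen))
      writeAsciiGrid(richness[[scen]], p)
      files <- c(files, p)
    }
    paFiles <- file.path(out_dir, c("pas.asc", "pas.csv"))
    writePAs(pas, mask, paFiles[1], paFiles[2])
    files <- c(files, paFiles)
    writePCATransform(pca, file.path(out_dir, "pca.json"))
    files <- c(files, file.path(out_dir, "pca.json"))
    manifest <- list(
      package = as.character(utils::packageVersion("ensembleSDM")),
      seed = config$seed,
      stage_seeds = stats::setNames(
        lapply(c("simulate", "landcover", "pas"), seedFor),
        c("simulate", "landcover", "pas")),
      n_axes = nAxes(pca),
      files = as.list(tools::md5sum(files)))
    names(manifest$files) <- basename(names(manifest$files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeRunConfig(config, file.path(out_dir, "config.yaml"))
  }

  invisible(list(climate = climate, pca = pca, species = speciesRuns,
                 evaluation = evalTab, range_change = changeTab,
                 richness = richness, gap = gapTab, null_model = nullTab,
                 protected_richness = protRich, pas = pas,
                 landcover = landcover, mask = mask, manifest = manifest))
}
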