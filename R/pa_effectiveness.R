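#' @rdname generateProtectedAreas
#' @param x a [PAUnit-class].
#' @export
paCells <- function(x) x@cells

#' @rdname generateProtectedAreas
#' @export
paArea <- function(x) x@area

#' @rdname generateProtectedAreas
#' @export
paCategory <- function(x) x@category

#' @rdname generateProtectedAreas
#' @export
paId <- function(x) x@id

setMethod("show", "PAUnit", function(object) {
  cat(sprintf("PAUnit '%s' (%s): %d cells, %.0f km2\n", object@id,
              object@category, nrow(object@cells), object@area))
})

# Union of PA footprints as a logical matrix on the grid of `template`.
paUnionMask <- function(pas, template) {
  m <- matrix(FALSE, nrow(template@values), ncol(template@values))
  for (pa in pas) m[pa@cells] <- TRUE
  m
}

#' Filter protected areas by biome membership and minimum size
#'
#' Each footprint is first clipped to the biome mask (only the part inside
#' the study area counts), then dropped if the remaining area falls below
#' `min_area` — small fragments would overstate the species they contain at
#' the modelling resolution.
#'
#' @param pas list of [PAUnit-class].
#' @param biome_mask study-area [RasterGrid-class].
#' @param min_area minimum clipped area in km2 (default 50).
#' @param cell_areas per-cell area matrix (km2); default uniform from the
#'   PA areas themselves.
#' @return the filtered (clipped) list of [PAUnit-class].
#' @export
filterPAs <- function(pas, biome_mask, min_area = 50, cell_areas = NULL) {
  inside <- maskInterior(biome_mask)
  if (is.null(cell_areas)) {
    perCell <- vapply(pas, function(p)
      if (nrow(p@cells)) p@area / nrow(p@cells) else NA_real_, numeric(1))
    unit <- stats::median(perCell, na.rm = TRUE)
    cell_areas <- matrix(unit, nrow(biome_mask@values), ncol(biome_mask@values))
  }
  out <- list()
  for (pa in pas) {
    keep <- inside[pa@cells]
    cells <- pa@cells[keep, , drop = FALSE]
    if (nrow(cells) == 0L) next
    area <- sum(cell_areas[cells])
    if (area < min_area) next
    out[[length(out) + 1L]] <- initialize(pa, cells = cells, area = area)
  }
  out
}

#' Range-size-dependent representation target
#'
#' Restricted-range species (potential distribution below 1,000 km2) should
#' have 100% of their range protected; widespread species (above
#' 250,000 km2) at least 10%; between the anchors the target is
#' interpolated linearly in log area:
#' `100 - 90 * (log(area) - log(1000)) / (log(250000) - log(1000))`.
#'
#' @param range_area potential-distribution area in km2 (> 0).
#' @param area_full,area_min the two anchor areas (km2).
#' @return target percentage in \[10, 100\].
#' @examples
#' representationTarget(800)      # 100
#' representationTarget(500000)   # 10
#' @export
representationTarget <- function(range_area, area_full = 1000,
                                 area_min = 250000) {
  if (any(range_area <= 0)) stop("range area must be positive", call. = FALSE)
  t <- 100 - 90 * (log(range_area) - log(area_full)) /
    (log(area_min) - log(area_full))
  pmin(100, pmax(10, t))
}

#' Percent of a range inside the protected-area network
#'
#' Area-weighted fraction of presence cells covered by the union of PA
#' footprints (overlapping PAs count once).
#'
#' @param binary 0/1 [RasterGrid-class] range map.
#' @param pas list of [PAUnit-class].
#' @param cell_areas per-cell area matrix (km2).
#' @return achieved protection in percent.
#' @export
achievedProtection <- function(binary, pas, cell_areas) {
  inPA <- paUnionMask(pas, binary)
  pres <- binary@values == 1 & !is.na(binary@values)
  tot <- sum(cell_areas[pres])
  if (tot == 0) stop("empty range: achieved protection undefined", call. = FALSE)
  100 * sum(cell_areas[pres & inPA]) / tot
}

#' Gap-analysis conservation classes
#'
#' Attainment is the achieved protection as a percentage of the target;
#' the class thresholds are 90 / 70 / 20:
#' Protected (P) at >= 90, Partially Protected (PP) at \[70, 90),
#' Gap (G) at \[20, 70), Not Protected (NP) below 20.
#'
#' @param achieved_pct percent of the range inside PAs.
#' @param target_pct representation target (> 0).
#' @return list with `attainment` (percent of target) and `category`.
#' @export
classifyGap <- function(achieved_pct, target_pct) {
  if (target_pct <= 0) stop("target must be positive", call. = FALSE)
  att <- achieved_pct / target_pct * 100
  cat <- if (att >= 90) "P" else if (att >= 70) "PP" else if (att >= 20) "G"
         else "NP"
  list(attainment = att, category = cat)
}

#' Per-species gap analysis across scenarios
#'
#' @param binary_maps nested list: `binary_maps[[scenario]][[species]]`,
#'   each a 0/1 [RasterGrid-class].
#' @param pas filtered list of [PAUnit-class].
#' @param cell_areas per-cell area matrix (km2).
#' @return data.frame: species, scenario, range_area, target_pct,
#'   achieved_pct, attainment, category.
#' @export
gapAnalysis <- function(binary_maps, pas, cell_areas) {
  out <- list()
  for (scen in names(binary_maps)) {
    for (sp in names(binary_maps[[scen]])) {
      b <- binary_maps[[scen]][[sp]]
      area <- rangeArea(b, cell_areas)
      if (area == 0) {
        out[[length(out) + 1L]] <- data.frame(
          species = sp, scenario = scen, range_area = 0,
          target_pct = NA_real_, achieved_pct = NA_real_,
          attainment = NA_real_, category = NA_character_)
        next
      }
      target <- representationTarget(area)
      achieved <- achievedProtection(b, pas, cell_areas)
      cls <- classifyGap(achieved, target)
      out[[length(out) + 1L]] <- data.frame(
        species = sp, scenario = scen, range_area = area,
        target_pct = target, achieved_pct = achieved,
        attainment = cls$attainment, category = cls$category)
    }
  }
  do.call(rbind, out)
}

# All translations (dr, dc) that keep every cell of `cells` inside the
# domain mask. Returns a 2-column matrix of offsets.
validPlacements <- function(cells, domain) {
  d <- dim(domain)
  r0 <- min(cells[, 1]); c0 <- min(cells[, 2])
  rel <- cbind(cells[, 1] - r0, cells[, 2] - c0)
  h <- max(rel[, 1]); w <- max(rel[, 2])
  offs <- expand.grid(dr = seq_len(d[1] - h) - 1L, dc = seq_len(d[2] - w) - 1L)
  ok <- vapply(seq_len(nrow(offs)), function(i) {
    all(domain[cbind(rel[, 1] + offs$dr[i] + 1L, rel[, 2] + offs$dc[i] + 1L)])
  }, logical(1))
  as.matrix(offs[ok, , drop = FALSE])
}

#' Randomly relocate a protected area, preserving its shape
#'
#' The footprint is translated by an offset drawn uniformly among all
#' placements that keep every cell inside the domain; no rotation or
#' reflection, so size, orientation and shape are preserved exactly.
#'
#' @param pa a [PAUnit-class].
#' @param domain_mask study-area [RasterGrid-class].
#' @param seed integer seed.
#' @return a relocated [PAUnit-class] with the same cell count and area.
#' @export
randomizePA <- function(pa, domain_mask, seed = 1) {
  domain <- maskInterior(domain_mask)
  placements <- validPlacements(pa@cells, domain)
  if (nrow(placements) == 0)
    stop("protected area does not fit inside the domain", call. = FALSE)
  off <- placements[withSeed(seed, sample.int(nrow(placements), 1L)), ]
  r0 <- min(pa@cells[, 1]); c0 <- min(pa@cells[, 2])
  cells <- cbind(pa@cells[, 1] - r0 + off[1] + 1L,
                 pa@cells[, 2] - c0 + off[2] + 1L)
  initialize(pa, cells = cells)
}

#' Null-model test of a protected area's richness retention
#'
#' The observed statistic (mean per-cell richness inside the footprint, or
#' the summed richness with `statistic = "sum"`) is compared with the same
#' statistic at `n` random shape-preserving relocations of the footprint
#' across the domain; relocations are drawn among the *alternative*
#' placements (the PA's own position is excluded unless it is the only
#' valid one). The p-value is `(1 + #(null >= observed)) / (n + 1)`;
#' the PA is called effective when the observed richness sits in the upper
#' 5% tail of the null distribution (p < `alpha`).
#'
#' @param pa a [PAUnit-class].
#' @param richness richness [RasterGrid-class] (co-registered with the
#'   domain).
#' @param domain_mask study-area [RasterGrid-class].
#' @param n number of randomizations (default 999).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @param statistic `"mean"` (default) or `"sum"` per-cell richness.
#' @return list of class `NullModelResult`: `unit_id`, `observed_stat`,
#'   `null_stats` (length `n`), `p_value`, `effective`.
#' @export
nullModelTest <- function(pa, richness, domain_mask, n = 999, alpha = 0.05,
                          seed = 1, statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  stopIfNotCoRegistered(richness, domain_mask)
  domain <- maskInterior(domain_mask)
  placements <- validPlacements(pa@cells, domain)
  if (nrow(placements) == 0)
    stop("protected area does not fit inside the domain", call. = FALSE)
  stat <- function(cells) {
    v <- richness@values[cells]
    if (statistic == "mean") mean(v, na.rm = TRUE) else sum(v, na.rm = TRUE)
  }
  observed <- stat(pa@cells)
  r0 <- min(pa@cells[, 1]); c0 <- min(pa@cells[, 2])
  rel <- cbind(pa@cells[, 1] - r0, pa@cells[, 2] - c0)
  # the null describes *alternative* placements: drop the PA's own position
  # (kept only when it is the sole valid placement)
  alt <- placements[!(placements[, 1] == r0 - 1L &
                      placements[, 2] == c0 - 1L), , drop = FALSE]
  if (nrow(alt) > 0) placements <- alt
  draws <- withSeed(seed,
                    placements[sample.int(nrow(placements), n, replace = TRUE), ,
                               drop = FALSE])
  nulls <- vapply(seq_len(n), function(i)
    stat(cbind(rel[, 1] + draws[i, 1] + 1L, rel[, 2] + draws[i, 2] + 1L)),
    numeric(1))
  p <- (1 + sum(nulls >= observed)) / (n + 1)
  structure(list(unit_id = pa@id, observed_stat = observed,
                 null_stats = nulls, p_value = p, effective = p < alpha),
            class = "NullModelResult")
}

#' Proportion of total richness inside the protected-area network
#'
#' `100 * sum(richness over PA-union cells) / sum(richness over the study
#' mask)` — how much of the scenario's stacked richness the network
#' captures.
#'
#' @param richness richness [RasterGrid-class].
#' @param pas list of [PAUnit-class].
#' @param mask study-area [RasterGrid-class] (`NULL` = all non-nodata
#'   cells).
#' @return percent of richness protected.
#' @export
protectedRichnessProportion <- function(richness, pas, mask = NULL) {
  keep <- !is.na(richness@values)
  if (!is.null(mask)) keep <- keep & maskInterior(mask)
  tot <- sum(richness@values[keep])
  if (tot == 0) stop("total richness is zero", call. = FALSE)
  inPA <- paUnionMask(pas, richness) & keep
  100 * sum(richness@values[inPA]) / tot
}

#' Write / read protected areas as an integer raster plus CSV sidecar
#'
#' The raster holds the PA id (integer index) per cell (ties broken by
#' later PAs overwriting earlier); the sidecar CSV records id, category and
#' area.
#'
#' @param pas list of [PAUnit-class].
#' @param template a [RasterGrid-class] defining the grid.
#' @param raster_file,csv_file output paths.
#' @export
writePAs <- function(pas, template, raster_file, csv_file) {
  m <- matrix(NA_real_, nrow(template@values), ncol(template@values))
  for (i in seq_along(pas)) m[pas[[i]]@cells] <- i
  writeAsciiGrid(withValues(template, m), raster_file)
  utils::write.csv(data.frame(
    id = vapply(pas, paId, character(1)),
    category = vapply(pas, paCategory, character(1)),
    area_km2 = vapply(pas, paArea, numeric(1))), csv_file, row.names = FALSE)
  invisible(list(raster_file, csv_file))
}

#' @rdname writePAs
#' @export
readPAs <- function(raster_file, csv_file) {
  r <- readAsciiGrid(raster_file)
  meta <- utils::read.csv(csv_file, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    new("PAUnit", id = as.character(meta$id[i]), category = meta$category[i],
        cells = which(r@values == i, arr.ind = TRUE), area = meta$area_km2[i])
  })
}
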