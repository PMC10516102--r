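#' Mask a binary range by permitted land-cover classes
#'
#' Presence is retained only where the land-cover raster holds one of the
#' permitted class codes — the overlay of climate suitability on vegetation
#' cover. Each scenario should supply its own land-cover raster.
#'
#' @param binary 0/1 [RasterGrid-class] range map.
#' @param landcover categorical [RasterGrid-class] of class codes.
#' @param allowed vector of permitted class codes (e.g. the codes of the
#'   five broadleaf classes in [allowedLandcoverClasses()]).
#' @return the masked 0/1 [RasterGrid-class].
#' @export
maskLandcover <- function(binary, landcover, allowed) {
  stopIfNotCoRegistered(binary, landcover)
  b <- binary@values
  out <- ifelse(is.na(b), NA,
                as.numeric(b == 1 & !is.na(landcover@values) &
                           landcover@values %in% allowed))
  withValues(binary, out)
}

#' Total area of a binary range
#'
#' @param binary 0/1 [RasterGrid-class].
#' @param cell_areas per-cell area matrix (km2), e.g. from [cellAreas()].
#' @return area in km2.
#' @export
rangeArea <- function(binary, cell_areas) {
  stopifnot(all(cell_areas > 0), identical(dim(cell_areas), dim(binary@values)))
  sum(cell_areas[which(binary@values == 1)])
}

#' Range change between present and future
#'
#' Percent change `(future - present) / present * 100` and its class:
#' species whose absolute change is below 5% are `"stable"`, otherwise
#' `"loss"` or `"gain"` by sign.
#'
#' @param area_present,area_future range areas in km2 (`area_present` > 0).
#' @param stability_pct the stability band half-width in percent
#'   (default 5; strict inequality).
#' @return list with `area_present`, `area_future`, `pct_change`,
#'   `change_class`.
#' @export
rangeChange <- function(area_present, area_future, stability_pct = 5) {
  if (area_present <= 0) stop("present range area must be positive", call. = FALSE)
  pct <- (area_future - area_present) / area_present * 100
  cls <- if (abs(pct) < stability_pct) "stable"
         else if (pct < 0) "loss" else "gain"
  list(area_present = area_present, area_future = area_future,
       pct_change = pct, change_class = cls)
}

#' Percent change in climatic suitability
#'
#' Domain-wide percent change in summed continuous suitability between two
#' ensemble maps (`statistic = "sum"`, the default), or the percent change
#' in mean suitability within the present binary range
#' (`statistic = "mean_within_range"`).
#'
#' @param present_map,future_map continuous suitability
#'   [RasterGrid-class] maps.
#' @param mask optional study-area raster restricting the comparison.
#' @param statistic `"sum"` or `"mean_within_range"`.
#' @param present_binary the present 0/1 range (required for
#'   `"mean_within_range"`).
#' @return percent change (negative = suitability loss).
#' @export
suitabilityChange <- function(present_map, future_map, mask = NULL,
                              statistic = c("sum", "mean_within_range"),
                              present_binary = NULL) {
  statistic <- match.arg(statistic)
  stopIfNotCoRegistered(present_map, future_map)
  keep <- !is.na(present_map@values) & !is.na(future_map@values)
  if (!is.null(mask)) keep <- keep & maskInterior(mask)
  if (statistic == "mean_within_range") {
    if (is.null(present_binary))
      stop("mean_within_range needs the present binary range", call. = FALSE)
    keep <- keep & present_binary@values == 1
  }
  sPres <- sum(present_map@values[keep])
  if (sPres == 0) stop("present suitability sums to zero", call. = FALSE)
  sFut <- sum(future_map@values[keep])
  100 * (sFut - sPres) / sPres
}

#' Stack binary ranges into a species-richness map
#'
#' Cell-wise sum of the species' 0/1 range maps: richness ranges from 0 to
#' the number of species.
#'
#' @param binary_maps list of co-registered 0/1 [RasterGrid-class] maps.
#' @return integer-valued richness [RasterGrid-class].
#' @export
stackRichness <- function(binary_maps) {
  stopifnot(length(binary_maps) >= 1)
  ref <- binary_maps[[1]]
  for (b in binary_maps[-1]) stopIfNotCoRegistered(ref, b)
  acc <- Reduce(`+`, lapply(binary_maps, function(b) {
    v <- b@values
    v[is.na(v)] <- 0
    v
  }))
  allNA <- Reduce(`&`, lapply(binary_maps, function(b) is.na(b@values)))
  acc[allNA] <- NA
  withValues(ref, acc)
}

#' Range-change table across species and scenarios
#'
#' @param areas data.frame with columns `species`, `scenario`,
#'   `area_km2`; must contain a `"present"` scenario row per species.
#' @param stability_pct stability band (percent).
#' @return data.frame: species, scenario, area_present, area_future,
#'   pct_change, change_class.
#' @export
rangeChangeTable <- function(areas, stability_pct = 5) {
  out <- list()
  for (sp in unique(areas$species)) {
    a <- areas[areas$species == sp, ]
    pres <- a$area_km2[a$scenario == "present"]
    if (length(pres) != 1) stop("need one present row per species", call. = FALSE)
    for (i in which(a$scenario != "present")) {
      rc <- rangeChange(pres, a$area_km2[i], stability_pct)
      out[[length(out) + 1L]] <- data.frame(
        species = sp, scenario = a$scenario[i],
        area_present = rc$area_present, area_future = rc$area_future,
        pct_change = rc$pct_change, change_class = rc$change_class)
    }
  }
  do.call(rbind, out)
}
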