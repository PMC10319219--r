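#' Flood intensity map from stage maps
#'
#' Per-pixel count of the intra-season stage maps in which the pixel was
#' flooded. With the three-stage design the values 1-3 mean a single, a
#' double and a triple inundation.
#'
#' @param stage_maps List of co-registered binary flood maps (one per
#'   stage). More than three stages triggers a warning: the 0-3 class scheme
#'   assumes at most three.
#' @return `fs_raster` of counts `0..k`; nodata where any stage is nodata.
#' @export
intensity_map <- function(stage_maps) {
  stack_count(stage_maps, warn_over = 3L,
              warn_msg = "more than 3 stage maps: intensity exceeds the 0-3 class scheme")
}

#' Flood frequency map from annual maps
#'
#' Per-pixel count of years in which the pixel was flooded (0-6 for a
#' six-year record).
#'
#' @param annual_maps List of co-registered binary annual flood maps.
#' @return `fs_raster` of counts.
#' @export
frequency_map <- function(annual_maps) {
  stack_count(annual_maps, warn_over = Inf, warn_msg = NULL)
}

stack_count <- function(maps, warn_over, warn_msg) {
  if (!length(maps)) stop("need at least one map", call. = FALSE)
  do.call(assert_same_geometry, maps)
  if (length(maps) > warn_over) warning(warn_msg, call. = FALSE)
  vals <- Reduce(`+`, lapply(maps, function(m) m$values))
  with_values(maps[[1L]], vals)
}

#' Newly flooded area relative to the historical maximum
#'
#' Compares the current flood extent with the pixelwise union of the prior
#' years' extents (the "maximum ever-flooded" area). Reports the map of
#' pixels flooded now but never before, its area, and that area as an
#' integer percentage of the maximum ever-flooded area (rounded half away
#' from zero, the convention behind printed shares like 29%).
#'
#' @param current Binary flood map of the year under study.
#' @param prior List of binary flood maps for the preceding years.
#' @return List with `new_map` (binary `fs_raster`), `new_area_km2`,
#'   `max_ever_km2` and `ratio_percent`.
#' @export
newly_added <- function(current, prior) {
  if (!length(prior)) stop("need at least one prior-year map", call. = FALSE)
  do.call(assert_same_geometry, c(list(current), prior))
  union_prior <- Reduce(function(a, b) pmax(a, b),
                        lapply(prior, function(m) m$values))
  max_ever <- sum(union_prior == 1, na.rm = TRUE) *
    current$pixel_size^2 / 1e6
  if (max_ever == 0)
    stop("prior-year union is empty: newly-added ratio undefined",
         call. = FALSE)
  newv <- ifelse(is.na(current$values) | is.na(union_prior), NA_real_,
                 (current$values == 1 & union_prior == 0) + 0)
  new_map <- with_values(current, newv)
  new_area <- area_km2(new_map, 1)
  list(new_map = new_map, new_area_km2 = new_area,
       max_ever_km2 = max_ever,
       ratio_percent = share_percent(new_area, max_ever))
}

#' Per-zone flood-intensity area table
#'
#' Tabulates, for every zone and every intensity class, the flooded area in
#' km². Marginal sums over zones reproduce the global per-class areas
#' because each pixel belongs to exactly one zone.
#'
#' @param map Intensity `fs_raster` (values 0..3).
#' @param zones `fs_zones` tibble.
#' @param classes Intensity classes to report (default 1:3, flooded only).
#' @return Tibble `zone_id`, `name`, `class`, `area_km2`.
#' @export
intensity_area_report <- function(map, zones, classes = 1:3) {
  zonal_class_areas(map, zones, classes = classes)
}
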