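#' Run the full flood-mapping and damage-assessment pipeline
#'
#' End-to-end replay on a synthetic scene: simulate the scene, optionally
#' speckle-filter every acquisition, composite the stacks, build the CDAT
#' and NDFI change indices per stage, resolve thresholds (sample-calibrated
#' by default, statistical `mean - Kc*sd` on the filter-eligible pixels, or
#' fixed values), apply the terrain / background / seasonal filter cascade,
#' intersect the two algorithms into per-stage synergy maps, then derive the
#' intensity map, the multi-year frequency and newly-flooded accounting, the
#' sample-based accuracy metrics, the optical cross-map agreement, and the
#' cropland damage report. Every output table is a tibble; rasters, tables
#' and a JSON manifest (parameters, seed, resolved thresholds, filter pixel
#' accounting) are written when `out_dir` is given.
#'
#' @param config A [scene_config()] (or a YAML path readable by
#'   [read_scene_config()]).
#' @param out_dir Output directory; `NULL` skips writing.
#' @param threshold `"calibrated"` (sample-based search), `"auto"`
#'   (statistical) or a named numeric vector `c(cdat = , ndfi = )`.
#' @param Kc Coefficient for the `"auto"` threshold.
#' @param seasonal_cutoff_db Land-water cutoff for the seasonal filter (dB).
#' @param slope_cutoff_deg Terrain-filter slope cutoff (degrees).
#' @param filter_speckle Median-filter each acquisition before compositing;
#'   the default filters exactly when speckle is simulated
#'   (`config$looks < Inf`).
#' @param filter_window Speckle-filter window.
#' @param quiet Suppress progress messages.
#' @return A list of class `fs_pipeline_result`: scene, per-stage maps,
#'   thresholds, intensity/frequency products, accuracy metrics, optical
#'   cross-map, damage results, and the manifest.
#' @export
run_flood_pipeline <- function(config = scene_config(), out_dir = NULL,
                               threshold = "calibrated", Kc = 1.5,
                               seasonal_cutoff_db = -19,
                               slope_cutoff_deg = 5,
                               filter_speckle = NULL, filter_window = 3,
                               quiet = TRUE) {
  if (is.character(config) && length(config) == 1L && file.exists(config))
    config <- read_scene_config(config)
  stopifnot(inherits(config, "fs_scene_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  say("simulating scene (seed %d)", config$seed)
  scene <- generate_scene(config)
  samples <- sample_points(scene$truth, config$n_samples,
                           config$flooded_fraction, seed = config$seed,
                           train_fraction = config$train_fraction)

  filter_speckle <- filter_speckle %||% is.finite(config$looks)
  prep <- function(s) {
    if (!filter_speckle) return(s)
    raster_stack(lapply(s$rasters, speckle_filter, window = filter_window),
                 s$dates)
  }
  ref <- prep(scene$ref_stack)
  floods <- lapply(scene$flood_stacks, prep)
  all_flood <- raster_stack(
    unlist(lapply(floods, function(s) s$rasters), recursive = FALSE),
    do.call(c, lapply(floods, function(s) s$dates)))

  min_ref <- temporal_min(ref)
  elig_terrain <- terrain_filter(scene$dem, slope_cutoff_deg)

  # overall (whole flood period) indices used for threshold resolution
  min_flood_all <- temporal_min(all_flood)
  d_all <- cdat_difference(min_flood_all, min_ref)
  ndfi_all <- ndfi(ref, all_flood)
  seas_all <- seasonal_filter(min_flood_all, seasonal_cutoff_db)
  bg_all <- background_filter(d_all)

  thresholds <- resolve_thresholds(threshold, d_all, ndfi_all, samples,
                                   elig_terrain, bg_all, seas_all, Kc,
                                   config$seed)
  say("thresholds: CDAT %.4g, NDFI %.4g (%s)",
      thresholds$cdat$T, thresholds$ndfi$T, thresholds$cdat$method)

  map_stage <- function(fs) {
    min_f <- temporal_min(fs)
    d <- cdat_difference(min_f, min_ref)
    nd <- ndfi(ref, fs)
    seas <- seasonal_filter(min_f, seasonal_cutoff_db)
    bg <- background_filter(d)
    cdat_map <- classify_flood(d, thresholds$cdat, elig_terrain, bg, seas)
    ndfi_map <- classify_flood(nd, thresholds$ndfi, elig_terrain, seas)
    list(cdat = cdat_map, ndfi = ndfi_map,
         synergy = synergy_map(cdat_map, ndfi_map),
         filter_counts = c(
           terrain_removed = sum(elig_terrain$values == 0, na.rm = TRUE),
           background_removed = sum(bg$values == 0, na.rm = TRUE),
           seasonal_removed = sum(seas$values == 0, na.rm = TRUE)))
  }
  say("mapping %d stages", length(floods))
  stage_results <- lapply(floods, map_stage)
  stage_maps <- lapply(stage_results, `[[`, "synergy")

  intensity <- intensity_map(stage_maps)
  union_map <- with_values(intensity, (intensity$values >= 1) + 0)

  prior_years <- as.character(setdiff(
    as.integer(names(scene$truth$annual_masks)), config$flood_year))
  priors <- scene$truth$annual_masks[prior_years]
  annual_maps <- c(priors, list(union_map))
  freq <- frequency_map(annual_maps)
  newly <- newly_added(union_map, priors)

  cm <- confusion(union_map, samples, split = "val")
  metrics <- accuracy_metrics(cm)
  say("validation OA %.2f%%", metrics$oa)

  oi <- optical_indices(scene$optical$red, scene$optical$blue,
                        scene$optical$nir, scene$optical$swir1)
  omap <- optical_flood(oi$ndvi, oi$evi, oi$lswi)
  cross <- crossmap_agreement(union_map, omap, scene$zones)

  damage <- assess_crop_damage(union_map, intensity, scene$truth$cropland,
                               scene$vi, scene$zones)

  stage_area <- vapply(stage_maps, area_km2, numeric(1), category = 1)
  manifest <- list(
    package_version = as.character(utils::packageVersion("floodscope")),
    seed = config$seed, shape = config$shape,
    pixel_size = config$pixel_size, looks = config$looks,
    sigma_db = config$sigma_db, threshold_method = thresholds$cdat$method,
    threshold_cdat = thresholds$cdat$T, threshold_ndfi = thresholds$ndfi$T,
    Kc = Kc, seasonal_cutoff_db = seasonal_cutoff_db,
    slope_cutoff_deg = slope_cutoff_deg,
    filter_speckle = filter_speckle, filter_window = filter_window,
    filter_counts = lapply(stage_results,
                           function(x) as.list(x$filter_counts)),
    stage_area_km2 = stage_area)

  result <- structure(list(
    scene = scene, samples = samples, thresholds = thresholds,
    stage_results = stage_results, stage_maps = stage_maps,
    intensity = intensity, union_map = union_map, frequency = freq,
    newly_added = newly, confusion = cm, metrics = metrics,
    optical_map = omap, crossmap = cross, damage = damage,
    stage_area_km2 = stage_area, manifest = manifest),
    class = "fs_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

resolve_thresholds <- function(threshold, d_all, ndfi_all, samples,
                               elig_terrain, bg_all, seas_all, Kc, seed) {
  if (is.numeric(threshold)) {
    if (!all(c("cdat", "ndfi") %in% names(threshold)))
      stop("numeric thresholds need names 'cdat' and 'ndfi'", call. = FALSE)
    return(list(cdat = fixed_threshold(threshold[["cdat"]], "CDAT"),
                ndfi = fixed_threshold(threshold[["ndfi"]], "NDFI")))
  }
  switch(match.arg(threshold, c("calibrated", "auto")),
         calibrated = list(
           cdat = calibrate_threshold(d_all, samples, seed = seed),
           ndfi = calibrate_threshold(ndfi_all, samples, seed = seed)),
         auto = list(
           cdat = adaptive_threshold(
             apply_mask(d_all, elig_terrain, bg_all, seas_all), Kc = Kc),
           ndfi = adaptive_threshold(
             apply_mask(ndfi_all, elig_terrain, seas_all), Kc = Kc)))
}

#' Cropland damage assessment from vegetation-index series
#'
#' Builds the damage components (NDVI and EVI differences, DVDI from the
#' historical climatology), reclassifies each over the flooded-cropland
#' pixels with geometrical intervals (declines >= 0 stay class 0), and
#' combines them with flood intensity into the severity degree and its
#' slight / moderate / severe classes.
#'
#' @param flood_map Binary flood map of the whole flood period.
#' @param intensity Intensity raster (0-3).
#' @param crops Cropland raster (codes 0/1/2).
#' @param vi VI series list as produced by [generate_vi_series()].
#' @param zones `fs_zones` for the report.
#' @return List: `overlay` ([flooded_cropland()] output), `ndvi_d`,
#'   `evi_d`, `dvdi`, the three reclassified rasters, `degree`, `classes`,
#'   and `report` ([damage_report()] output).
#' @export
assess_crop_damage <- function(flood_map, intensity, crops, vi, zones) {
  overlay <- flooded_cropland(flood_map, crops)
  dom <- overlay$mask$values == 1
  dom[is.na(dom)] <- FALSE
  if (!any(dom)) {
    warning("no flooded cropland: damage assessment is empty")
    empty <- with_values(flood_map,
                         matrix(NA_real_, nrow(dom), ncol(dom)))
    return(list(overlay = overlay, ndvi_d = empty, evi_d = empty,
                dvdi = empty, ndvi_cls = empty, evi_cls = empty,
                dvdi_cls = empty, degree = empty, classes = empty,
                report = damage_report(empty, crops, zones)))
  }
  restrict <- function(r) {
    v <- r$values
    v[!dom] <- NA_real_
    with_values(r, v)
  }
  ndvi_d <- vi_difference(vi$ndvi_a, vi$ndvi_b)
  evi_d <- vi_difference(vi$evi_a, vi$evi_b)
  clim <- vi_climatology(vi$hist)
  dv <- dvdi(mvci(vi$ndvi_a, clim$med, clim$max),
             mvci(vi$ndvi_pre, clim$med, clim$max))
  ndvi_cls <- geometric_interval_reclass(restrict(ndvi_d), zero_floor = TRUE)
  evi_cls <- geometric_interval_reclass(restrict(evi_d), zero_floor = TRUE)
  dvdi_cls <- geometric_interval_reclass(restrict(dv), zero_floor = TRUE)
  intensity_dom <- restrict(intensity)
  fill0 <- function(r) {
    v <- r$values
    v[dom & is.na(v)] <- 0
    with_values(r, v)
  }
  sev <- severity_degree(fill0(ndvi_cls), fill0(evi_cls), fill0(dvdi_cls),
                         intensity_dom)
  list(overlay = overlay, ndvi_d = ndvi_d, evi_d = evi_d, dvdi = dv,
       ndvi_cls = ndvi_cls, evi_cls = evi_cls, dvdi_cls = dvdi_cls,
       degree = sev$degree, classes = sev$classes,
       report = damage_report(sev$classes, crops, zones))
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(r, name, nodata = -9999)
    write_raster(r, file.path(out_dir, name), nodata = nodata)
  for (k in seq_along(result$stage_maps))
    wr(result$stage_maps[[k]], sprintf("flood_stage%d.asc", k), nodata = 255)
  wr(result$intensity, "intensity.asc", nodata = 255)
  wr(result$union_map, "flood_2020.asc", nodata = 255)
  wr(result$frequency, "frequency.asc", nodata = 255)
  wr(result$newly_added$new_map, "newly_added.asc", nodata = 255)
  wr(result$damage$degree, "damage_degree.asc")
  wr(result$damage$classes, "damage_classes.asc", nodata = 255)
  write_samples(result$samples, file.path(out_dir, "samples.csv"))
  utils::write.csv(result$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(result$crossmap$table,
                   file.path(out_dir, "crossmap_zones.csv"),
                   row.names = FALSE)
  utils::write.csv(result$damage$report$by_zone,
                   file.path(out_dir, "damage_by_zone.csv"),
                   row.names = FALSE)
  utils::write.csv(result$damage$report$summary,
                   file.path(out_dir, "damage_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(
    intensity_area_report(result$intensity, result$scene$zones),
    file.path(out_dir, "intensity_by_zone.csv"), row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.fs_pipeline_result <- function(x, ...) {
  cat("<fs_pipeline_result>\n")
  cat(sprintf("  stage areas (km2): %s\n",
              paste(sprintf("%.3f", x$stage_area_km2), collapse = ", ")))
  cat(sprintf("  validation OA: %.2f%%  F1: %.3f\n", x$metrics$oa,
              x$metrics$f1))
  cat(sprintf("  newly flooded: %.3f km2 (%d%% of max ever flooded)\n",
              x$newly_added$new_area_km2, x$newly_added$ratio_percent))
  invisible(x)
}
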