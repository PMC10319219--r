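#' Flooded-cropland overlay
#'
#' Intersects a binary flood map with a cropland raster (codes 0 = non-crop,
#' 1 = rice, 2 = other crop) and accounts the inundated area per crop type.
#'
#' @param flood Binary flood map.
#' @param crops Cropland raster with codes `{0, 1, 2}`.
#' @return List with `mask` (binary flooded-cropland raster), `areas`
#'   (tibble `crop`, `area_km2`) and `rice_share_percent`.
#' @export
flooded_cropland <- function(flood, crops) {
  assert_same_geometry(flood, crops)
  codes <- crops$values[!is.na(crops$values)]
  if (!all(codes %in% 0:2))
    stop("cropland codes must be 0 (non-crop), 1 (rice) or 2 (other)",
         call. = FALSE)
  m <- ifelse(is.na(flood$values) | is.na(crops$values), NA_real_,
              (flood$values == 1 & crops$values > 0) + 0)
  mask <- with_values(flood, m)
  px_km2 <- flood$pixel_size^2 / 1e6
  rice <- sum(m == 1 & crops$values == 1, na.rm = TRUE) * px_km2
  other <- sum(m == 1 & crops$values == 2, na.rm = TRUE) * px_km2
  total <- rice + other
  list(mask = mask,
       areas = tibble::tibble(crop = c("rice", "other"),
                              area_km2 = c(rice, other)),
       rice_share_percent = if (total > 0) share_percent(rice, total) else
         NA_real_)
}

#' Vegetation-index difference (after minus before)
#'
#' The elementwise post-flood minus pre-flood window mean; a flood-damaged
#' canopy shows a negative difference.
#'
#' @param after_mean,before_mean Window-mean VI rasters.
#' @return `fs_raster` of differences.
#' @export
vi_difference <- function(after_mean, before_mean) {
  assert_same_geometry(after_mean, before_mean)
  with_values(after_mean, after_mean$values - before_mean$values)
}

#' Historical NDVI climatology (per-pixel median and maximum)
#'
#' @param hist An `fs_stack` of historical NDVI layers (one per year).
#' @return List with `med` and `max` rasters.
#' @export
vi_climatology <- function(hist) {
  list(med = temporal_median(hist), max = temporal_max(hist))
}

temporal_max <- function(s) {
  out <- temporal_composite_max(s)
  out
}

temporal_composite_max <- function(s) {
  arr <- vapply(s$rasters, function(r) as.vector(r$values),
                numeric(length(s$rasters[[1L]]$values)))
  arr <- matrix(arr, ncol = length(s$rasters))
  vals <- apply(arr, 1L, function(x) if (all(is.na(x))) NA_real_ else
    max(x, na.rm = TRUE))
  out <- with_values(s$rasters[[1L]],
                     matrix(vals, nrow = nrow(s$rasters[[1L]]$values)))
  attr(out, "statistic") <- "max"
  out
}

#' Modified vegetation condition index (mVCI) and its flood change (DVDI)
#'
#' `mVCI = (NDVI - NDVI_med) / (NDVI_max - NDVI_med)` anchors the current
#' window-mean NDVI at the per-pixel historical median (0) and maximum (1).
#' The disaster vegetation damage index is the post-minus-pre change,
#' `DVDI = mVCI_a - mVCI_b`; a healthy canopy drowned by the flood drives it
#' negative. Pixels whose historical maximum equals the median carry no
#' usable anchor and become nodata.
#'
#' @param ndvi_mean Window-mean NDVI raster.
#' @param ndvi_med,ndvi_max Historical climatology rasters (see
#'   [vi_climatology()]).
#' @return `fs_raster`.
#' @export
mvci <- function(ndvi_mean, ndvi_med, ndvi_max) {
  assert_same_geometry(ndvi_mean, ndvi_med, ndvi_max)
  den <- ndvi_max$values - ndvi_med$values
  vals <- ifelse(is.na(den) | den <= 1e-12, NA_real_,
                 (ndvi_mean$values - ndvi_med$values) / den)
  with_values(ndvi_mean, vals)
}

#' @rdname mvci
#' @param mvci_a,mvci_b mVCI rasters after (September-October) and before
#'   (June-July) the flood.
#' @export
dvdi <- function(mvci_a, mvci_b) {
  assert_same_geometry(mvci_a, mvci_b)
  with_values(mvci_a, mvci_a$values - mvci_b$values)
}

#' Geometrical-interval reclassification
#'
#' Splits a continuous raster into `n_classes` classes whose break widths
#' form a geometric progression: widths `w, w*r, w*r^2, ...` spanning
#' exactly the data range. The common ratio `r` is selected by a dense
#' search over `r` in `[1/8, 8]` (log-spaced) minimizing the variance of the
#' per-class pixel counts - the balancing property geometrical intervals are
#' used for on skewed data; ties prefer the `r` closest to 1. Classes are
#' numbered so that the most negative interval (largest vegetation-index
#' decline) gets the highest class.
#'
#' @param r Continuous `fs_raster` (e.g. an NDVI difference).
#' @param n_classes Number of classes (default 4, classes 0-3).
#' @param zero_floor If `TRUE`, values `>= 0` (no decline) are forced to
#'   class 0 regardless of the breaks, the orientation used for damage
#'   scoring.
#' @return `fs_raster` of integer classes `0..n_classes-1` with attribute
#'   `breaks` (ascending) and `ratio`.
#' @export
geometric_interval_reclass <- function(r, n_classes = 4, zero_floor = FALSE) {
  stopifnot(is_raster(r))
  x <- r$values[!is.na(r$values)]
  if (!length(x)) stop("no valid pixels to reclassify", call. = FALSE)
  lo <- min(x); hi <- max(x)
  if (length(unique(x)) < n_classes || hi - lo < 1e-300) {
    warning("fewer distinct values than classes; all pixels in class 0")
    out <- with_values(r, ifelse(is.na(r$values), NA_real_, 0))
    attr(out, "breaks") <- c(lo, hi)
    attr(out, "ratio") <- 1
    return(out)
  }
  ratios <- exp(seq(log(1 / 8), log(8), length.out = 2001L))
  scores <- vapply(ratios, function(rr)
    stats::var(class_counts(x, geometric_breaks(lo, hi, n_classes, rr))),
    numeric(1))
  best <- min(scores)
  cand <- which(scores <= best + 1e-9)
  ratio <- ratios[cand[which.min(abs(log(ratios[cand])))]]
  breaks <- geometric_breaks(lo, hi, n_classes, ratio)
  cls <- matrix(classify_breaks(r$values, breaks), nrow = nrow(r$values))
  # orientation: interval containing the minimum (largest decline) = top class
  cls <- (n_classes - 1) - cls
  if (zero_floor) cls[!is.na(r$values) & r$values >= 0] <- 0
  out <- with_values(r, cls)
  attr(out, "breaks") <- breaks
  attr(out, "ratio") <- ratio
  out
}

geometric_breaks <- function(lo, hi, k, r) {
  w <- if (abs(r - 1) < 1e-12) rep((hi - lo) / k, k) else
    (hi - lo) * (r - 1) / (r^k - 1) * r^(0:(k - 1))
  cumsum(c(lo, w))
}

class_counts <- function(x, breaks) {
  tabulate(classify_breaks(x, breaks) + 1L, nbins = length(breaks) - 1L)
}

#' Assign values to intervals (lowest interval = 0); the first interval is
#' closed on the left, all intervals closed on the right.
#' @noRd
classify_breaks <- function(v, breaks) {
  k <- length(breaks) - 1L
  cls <- findInterval(v, breaks, left.open = TRUE, rightmost.closed = FALSE)
  cls[!is.na(v) & v <= breaks[1L]] <- 1L
  cls[!is.na(v) & v >= breaks[k + 1L]] <- k
  cls - 1L
}

#' Composite crop-damage severity degree
#'
#' Quarter-weighted sum of the three reclassified vegetation-index changes
#' and the flood intensity:
#' `degree = (NDVI_class + EVI_class + DVDI_class + intensity) / 4`,
#' evaluated only on flooded cropland (intensity >= 1). Degrees are classed
#' as slight (0, 1], moderate (1, 2] and severe (2, 3].
#'
#' @param ndvi_cls,evi_cls,dvdi_cls Reclassified (0-3) damage-component
#'   rasters.
#' @param intensity Flood intensity raster (0-3).
#' @return List with `degree` (continuous `fs_raster`, nodata off the
#'   flooded cropland) and `classes` (`fs_raster` coded 0 none / 1 slight /
#'   2 moderate / 3 severe).
#' @export
severity_degree <- function(ndvi_cls, evi_cls, dvdi_cls, intensity) {
  assert_same_geometry(ndvi_cls, evi_cls, dvdi_cls, intensity)
  on_domain <- !is.na(intensity$values) & intensity$values >= 1
  deg <- (ndvi_cls$values + evi_cls$values + dvdi_cls$values +
            intensity$values) / 4
  deg[!on_domain] <- NA_real_
  cls <- ifelse(is.na(deg), NA_real_, pmin(ceiling(deg - 1e-12), 3))
  list(degree = with_values(intensity, deg),
       classes = with_values(intensity, cls))
}

#' Damage report by class, crop type and zone
#'
#' Areas of slight / moderate / severe damage per crop type and zone, plus
#' whole-map class areas and their integer-percent shares of the total
#' damaged area.
#'
#' @param damage_classes Damage-class raster (1 slight / 2 moderate / 3
#'   severe) from [severity_degree()].
#' @param crops Cropland raster (codes 0/1/2).
#' @param zones `fs_zones`.
#' @return List with `by_zone` (tibble `zone_id`, `name`, `class`, `crop`,
#'   `area_km2`) and `summary` (tibble `class`, `area_km2`,
#'   `share_percent`).
#' @export
damage_report <- function(damage_classes, crops, zones) {
  assert_same_geometry(damage_classes, crops)
  labels <- c("slight", "moderate", "severe")
  px_km2 <- damage_classes$pixel_size^2 / 1e6
  by_zone <- purrr::map_dfr(1:3, function(cl)
    purrr::map_dfr(c(rice = 1, other = 2), function(code) {
      sel <- with_values(damage_classes,
                         ifelse(is.na(damage_classes$values), NA_real_,
                                (damage_classes$values == cl &
                                   !is.na(crops$values) &
                                   crops$values == code) + 0))
      dplyr::mutate(zonal_area(sel, zones, 1),
                    class = labels[cl], .before = "area_km2")
    }, .id = "crop")) |>
    dplyr::relocate("crop", .after = "class") |>
    dplyr::arrange(.data$zone_id, .data$class, .data$crop)
  areas <- vapply(1:3, function(cl)
    sum(damage_classes$values == cl, na.rm = TRUE) * px_km2, numeric(1))
  total <- sum(areas)
  summary <- tibble::tibble(
    class = labels, area_km2 = areas,
    share_percent = if (total > 0) vapply(areas, share_percent,
                                          numeric(1), whole = total) else
      rep(NA_real_, 3))
  list(by_zone = by_zone, summary = summary)
}
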