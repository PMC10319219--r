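#' CDAT difference image
#'
#' Change detection and thresholding (CDAT) contrasts the temporal minimum of
#' the flood-period stack with that of the reference stack:
#' `D = min(F) - min(R)` (dB). Newly inundated pixels drop to open-water
#' backscatter only during the flood, so D is strongly negative there, while
#' unchanged land and permanent water sit near zero.
#'
#' @param min_flood,min_ref Min-composites (from [temporal_min()]) of the
#'   flood and reference stacks.
#' @return `fs_raster` with attribute `algorithm = "CDAT"`; nodata wherever
#'   either composite is nodata.
#' @export
cdat_difference <- function(min_flood, min_ref) {
  assert_same_geometry(min_flood, min_ref)
  for (r in list(min_flood, min_ref))
    if (!is.na(composite_statistic(r)) && composite_statistic(r) != "min")
      stop("CDAT expects min-composites, got a ", composite_statistic(r),
           " composite", call. = FALSE)
  out <- with_values(min_ref, min_flood$values - min_ref$values)
  attr(out, "algorithm") <- "CDAT"
  out
}

#' Normalized difference flood index (NDFI)
#'
#' Contrasts the reference-period mean backscatter (the pixel's normal state)
#' with the minimum over the reference and flood stacks taken together (the
#' lowest state it ever reached):
#' `NDFI = (mean(R) - min(R, F)) / (mean(R) + min(R, F))`.
#' On negative-dB imagery a transiently flooded pixel pulls the combined
#' minimum far below the reference mean, driving NDFI negative; the more
#' extreme the flood backscatter drop, the more negative the index.
#'
#' @param ref_stack,flood_stack Co-registered `fs_stack` objects (dB).
#' @param eps Denominator magnitudes below `eps` become nodata.
#' @return `fs_raster` with attribute `algorithm = "NDFI"`.
#' @export
ndfi <- function(ref_stack, flood_stack, eps = 1e-9) {
  for (s in list(ref_stack, flood_stack))
    if (!inherits(s, "fs_stack") || !length(s$rasters))
      stop("ndfi needs non-empty stacks with at least one raster each",
           call. = FALSE)
  mean_r <- temporal_mean(ref_stack)
  min_rf <- combined_min(ref_stack, flood_stack)
  den <- mean_r$values + min_rf$values
  num <- mean_r$values - min_rf$values
  vals <- ifelse(abs(den) < eps, NA_real_, num / den)
  out <- with_values(mean_r, vals)
  attr(out, "statistic") <- NULL
  attr(out, "algorithm") <- "NDFI"
  out
}

index_algorithm <- function(r) attr(r, "algorithm") %||% NA_character_

#' Adaptive threshold from index statistics
#'
#' The change-detection threshold `T = mean(I) - Kc * sd(I)`, computed over
#' the valid pixels of the (already filter-masked) index raster. The default
#' coefficient `Kc = 1.5` is the standard choice for SAR change-detection
#' water extraction; `sd` is the population standard deviation by default.
#'
#' @param index Index raster (CDAT difference or NDFI), typically already
#'   restricted to decision-tree-eligible pixels via [apply_mask()].
#' @param Kc Threshold coefficient.
#' @param std_kind `"population"` (divide by n) or `"sample"` (divide by
#'   n - 1).
#' @return An `fs_threshold` object (threshold `T`, the statistics behind
#'   it, and provenance).
#' @export
adaptive_threshold <- function(index, Kc = 1.5,
                               std_kind = c("population", "sample")) {
  std_kind <- match.arg(std_kind)
  x <- index$values[!is.na(index$values)]
  if (length(x) < 2L)
    stop("adaptive threshold needs at least 2 valid pixels", call. = FALSE)
  m <- mean(x)
  s <- stats::sd(x)
  if (std_kind == "population") s <- s * sqrt((length(x) - 1) / length(x))
  new_threshold(T = m - Kc * s, method = "adaptive", Kc = Kc,
                mean = m, sd = s, std_kind = std_kind, n = length(x),
                algorithm = index_algorithm(index))
}

new_threshold <- function(T, method, ...) {
  if (!is.finite(T)) stop("resolved threshold is not finite", call. = FALSE)
  structure(list(T = T, method = method, ...), class = "fs_threshold")
}

#' Fixed (calibrated) threshold
#'
#' Wraps an externally chosen threshold value, e.g. one calibrated from
#' labeled samples, in the same object used by [classify_flood()].
#'
#' @param T Threshold value.
#' @param algorithm Optional index name the threshold belongs to.
#' @export
fixed_threshold <- function(T, algorithm = NA_character_) {
  new_threshold(T = T, method = "fixed", algorithm = algorithm)
}

#' @export
print.fs_threshold <- function(x, ...) {
  cat(sprintf("<fs_threshold> T = %.6g (%s%s)\n", x$T, x$method,
              if (!is.null(x$Kc)) sprintf(", Kc = %g", x$Kc) else ""))
  invisible(x)
}

#' Terrain eligibility filter
#'
#' Floods pond on flat ground; brightness changes on steep slopes are mostly
#' viewing-geometry artifacts. The filter computes slope by Horn's 3x3
#' finite-difference method on the DEM and keeps pixels whose slope does not
#' exceed the cutoff (inclusive, default 5 degrees).
#'
#' @param dem Elevation raster, meters, on a metric grid.
#' @param cutoff_deg Maximum eligible slope in degrees.
#' @return Binary eligibility raster (1 = eligible).
#' @export
terrain_filter <- function(dem, cutoff_deg = 5) {
  if (cutoff_deg < 0) stop("slope cutoff must be >= 0", call. = FALSE)
  sl <- slope_deg(dem)
  with_values(dem, ifelse(is.na(sl$values), NA_real_,
                          (sl$values <= cutoff_deg + 1e-9) + 0))
}

#' Slope in degrees by Horn's method
#'
#' 3x3 weighted finite differences on a square metric grid; border pixels use
#' edge replication.
#'
#' @param dem Elevation raster in meters.
#' @return `fs_raster` of slope in degrees.
#' @export
slope_deg <- function(dem) {
  stopifnot(is_raster(dem))
  if (dem$units != "m")
    stop("slope needs a metric DEM grid", call. = FALSE)
  z <- dem$values
  n <- nrow(z); p <- ncol(z); px <- dem$pixel_size
  Z <- rbind(z[1L, , drop = FALSE], z, z[n, , drop = FALSE])
  Z <- cbind(Z[, 1L, drop = FALSE], Z, Z[, p, drop = FALSE])
  nw <- Z[1:n, 1:p];         no <- Z[1:n, 2:(p + 1)];     ne <- Z[1:n, 3:(p + 2)]
  we <- Z[2:(n + 1), 1:p];                                ea <- Z[2:(n + 1), 3:(p + 2)]
  sw <- Z[3:(n + 2), 1:p];   so <- Z[3:(n + 2), 2:(p + 1)]; se <- Z[3:(n + 2), 3:(p + 2)]
  dzdx <- ((ne + 2 * ea + se) - (nw + 2 * we + sw)) / (8 * px)
  dzdy <- ((sw + 2 * so + se) - (nw + 2 * no + ne)) / (8 * px)
  with_values(dem, atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi)
}

#' Background (zero-difference) filter
#'
#' Pixels whose CDAT difference is zero did not change between the reference
#' and flood periods - dry land staying dry, permanent water staying wet -
#' and are excluded from the flood candidates.
#'
#' @param D CDAT difference raster (errors on an NDFI input: the rule is
#'   defined on the difference image only).
#' @param eps Differences with `|D| <= eps` (dB) count as zero.
#' @return Binary eligibility raster.
#' @export
background_filter <- function(D, eps = 1e-6) {
  alg <- index_algorithm(D)
  if (!is.na(alg) && alg != "CDAT")
    stop("the background filter is defined on the CDAT difference image, ",
         "not on ", alg, call. = FALSE)
  with_values(D, ifelse(is.na(D$values), NA_real_,
                        (abs(D$values) > eps) + 0))
}

#' Seasonal land-cover change filter
#'
#' Seasonal surface changes (e.g. harvested fields) also lower backscatter,
#' but rarely to open-water levels. Only pixels whose flood-period minimum
#' backscatter falls strictly below the land-water cutoff (default -19 dB)
#' remain flood candidates.
#'
#' @param min_flood Min-composite of the flood stack (dB).
#' @param cutoff_db Land-water boundary in dB.
#' @return Binary eligibility raster.
#' @export
seasonal_filter <- function(min_flood, cutoff_db = -19) {
  stopifnot(is_raster(min_flood))
  with_values(min_flood, ifelse(is.na(min_flood$values), NA_real_,
                                (min_flood$values < cutoff_db) + 0))
}

#' Restrict an index raster to eligible pixels
#'
#' Masks are intersected, so the order in which filters are applied does not
#' matter. Used both to classify and to restrict the adaptive-threshold
#' statistics to decision-tree-eligible pixels.
#'
#' @param index Index raster.
#' @param ... Binary eligibility rasters.
#' @return Index raster with ineligible pixels set to nodata.
#' @export
apply_mask <- function(index, ...) {
  masks <- list(...)
  v <- index$values
  for (m in masks) {
    assert_same_geometry(index, m)
    v[is.na(m$values) | m$values == 0] <- NA_real_
  }
  out <- with_values(index, v)
  attr(out, "algorithm") <- index_algorithm(index)
  out
}

#' Threshold an index raster into a binary flood map
#'
#' A pixel is flooded when its index value is strictly below the threshold
#' and every eligibility mask admits it. Pixels exactly at the threshold are
#' non-flooded.
#'
#' @param index Index raster.
#' @param threshold An `fs_threshold` (from [adaptive_threshold()],
#'   [calibrate_threshold()] or [fixed_threshold()]) or a bare number.
#' @param ... Binary eligibility rasters (e.g. from [terrain_filter()],
#'   [background_filter()], [seasonal_filter()]).
#' @return Binary (0/1) `fs_raster`; nodata where the index is nodata.
#' @export
classify_flood <- function(index, threshold, ...) {
  T <- if (inherits(threshold, "fs_threshold")) threshold$T else
    as.numeric(threshold)
  v <- (index$values < T) + 0
  out <- with_values(index, v)
  out <- apply_mask(out, ...)
  # masked-out pixels are known non-flooded, not unknown
  keep_na <- is.na(index$values)
  vv <- out$values
  vv[is.na(vv) & !keep_na] <- 0
  attr(out, "algorithm") <- NULL
  with_values(out, vv)
}

#' Synergy (consistency) flood map
#'
#' The per-pixel logical AND of the CDAT and NDFI flood maps: only areas
#' flagged by both change-detection algorithms are kept, which suppresses
#' speckle-driven false alarms in either single map.
#'
#' @param cdat_map,ndfi_map Binary flood maps.
#' @return Binary `fs_raster`; nodata where either input is nodata.
#' @export
synergy_map <- function(cdat_map, ndfi_map) {
  assert_same_geometry(cdat_map, ndfi_map)
  a <- cdat_map$values; b <- ndfi_map$values
  vals <- ifelse(is.na(a) | is.na(b), NA_real_, (a == 1 & b == 1) + 0)
  with_values(cdat_map, vals)
}
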