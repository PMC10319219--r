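#' Construct a georeferenced raster grid
#'
#' The package's core spatial container: a numeric matrix on a regular,
#' square-pixel, north-up grid in a local metric coordinate system. Row 1 is
#' the top (northernmost) row; missing data are `NA`. All layers that are
#' combined in one operation must share the same geometry (shape, origin,
#' pixel size, units).
#'
#' @param values Numeric matrix (row 1 = top of the scene). `NA` marks nodata.
#' @param xmin,ymin Coordinates of the lower-left corner of the grid (same
#'   units as `pixel_size`).
#' @param pixel_size Pixel edge length. Metric rasters use meters.
#' @param units `"m"` for projected/metric grids, `"deg"` for geographic ones.
#'   Area accounting requires `"m"`.
#' @return An object of class `fs_raster`.
#' @examples
#' r <- raster_grid(matrix(1.5, 3, 3), pixel_size = 10)
#' area_km2(raster_grid(matrix(1L, 10, 10), pixel_size = 10), 1)
#' @export
raster_grid <- function(values, xmin = 0, ymin = 0, pixel_size = 10,
                        units = c("m", "deg")) {
  units <- match.arg(units)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  structure(
    list(values = values, xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         pixel_size = as.numeric(pixel_size), units = units),
    class = "fs_raster"
  )
}

#' @export
print.fs_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<fs_raster> %d x %d pixels @ %g %s\n",
              nrow(v), ncol(v), x$pixel_size, x$units))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xmin, x$xmin + ncol(v) * x$pixel_size,
              x$ymin, x$ymin + nrow(v) * x$pixel_size))
  vv <- v[!is.na(v)]
  if (length(vv))
    cat(sprintf("  values: [%g, %g], %d valid / %d nodata\n",
                min(vv), max(vv), length(vv), sum(is.na(v))))
  else cat("  values: all nodata\n")
  invisible(x)
}

#' @export
dim.fs_raster <- function(x) dim(x$values)

is_raster <- function(x) inherits(x, "fs_raster")

#' Replace the value matrix of a raster, keeping its geometry
#' @noRd
with_values <- function(r, values) {
  if (!identical(dim(values), dim(r$values)))
    stop("replacement values do not match raster shape", call. = FALSE)
  r$values <- values
  r
}

#' Coordinates of pixel centers
#'
#' @param r An `fs_raster`.
#' @return A list with `x` (length ncol, west to east) and `y` (length nrow,
#'   top row first, i.e. north to south).
#' @keywords internal
pixel_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values); px <- r$pixel_size
  list(x = r$xmin + (seq_len(nc) - 0.5) * px,
       y = r$ymin + (nr - seq_len(nr) + 0.5) * px)
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$pixel_size - b$pixel_size) < tol && identical(a$units, b$units)
}

assert_same_geometry <- function(...) {
  rs <- list(...)
  ref <- rs[[1L]]
  for (r in rs[-1L]) {
    if (!is_raster(r) || !is_raster(ref))
      stop("all inputs must be fs_raster objects", call. = FALSE)
    if (!same_geometry(ref, r))
      stop("raster geometries differ (shape, origin, pixel size or units); ",
           "all rasters combined in one operation must be co-registered",
           call. = FALSE)
  }
  invisible(TRUE)
}

# ---- file I/O: ESRI ASCII grid + JSON sidecar -------------------------------

sidecar_path <- function(path) paste0(path, ".aux.json")

#' Read / write rasters as ESRI ASCII grids
#'
#' Rasters are stored in the plain-text ESRI ASCII grid format (`NCOLS`,
#' `NROWS`, `XLLCORNER`, `YLLCORNER`, `CELLSIZE`, `NODATA_value`, then rows of
#' values from the top row down). Because the `.asc` header carries no
#' coordinate-system information, `write_raster()` also writes a small JSON
#' sidecar (`<path>.aux.json`) recording the units; `read_raster()` consults
#' it, or the explicit `units` argument, and fails if neither is available.
#' Round-trips preserve values to full double precision.
#'
#' @param path File path of the `.asc` grid.
#' @param units Grid units (`"m"` or `"deg"`) to assume when no sidecar is
#'   present.
#' @param r An `fs_raster` to write.
#' @param nodata Sentinel written for `NA` cells. Defaults to `-9999`; use
#'   `255` for categorical (small non-negative integer) maps.
#' @return `read_raster()` returns an `fs_raster`; `write_raster()` returns
#'   `path` invisibly.
#' @export
read_raster <- function(path, units = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid (incomplete header): ", path, call. = FALSE)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    aux <- jsonlite::read_json(sc, simplifyVector = TRUE)
    units <- aux$units
  } else if (is.null(units)) {
    stop("coordinate units unknown for ", path,
         ": no sidecar found and `units` not supplied", call. = FALSE)
  }
  vals <- scan(path, skip = 6L, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("grid body has ", length(vals), " values, expected ", nr * nc,
         call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  raster_grid(m, xmin = hdr$xllcorner, ymin = hdr$yllcorner,
              pixel_size = hdr$cellsize, units = units)
}

#' @rdname read_raster
#' @export
write_raster <- function(r, path, nodata = -9999) {
  stopifnot(is_raster(r))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  v <- r$values
  if (any(v[!is.na(v)] == nodata))
    stop("raster contains the nodata sentinel ", nodata,
         " as a valid value; choose another sentinel", call. = FALSE)
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("NCOLS %d", ncol(v)),
           sprintf("NROWS %d", nrow(v)),
           sprintf("XLLCORNER %.10g", r$xmin),
           sprintf("YLLCORNER %.10g", r$ymin),
           sprintf("CELLSIZE %.10g", r$pixel_size),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(v, 1L, function(row) paste(sprintf("%.17g", row),
                                           collapse = " "))
  writeLines(c(hdr, body), path)
  jsonlite::write_json(list(units = r$units, nodata = nodata),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

# ---- stacks -----------------------------------------------------------------

#' Construct a time-ordered raster stack
#'
#' @param rasters List of co-registered `fs_raster` layers.
#' @param dates `Date` vector, one per layer, strictly increasing.
#' @return An object of class `fs_stack`.
#' @export
raster_stack <- function(rasters, dates) {
  if (!length(rasters)) stop("a stack needs at least one raster", call. = FALSE)
  dates <- as.Date(dates)
  if (length(dates) != length(rasters))
    stop("need one date per raster", call. = FALSE)
  if (is.unsorted(dates, strictly = TRUE))
    stop("stack dates must be strictly increasing", call. = FALSE)
  do.call(assert_same_geometry, rasters)
  structure(list(rasters = rasters, dates = dates), class = "fs_stack")
}

#' @export
print.fs_stack <- function(x, ...) {
  cat(sprintf("<fs_stack> %d layers, %s to %s\n", length(x$rasters),
              min(x$dates), max(x$dates)))
  print(x$rasters[[1L]])
  invisible(x)
}

#' @export
length.fs_stack <- function(x) length(x$rasters)

#' Read / write a stack as a directory of date-stamped ASCII grids
#'
#' Layers are stored as `<prefix>_<YYYY-MM-DD>.asc` files; reading sorts by
#' the date embedded in the filename, so band order always equals time order.
#'
#' @param s An `fs_stack`.
#' @param dir Directory holding (or to receive) the layer files.
#' @param prefix Filename prefix.
#' @return `read_stack()` returns an `fs_stack`; `write_stack()` the
#'   directory, invisibly.
#' @export
write_stack <- function(s, dir, prefix = "layer") {
  stopifnot(inherits(s, "fs_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(s$rasters))
    write_raster(s$rasters[[i]],
                 file.path(dir, sprintf("%s_%s.asc", prefix, s$dates[i])))
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  files <- list.files(dir, pattern = "\\d{4}-\\d{2}-\\d{2}\\.asc$",
                      full.names = TRUE)
  if (!length(files)) stop("no dated .asc layers in ", dir, call. = FALSE)
  dates <- as.Date(sub("^.*_(\\d{4}-\\d{2}-\\d{2})\\.asc$", "\\1",
                       basename(files)))
  ord <- order(dates)
  raster_stack(lapply(files[ord], read_raster), dates[ord])
}

# ---- zones ------------------------------------------------------------------

#' Zone sets (county / grid polygons)
#'
#' A zone set is a tibble with one row per polygon: `zone_id`, `name`, and a
#' list-column `ring` of closed 2-column (x, y) coordinate matrices in the
#' raster coordinate system. `grid_zones()` builds a regular rectangular
#' tessellation of a raster's extent, the synthetic stand-in for county
#' boundaries. Zone sets round-trip through GeoJSON FeatureCollections
#' (`Polygon` features with `zone_id` and `name` properties).
#'
#' @param r Template `fs_raster` whose extent is tiled.
#' @param nx,ny Number of zones along x and y.
#' @param prefix Zone id prefix.
#' @return A tibble of class `fs_zones`.
#' @export
grid_zones <- function(r, nx = 3, ny = 3, prefix = "Z") {
  stopifnot(is_raster(r))
  w <- ncol(r$values) * r$pixel_size / nx
  h <- nrow(r$values) * r$pixel_size / ny
  rows <- list(); k <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    k <- k + 1L
    x0 <- r$xmin + (i - 1) * w; y0 <- r$ymin + (j - 1) * h
    ring <- matrix(c(x0, y0, x0 + w, y0, x0 + w, y0 + h, x0, y0 + h, x0, y0),
                   ncol = 2L, byrow = TRUE)
    rows[[k]] <- tibble::tibble(zone_id = sprintf("%s%02d", prefix, k),
                                name = sprintf("Zone %02d", k),
                                ring = list(ring))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fs_zones", class(out))
  out
}

#' @rdname grid_zones
#' @param path GeoJSON file path.
#' @export
read_zones <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path,
                                 call. = FALSE)
  rows <- purrr::map(gj$features, function(f) {
    coords <- f$geometry$coordinates[[1L]]
    ring <- do.call(rbind, lapply(coords, function(p)
      c(as.numeric(p[[1L]]), as.numeric(p[[2L]]))))
    tibble::tibble(zone_id = as.character(f$properties$zone_id),
                   name = as.character(f$properties$name %||% f$properties$zone_id),
                   ring = list(ring))
  })
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$zone_id)) stop("duplicate zone_id in ", path,
                                       call. = FALSE)
  class(out) <- c("fs_zones", class(out))
  out
}

#' @rdname grid_zones
#' @param zones An `fs_zones` tibble.
#' @export
write_zones <- function(zones, path) {
  feats <- purrr::pmap(zones, function(zone_id, name, ring, ...) {
    list(type = "Feature",
         properties = list(zone_id = zone_id, name = name),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign every pixel to at most one zone by its center point
#'
#' First matching zone wins where polygons overlap, which keeps the
#' assignment deterministic and the zonal areas additive.
#'
#' @return Integer matrix of zone row indices (`NA` = outside all zones).
#' @noRd
zone_assignment <- function(r, zones) {
  ctr <- pixel_centers(r)
  pts <- cbind(rep(ctr$x, each = nrow(r$values)),
               rep(ctr$y, times = ncol(r$values)))
  assign <- rep(NA_integer_, nrow(pts))
  for (z in seq_len(nrow(zones))) {
    todo <- is.na(assign)
    if (!any(todo)) break
    inside <- mgcv::in.out(zones$ring[[z]], pts[todo, , drop = FALSE])
    assign[which(todo)[inside]] <- z
  }
  matrix(assign, nrow = nrow(r$values))
}

# ---- area accounting --------------------------------------------------------

#' Area of a map category in square kilometers
#'
#' Pixel-counting area: `count(category) * pixel_area / 1e6`. Nodata pixels
#' never contribute. Requires a metric grid; geographic (degree) grids must
#' be projected first.
#'
#' @param map A categorical `fs_raster`.
#' @param category Category value(s) to count.
#' @return Area in km².
#' @export
area_km2 <- function(map, category = 1) {
  stopifnot(is_raster(map))
  if (map$units != "m")
    stop("area_km2() needs a projected metric grid; ",
         "this raster is in degrees - project it to meters first",
         call. = FALSE)
  sum(map$values %in% category) * map$pixel_size^2 / 1e6
}

#' Zonal area accounting
#'
#' Sums the area of a map category within each zone, assigning every pixel to
#' exactly one zone by its center point, so zone totals add up exactly to the
#' whole-map area over the zoned footprint.
#'
#' @inheritParams area_km2
#' @param zones An `fs_zones` tibble.
#' @return A tibble with `zone_id`, `name`, `area_km2`.
#' @export
zonal_area <- function(map, zones, category = 1) {
  za <- zone_assignment(map, zones)
  if (all(is.na(za))) {
    warning("zones do not intersect the raster extent")
    return(tibble::tibble(zone_id = character(), name = character(),
                          area_km2 = numeric()))
  }
  hit <- map$values %in% category
  counts <- tapply(hit, factor(za, levels = seq_len(nrow(zones))), sum)
  counts[is.na(counts)] <- 0
  tibble::tibble(zone_id = zones$zone_id, name = zones$name,
                 area_km2 = as.numeric(counts) * map$pixel_size^2 / 1e6)
}

#' Per-zone, per-class area table
#'
#' @inheritParams zonal_area
#' @param classes Class values to tabulate; defaults to the sorted distinct
#'   valid values of the map.
#' @return A tibble with `zone_id`, `name`, `class`, `area_km2`.
#' @export
zonal_class_areas <- function(map, zones, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(map$values[!is.na(map$values)]))
  purrr::map_dfr(classes, function(cl) {
    dplyr::mutate(zonal_area(map, zones, category = cl),
                  class = cl, .before = "area_km2")
  }) |>
    dplyr::arrange(.data$zone_id, .data$class)
}

#' Aggregate a binary flood map to coarse-cell flooded percentages
#'
#' Rescales a fine binary map to a coarser grid (e.g. 10 m pixels to 10 km
#' cells), reporting for each coarse cell the percentage of its valid fine
#' pixels that are flooded. Cells with no valid pixel become nodata.
#'
#' @param map Binary (0/1) `fs_raster`.
#' @param cell_size_m Coarse cell edge length; must be an integer multiple of
#'   the pixel size, and the raster dimensions must be divisible by the
#'   resulting block factor.
#' @return An `fs_raster` of percentages in `[0, 100]`.
#' @export
grid_percentage <- function(map, cell_size_m) {
  stopifnot(is_raster(map))
  f <- cell_size_m / map$pixel_size
  if (abs(f - round(f)) > 1e-9)
    stop("cell size must be an integer multiple of the pixel size",
         call. = FALSE)
  f <- as.integer(round(f))
  v <- map$values
  if (nrow(v) %% f != 0L || ncol(v) %% f != 0L)
    stop("raster dimensions are not divisible by the aggregation factor ",
         f, call. = FALSE)
  flooded <- block_sum(ifelse(is.na(v), 0, v), f)
  valid <- block_sum((!is.na(v)) + 0, f)
  pct <- ifelse(valid > 0, 100 * flooded / valid, NA_real_)
  raster_grid(pct, xmin = map$xmin, ymin = map$ymin,
              pixel_size = cell_size_m, units = map$units)
}

block_sum <- function(m, f) {
  rg <- rep(seq_len(nrow(m) %/% f), each = f)
  cg <- rep(seq_len(ncol(m) %/% f), each = f)
  t(rowsum(t(rowsum(m, rg)), cg))
}
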