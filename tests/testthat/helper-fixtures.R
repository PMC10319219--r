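# Shared fixtures: tiny rasters, random scenes, and independent geometry
# oracles used to cross-check the package implementations.

rand_raster <- function(seed, nr = 16, nc = 16, px = 10, lo = -25, hi = -5,
                        na_frac = 0) {
  set.seed(seed)
  v <- matrix(stats::runif(nr * nc, lo, hi), nr, nc)
  if (na_frac > 0) v[sample.int(nr * nc, round(na_frac * nr * nc))] <- NA
  raster_grid(v, pixel_size = px)
}

rand_binary_map <- function(seed, nr = 16, nc = 16, px = 10, p = 0.4) {
  set.seed(seed)
  raster_grid(matrix((stats::runif(nr * nc) < p) + 0, nr, nc),
              pixel_size = px)
}

const_stack <- function(values_db, nr = 4, nc = 4, px = 10,
                        start = as.Date("2020-03-01")) {
  raster_stack(lapply(values_db, function(v)
    raster_grid(matrix(v, nr, nc), pixel_size = px)),
    start + seq_along(values_db) * 7)
}

# small, fast scene for pipeline-level tests (fewer samples to match the
# smaller eligible-pixel pool)
small_config <- function(seed = 1, ...) {
  scene_config(shape = c(60, 60), n_samples = 600, seed = seed, ...)
}

# memoized default-condition scene so several test files can share it
.scene_cache <- new.env(parent = emptyenv())
cached_scene <- function(seed = 42) {
  key <- as.character(seed)
  if (is.null(.scene_cache[[key]]))
    .scene_cache[[key]] <- generate_scene(scene_config(seed = seed))
  .scene_cache[[key]]
}

# independent even-odd-rule point-in-polygon (oracle for zonal accounting)
oracle_point_in_poly <- function(px, py, ring) {
  n <- nrow(ring) - 1L
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# brute-force per-pixel zone assignment (first matching zone wins)
oracle_zonal_counts <- function(map, zones, category) {
  nr <- nrow(map$values); nc <- ncol(map$values); pxs <- map$pixel_size
  counts <- stats::setNames(rep(0, nrow(zones)), zones$zone_id)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- map$values[i, j]
    if (is.na(v) || v != category) next
    cx <- map$xmin + (j - 0.5) * pxs
    cy <- map$ymin + (nr - i + 0.5) * pxs
    for (z in seq_len(nrow(zones))) {
      if (oracle_point_in_poly(cx, cy, zones$ring[[z]])) {
        counts[z] <- counts[z] + 1
        break
      }
    }
  }
  counts
}
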