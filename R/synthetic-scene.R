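#' Rectangle helper for scene layout
#'
#' Scene regions (permanent water, flood stages, hills, confounders,
#' cropland) are axis-aligned rectangles in scene coordinates (meters).
#'
#' @param xmin,xmax,ymin,ymax Rectangle bounds in meters.
#' @export
rect_region <- function(xmin, xmax, ymin, ymax) {
  if (!(xmin < xmax && ymin < ymax))
    stop("degenerate rectangle: need xmin < xmax and ymin < ymax",
         call. = FALSE)
  c(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax)
}

rects_overlap <- function(a, b) {
  a["xmin"] < b["xmax"] && b["xmin"] < a["xmax"] &&
    a["ymin"] < b["ymax"] && b["ymin"] < a["ymax"]
}

#' Synthetic scene configuration
#'
#' Describes a small inland floodplain: a permanent lake on the west edge,
#' three nested stage-flood extents spreading east from the lake (so pixels
#' near the lake flood in all three stages: intensity 3), five historical
#' annual flood extents, a hilly strip on the east edge, seasonal-change
#' confounder patches that darken only in the flood period, and cropland
#' (mostly rice) overlapping the flood zone. Class backscatter defaults
#' (land -8 dB, open water -20 dB, spread 1 dB, 10-look speckle) are chosen
#' so that the -19 dB land-water cutoff and Kc = 1.5 thresholds are
#' physically meaningful on the generated scenes.
#'
#' @param shape Grid shape `c(nrow, ncol)`.
#' @param pixel_size Pixel edge length in meters.
#' @param mu_land,mu_water Class mean backscatter in dB (water must be darker
#'   than land).
#' @param sigma_db Per-observation Gaussian spread in dB.
#' @param looks Equivalent number of looks for multiplicative Gamma speckle
#'   in linear power; `Inf` disables speckle.
#' @param water,hill,cropland Rectangles ([rect_region()]); `NULL` keeps the
#'   default layout, proportional to the extent.
#' @param stage_rects List of 3 flood rectangles (stage 1 outermost).
#' @param annual_rects Named list of flood rectangles for the 5 years before
#'   the flood year.
#' @param confounder_rects List of rectangles darkened only in the flood
#'   period (labeled non-flood in the truth).
#' @param confounder_db Backscatter the confounder patches take in the flood
#'   stacks; the default -21 dB is below the seasonal cutoff on purpose, to
#'   exercise the filter cascade's known failure mode.
#' @param hill_gradient DEM gradient inside the hill strip (m per m;
#'   0.2 = about 11 degrees, well above the 5-degree cutoff).
#' @param rice_fraction Share of cropland pixels that are rice.
#' @param vi Vegetation-index trajectory parameters: `baseline_ndvi`,
#'   `baseline_evi`, per-intensity depressions `delta` (increasing),
#'   observation noise `vi_sd`, historical years `hist_years`, deterministic
#'   year-effect amplitude `hist_amp`, historical noise `hist_sd`, and
#'   `baseline_years` (how many prior years define the pre-flood mean).
#' @param optical Post-flood reflectance (0-10000 scale) per class and noise
#'   sd, used for the optical cross-map.
#' @param n_ref Number of reference-period acquisitions.
#' @param n_per_stage Acquisitions per flood stage.
#' @param flood_year Flood year.
#' @param n_zones `c(nx, ny)` zone grid emulating county boundaries.
#' @param n_samples,flooded_fraction,train_fraction Labeled-sample design:
#'   3000 points, 43% flooded (1290/1710), a third of them training.
#' @param seed Integer seed; every random draw in the generator flows from
#'   it.
#' @return A validated `fs_scene_config` list.
#' @export
scene_config <- function(shape = c(120, 120), pixel_size = 10,
                         mu_land = -8, mu_water = -20, sigma_db = 1,
                         looks = 10,
                         water = NULL, stage_rects = NULL,
                         annual_rects = NULL, hill = NULL,
                         hill_gradient = 0.2,
                         confounder_rects = NULL, confounder_db = -21,
                         cropland = NULL, rice_fraction = 0.91,
                         vi = list(), optical = list(),
                         n_ref = 5, n_per_stage = 3, flood_year = 2020,
                         n_zones = c(3, 3),
                         n_samples = 3000, flooded_fraction = 0.43,
                         train_fraction = 1 / 3,
                         seed = 42) {
  W <- shape[2] * pixel_size; H <- shape[1] * pixel_size
  water <- water %||% rect_region(0, 0.15 * W, 0, H)
  stage_rects <- stage_rects %||% list(
    rect_region(0.15 * W, 0.55 * W, 0, H),
    rect_region(0.15 * W, 0.42 * W, 0, H),
    rect_region(0.15 * W, 0.29 * W, 0, H))
  annual_rects <- annual_rects %||% stats::setNames(
    lapply(1:5, function(k) rect_region(0.15 * W, (0.33 + 0.03 * k) * W, 0, H)),
    as.character(seq(flood_year - 5, flood_year - 1)))
  hill <- hill %||% rect_region(0.85 * W, W, 0, H)
  confounder_rects <- confounder_rects %||%
    list(rect_region(0.62 * W, 0.70 * W, 0.2 * H, 0.5 * H))
  cropland <- cropland %||% rect_region(0.15 * W, 0.80 * W, 0, H)
  vi <- utils::modifyList(list(baseline_ndvi = 0.70, baseline_evi = 0.50,
                               delta = c(0.15, 0.30, 0.45), vi_sd = 0.02,
                               hist_years = 2000:(flood_year - 1),
                               hist_amp = 0.10, hist_sd = 0.02,
                               baseline_years = 5), vi)
  optical <- utils::modifyList(list(
    land = c(red = 1000, blue = 500, nir = 4000, swir1 = 2000),
    water = c(red = 600, blue = 700, nir = 500, swir1 = 300),
    flood = c(red = 1000, blue = 800, nir = 1500, swir1 = 500),
    sd = 50), optical)

  if (!(mu_water < mu_land))
    stop("open water must be darker than land (mu_water < mu_land)",
         call. = FALSE)
  if (is.unsorted(vi$delta, strictly = TRUE))
    stop("vi$delta depressions must be strictly increasing with intensity",
         call. = FALSE)
  if (!(rice_fraction > 0 && rice_fraction <= 1))
    stop("rice_fraction must be in (0, 1]", call. = FALSE)
  if (!(flooded_fraction > 0 && flooded_fraction <= 1))
    stop("flooded_fraction must be in (0, 1]", call. = FALSE)
  for (rc in c(stage_rects, annual_rects))
    if (rects_overlap(rc, water))
      stop("flood rectangles must be disjoint from permanent water",
           call. = FALSE)

  structure(list(shape = shape, pixel_size = pixel_size, mu_land = mu_land,
                 mu_water = mu_water, sigma_db = sigma_db, looks = looks,
                 water = water, stage_rects = stage_rects,
                 annual_rects = annual_rects, hill = hill,
                 hill_gradient = hill_gradient,
                 confounder_rects = confounder_rects,
                 confounder_db = confounder_db, cropland = cropland,
                 rice_fraction = rice_fraction, vi = vi, optical = optical,
                 n_ref = n_ref, n_per_stage = n_per_stage,
                 flood_year = flood_year, n_zones = n_zones,
                 n_samples = n_samples, flooded_fraction = flooded_fraction,
                 train_fraction = train_fraction, seed = seed),
            class = "fs_scene_config")
}

#' Load a scene configuration from a YAML file
#'
#' Keys mirror the [scene_config()] arguments; rectangles are 4-element
#' `[xmin, xmax, ymin, ymax]` sequences.
#'
#' @param path YAML file.
#' @export
read_scene_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_rect <- function(v) rect_region(v[1], v[2], v[3], v[4])
  for (f in c("water", "hill", "cropland"))
    if (!is.null(raw[[f]])) raw[[f]] <- as_rect(raw[[f]])
  for (f in c("stage_rects", "annual_rects", "confounder_rects"))
    if (!is.null(raw[[f]])) raw[[f]] <- lapply(raw[[f]], as_rect)
  do.call(scene_config, raw)
}

rasterize_rect <- function(template, rc) {
  ctr <- pixel_centers(template)
  inx <- ctr$x > rc["xmin"] & ctr$x < rc["xmax"]
  iny <- ctr$y > rc["ymin"] & ctr$y < rc["ymax"]
  outer(iny, inx, `&`)
}

mask_raster <- function(template, m) with_values(template, m + 0)

#' Binary erosion by one pixel (3x3 structuring element)
#' @noRd
erode_mask <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    s <- shift_matrix(m + 0, dr, dc)
    s[is.na(s)] <- 0
    out <- out & (s == 1)
  }
  out
}

#' Apply class spread and speckle to a noise-free dB scene
#'
#' Gaussian class spread is added in dB; speckle is multiplicative
#' Gamma(looks, scale 1/looks) noise applied in the linear power domain, the
#' physically standard model for L-look SAR intensity, then converted back
#' to dB.
#'
#' @noRd
simulate_backscatter <- function(base_db, sigma_db, looks) {
  n <- length(base_db)
  db <- base_db
  if (sigma_db > 0) db <- db + stats::rnorm(n, 0, sigma_db)
  if (is.finite(looks)) {
    lin <- 10^(db / 10) * stats::rgamma(n, shape = looks, rate = looks)
    db <- 10 * log10(lin)
  }
  matrix(db, nrow = nrow(base_db))
}

#' Generate a synthetic SAR flood scene with known truth
#'
#' Produces everything the mapping, validation and damage stages consume:
#' a reference backscatter stack, one flood stack per stage, a DEM, post-
#' flood optical bands, vegetation-index series, a zone grid, and an
#' `fs_scene_truth` object holding the ground-truth masks. Deterministic
#' given `config$seed`.
#'
#' @param config An [scene_config()].
#' @return An `fs_scene` list: `ref_stack`, `flood_stacks` (list of 3),
#'   `dem`, `optical` (red/blue/nir/swir1 rasters), `vi` (see
#'   [generate_vi_series()]), `zones`, `truth`, `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "fs_scene_config"))
  set.seed(config$seed)
  template <- raster_grid(matrix(0, config$shape[1], config$shape[2]),
                          pixel_size = config$pixel_size)

  water <- rasterize_rect(template, config$water)
  stages <- lapply(config$stage_rects,
                   function(rc) rasterize_rect(template, rc) & !water)
  flood_union <- Reduce(`|`, stages)
  annual <- lapply(config$annual_rects,
                   function(rc) rasterize_rect(template, rc) & !water)
  annual[[as.character(config$flood_year)]] <- flood_union
  hill <- rasterize_rect(template, config$hill)
  conf <- Reduce(`|`, lapply(config$confounder_rects,
                             function(rc) rasterize_rect(template, rc)))
  conf <- conf & !water & !flood_union
  cropmask <- rasterize_rect(template, config$cropland) & !water
  crops <- matrix(0, nrow(water), ncol(water))
  rice <- matrix(stats::runif(length(water)) < config$rice_fraction,
                 nrow(water))
  crops[cropmask] <- ifelse(rice[cropmask], 1, 2)
  intensity <- Reduce(`+`, lapply(stages, `+`, 0))

  # DEM: flat plain, linear ramp inside the hill strip
  ctr <- pixel_centers(template)
  xmat <- matrix(ctr$x, nrow = nrow(water), ncol = ncol(water), byrow = TRUE)
  dem_v <- matrix(0, nrow(water), ncol(water))
  dem_v[hill] <- config$hill_gradient * (xmat[hill] - config$hill["xmin"])
  dem <- with_values(template, dem_v)

  truth <- structure(list(
    stage_masks = lapply(stages, mask_raster, template = template),
    annual_masks = lapply(annual, mask_raster, template = template),
    flood_union = mask_raster(template, flood_union),
    water_mask = mask_raster(template, water),
    confounder_mask = mask_raster(template, conf),
    hill_mask = mask_raster(template, hill),
    cropland = with_values(template, crops),
    intensity = with_values(template, intensity)), class = "fs_scene_truth")

  base_ref <- matrix(config$mu_land, nrow(water), ncol(water))
  base_ref[water] <- config$mu_water
  ref_dates <- as.Date(sprintf("%d-03-01", config$flood_year)) +
    seq(0, by = 14, length.out = config$n_ref)
  ref_stack <- raster_stack(lapply(seq_len(config$n_ref), function(i)
    with_values(template, simulate_backscatter(base_ref, config$sigma_db,
                                               config$looks))), ref_dates)

  windows <- stage_windows(config$flood_year)
  flood_stacks <- lapply(seq_along(stages), function(k) {
    base <- base_ref
    base[stages[[k]]] <- config$mu_water
    base[conf] <- config$confounder_db
    dts <- seq(windows$start[k], windows$end[k],
               length.out = config$n_per_stage)
    raster_stack(lapply(seq_len(config$n_per_stage), function(i)
      with_values(template, simulate_backscatter(base, config$sigma_db,
                                                 config$looks))),
      as.Date(round(as.numeric(dts)), origin = "1970-01-01"))
  })

  optical <- simulate_optical(template, flood_union, water, config)
  vi <- generate_vi_series(truth, config, seed = config$seed + 1L)
  zones <- grid_zones(template, config$n_zones[1], config$n_zones[2])

  structure(list(ref_stack = ref_stack, flood_stacks = flood_stacks,
                 dem = dem, optical = optical, vi = vi, zones = zones,
                 truth = truth, config = config), class = "fs_scene")
}

#' The three intra-season stage windows of the flood year
#'
#' Jul 1 - Jul 22, Jul 23 - Aug 13, Aug 14 - Aug 31.
#'
#' @param year Flood year.
#' @return Tibble with `stage`, `start`, `end` (non-overlapping, ordered).
#' @export
stage_windows <- function(year = 2020) {
  tibble::tibble(
    stage = 1:3,
    start = as.Date(sprintf(c("%d-07-01", "%d-07-23", "%d-08-14"), year)),
    end = as.Date(sprintf(c("%d-07-22", "%d-08-13", "%d-08-31"), year)))
}

simulate_optical <- function(template, flood_union, water, config) {
  op <- config$optical
  bands <- c("red", "blue", "nir", "swir1")
  out <- lapply(bands, function(b) {
    v <- matrix(op$land[[b]], nrow(water), ncol(water))
    v[water] <- op$water[[b]]
    v[flood_union] <- op$flood[[b]]
    if (op$sd > 0) v <- v + matrix(stats::rnorm(length(v), 0, op$sd),
                                   nrow(v))
    with_values(template, pmax(v, 0))
  })
  stats::setNames(out, bands)
}

#' Generate vegetation-index trajectories for the scene
#'
#' Post-flood (September-October) NDVI/EVI on flooded cropland are depressed
#' below baseline by `delta[intensity]`; unflooded vegetation stays at
#' baseline. The historical September-October NDVI series (2000 to the year
#' before the flood) is stationary around the baseline with a deterministic
#' year-effect pattern of amplitude `hist_amp`, so its per-pixel median sits
#' at the baseline and its maximum `hist_amp` above - keeping the modified
#' vegetation condition index well defined even in noise-free runs. Open
#' water carries no vegetation signal (nodata).
#'
#' @param truth An `fs_scene_truth`.
#' @param config The scene's [scene_config()].
#' @param seed Seed for the VI noise draws.
#' @return List with `ndvi_a`, `evi_a` (post-flood means), `ndvi_b`, `evi_b`
#'   (pre-flood baseline means over the prior `baseline_years`), `ndvi_pre`
#'   (June-July of the flood year) and `hist` (an `fs_stack` of historical
#'   NDVI layers).
#' @export
generate_vi_series <- function(truth, config, seed = config$seed + 1L) {
  set.seed(seed)
  p <- config$vi
  template <- truth$intensity
  n <- length(template$values)
  wet <- truth$water_mask$values == 1
  noise <- function(sd) if (sd > 0) stats::rnorm(n, 0, sd) else numeric(n)
  dep <- ifelse(truth$intensity$values >= 1,
                p$delta[pmax(truth$intensity$values, 1)], 0)

  vi_raster <- function(v) {
    v[wet] <- NA_real_
    with_values(template, matrix(v, nrow = nrow(template$values)))
  }

  yr_effect <- rep(c(-1, -0.5, 0, 0.5, 1), length.out = length(p$hist_years))
  hist_layers <- lapply(seq_along(p$hist_years), function(i)
    vi_raster(p$baseline_ndvi + p$hist_amp * yr_effect[i] +
                noise(p$hist_sd)))
  hist <- raster_stack(hist_layers,
                       as.Date(sprintf("%d-10-01", p$hist_years)))

  nb <- length(p$hist_years)
  base_idx <- seq(nb - p$baseline_years + 1L, nb)
  ndvi_b_vals <- Reduce(`+`, lapply(hist_layers[base_idx],
                                    function(r) r$values)) / p$baseline_years
  list(
    ndvi_a = vi_raster(p$baseline_ndvi - dep + noise(p$vi_sd)),
    evi_a = vi_raster(p$baseline_evi - dep + noise(p$vi_sd)),
    ndvi_b = with_values(template, ndvi_b_vals),
    evi_b = vi_raster(p$baseline_evi + noise(p$vi_sd)),
    ndvi_pre = vi_raster(p$baseline_ndvi + noise(p$vi_sd)),
    hist = hist)
}

#' Stratified labeled sample points from the scene truth
#'
#' Draws flooded / non-flooded point samples without replacement from the
#' truth masks, after eroding each class by one pixel so no sample sits on a
#' mixed land-water edge pixel, then assigns a train / validation split.
#' Defaults mirror a 3000-point design with 1290 flooded and 1710
#' non-flooded points, a third of them training.
#'
#' @param truth An `fs_scene_truth`.
#' @param n_total Total number of points.
#' @param flooded_fraction Share of flooded points (0.43 gives 1290/3000).
#' @param seed Seed for sampling.
#' @param train_fraction Share assigned to the training split.
#' @return Tibble with `x`, `y`, `label` (`flooded` / `non_flooded`) and
#'   `split` (`train` / `val`).
#' @export
sample_points <- function(truth, n_total = 3000, flooded_fraction = 0.43,
                          seed = 1, train_fraction = 1 / 3) {
  set.seed(seed)
  fl <- truth$flood_union$values == 1
  nf <- !fl & truth$water_mask$values != 1
  fl_core <- erode_mask(fl)
  nf_core <- erode_mask(nf)
  n_fl <- round(n_total * flooded_fraction)
  n_nf <- n_total - n_fl
  if (sum(fl_core) < n_fl || sum(nf_core) < n_nf)
    stop("not enough eligible pixels to draw ", n_fl, " flooded / ",
         n_nf, " non-flooded samples", call. = FALSE)
  pick <- function(core, n) sample(which(core), n)
  idx <- c(pick(fl_core, n_fl), pick(nf_core, n_nf))
  ctr <- pixel_centers(truth$flood_union)
  nr <- nrow(truth$flood_union$values)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  out <- tibble::tibble(
    x = ctr$x[cols], y = ctr$y[rows],
    label = rep(c("flooded", "non_flooded"), c(n_fl, n_nf)),
    split = "val")
  out$split[sample.int(n_total, round(n_total * train_fraction))] <- "train"
  out
}

#' Read / write labeled samples as CSV
#'
#' Columns `x`, `y`, `label` (`flooded`/`non_flooded`), `split`
#' (`train`/`val`).
#'
#' @param samples Sample tibble.
#' @param path CSV path.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("x", "y", "label", "split") %in% names(df)))
  tibble::as_tibble(df)
}
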