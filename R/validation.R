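#' Calibrate a classification threshold from labeled samples
#'
#' Sample-based alternative to the purely statistical adaptive threshold:
#' repeatedly re-partition the labeled points into training and validation
#' splits (1/3 - 2/3 by default, the 1000/2000 design), exhaustively search
#' candidate thresholds derived from the training-sample index values
#' (midpoints between consecutive sorted unique values, plus flanking
#' candidates), score each by validation overall accuracy under the
#' "flooded if index < T" rule, and keep the best threshold of the best
#' repeat. Deterministic given `seed`.
#'
#' @param index Index raster (CDAT difference or NDFI).
#' @param samples Labeled sample tibble (`x`, `y`, `label`).
#' @param n_repeats Number of re-partition repeats.
#' @param seed Seed for the re-partitions.
#' @param train_fraction Share of points used as training in each repeat.
#' @return An `fs_threshold` with the winning `T`, its validation overall
#'   accuracy `oa`, and per-repeat results in `$repeats`.
#' @export
calibrate_threshold <- function(index, samples, n_repeats = 5, seed = 1,
                                train_fraction = 1 / 3) {
  vals <- extract_values(index, samples)
  ok <- !is.na(vals)
  if (any(!ok)) warning(sum(!ok), " sample(s) on nodata pixels dropped")
  vals <- vals[ok]
  lab <- samples$label[ok] == "flooded"
  if (length(unique(lab)) < 2L)
    stop("both flooded and non-flooded samples are required", call. = FALSE)
  if (length(unique(vals)) == 1L) {
    warning("all samples share one index value; threshold is degenerate")
    return(new_threshold(T = vals[1L], method = "calibrated", oa = NA_real_,
                         algorithm = index_algorithm(index)))
  }
  set.seed(seed)
  n <- length(vals)
  n_train <- max(1L, round(n * train_fraction))
  reps <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    tr <- sort(sample.int(n, n_train))
    va <- setdiff(seq_len(n), tr)
    cand <- threshold_candidates(vals[tr])
    oa <- vapply(cand, function(T)
      mean((vals[va] < T) == lab[va]) * 100, numeric(1))
    best <- which.max(oa)
    tibble::tibble(repeat_id = r, T = cand[best], oa = oa[best])
  })
  winner <- reps[which.max(reps$oa), ]
  new_threshold(T = winner$T, method = "calibrated", oa = winner$oa,
                n_repeats = n_repeats, repeats = reps,
                algorithm = index_algorithm(index))
}

threshold_candidates <- function(x) {
  u <- sort(unique(x))
  if (length(u) == 1L) return(u)
  mids <- (u[-1L] + u[-length(u)]) / 2
  c(u[1L] - 1, mids, u[length(u)] + 1)
}

#' Look up raster values at sample points
#'
#' @param r An `fs_raster`.
#' @param samples Tibble with `x`, `y` point coordinates.
#' @return Numeric vector (`NA` outside the grid or on nodata).
#' @export
extract_values <- function(r, samples) {
  nr <- nrow(r$values); nc <- ncol(r$values); px <- r$pixel_size
  col <- floor((samples$x - r$xmin) / px) + 1L
  row <- nr - floor((samples$y - r$ymin) / px)
  inside <- col >= 1L & col <= nc & row >= 1L & row <= nr
  out <- rep(NA_real_, nrow(samples))
  out[inside] <- r$values[cbind(row[inside], col[inside])]
  out
}

#' Confusion matrix of a flood map against labeled samples
#'
#' Compares the predicted class at each sample point with its label, with
#' flooded as the positive class. Samples falling on nodata pixels are
#' excluded and counted.
#'
#' @param pred Binary flood map.
#' @param samples Labeled sample tibble (`x`, `y`, `label`, optionally
#'   `split`).
#' @param split Use only this split (`"train"`, `"val"`) or `"all"`.
#' @return An `fs_confusion` object with counts `tp`, `fp`, `fn`, `tn` and
#'   `n_excluded`.
#' @export
confusion <- function(pred, samples, split = c("all", "train", "val")) {
  split <- match.arg(split)
  if (split != "all") {
    if (is.null(samples$split)) stop("samples carry no split column",
                                     call. = FALSE)
    samples <- samples[samples$split == split, ]
  }
  v <- extract_values(pred, samples)
  drop <- is.na(v)
  if (any(drop)) warning(sum(drop), " sample(s) on nodata pixels excluded")
  v <- v[!drop]
  truth <- samples$label[!drop] == "flooded"
  predicted <- v == 1
  confusion_counts(tp = sum(predicted & truth),
                   fp = sum(predicted & !truth),
                   fn = sum(!predicted & truth),
                   tn = sum(!predicted & !truth),
                   n_excluded = sum(drop))
}

#' Build a confusion matrix from counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts, flooded = positive class.
#' @param n_excluded Samples dropped for falling on nodata.
#' @export
confusion_counts <- function(tp, fp, fn, tn, n_excluded = 0L) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 total = tp + fp + fn + tn, n_excluded = n_excluded),
            class = "fs_confusion")
}

#' @export
print.fs_confusion <- function(x, ...) {
  cat("<fs_confusion> (flooded = positive)\n")
  cat(sprintf("  tp %d  fp %d\n  fn %d  tn %d  (n = %d)\n",
              x$tp, x$fp, x$fn, x$tn, x$total))
  invisible(x)
}

#' Thematic accuracy metrics from a confusion matrix
#'
#' Overall accuracy, user's accuracy (precision) and producer's accuracy
#' (recall) per class - all in percent - and the flooded-class F1 score
#' (harmonic mean of precision and recall, on the 0-1 scale). Metrics whose
#' denominator is zero are returned as `NA` and flagged.
#'
#' @param cm An `fs_confusion`.
#' @return One-row tibble: `oa`, `ua_flooded`, `pa_flooded`,
#'   `ua_nonflooded`, `pa_nonflooded` (percent), `f1`.
#' @export
accuracy_metrics <- function(cm) {
  stopifnot(inherits(cm, "fs_confusion"))
  if (cm$total == 0) stop("empty confusion matrix", call. = FALSE)
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  ua_fl <- pct(cm$tp, cm$tp + cm$fp)
  pa_fl <- pct(cm$tp, cm$tp + cm$fn)
  p <- ua_fl / 100; r <- pa_fl / 100
  f1 <- if (is.na(p) || is.na(r) || p + r == 0) NA_real_ else
    2 * p * r / (p + r)
  out <- tibble::tibble(
    oa = pct(cm$tp + cm$tn, cm$total),
    ua_flooded = ua_fl, pa_flooded = pa_fl,
    ua_nonflooded = pct(cm$tn, cm$tn + cm$fn),
    pa_nonflooded = pct(cm$tn, cm$tn + cm$fp),
    f1 = f1)
  if (anyNA(out)) attr(out, "undefined") <- names(out)[is.na(out[1L, ])]
  out
}

#' Optical spectral indices (NDVI, EVI, LSWI)
#'
#' Standard band-ratio indices on 0-10000-scaled surface reflectance:
#' `NDVI = (NIR - RED) / (NIR + RED)`,
#' `EVI = 2.5 (NIR - RED) / (NIR + 6 RED - 7.5 BLUE + 10000)` (the constant
#' is the EVI soil/aerosol term L = 1 times the reflectance scale; set
#' `scale = 1` for 0-1 reflectance), and
#' `LSWI = (NIR - SWIR1) / (NIR + SWIR1)`. Zero denominators become nodata.
#'
#' @param red,blue,nir,swir1 Co-registered reflectance rasters.
#' @param scale Reflectance scale (10000 or 1).
#' @return List of rasters `ndvi`, `evi`, `lswi`.
#' @export
optical_indices <- function(red, blue, nir, swir1, scale = 10000) {
  assert_same_geometry(red, blue, nir, swir1)
  safe_ratio <- function(num, den)
    ifelse(abs(den) < 1e-12, NA_real_, num / den)
  R <- red$values; B <- blue$values; N <- nir$values; S <- swir1$values
  list(
    ndvi = with_values(red, safe_ratio(N - R, N + R)),
    evi = with_values(red, safe_ratio(2.5 * (N - R),
                                      N + 6 * R - 7.5 * B + scale)),
    lswi = with_values(red, safe_ratio(N - S, N + S)))
}

#' Optical surface-water rule
#'
#' A pixel is flagged flooded when `LSWI > EVI` and `NDVI > 0.1`, both
#' strictly. The rule targets inundated vegetated surfaces in a rainy-season
#' optical composite.
#'
#' @param ndvi,evi,lswi Index rasters from [optical_indices()].
#' @return Binary flood map; nodata where any index is nodata.
#' @export
optical_flood <- function(ndvi, evi, lswi) {
  assert_same_geometry(ndvi, evi, lswi)
  vals <- (lswi$values > evi$values & ndvi$values > 0.1) + 0
  with_values(ndvi, vals)
}

#' County-level agreement between two flood maps
#'
#' Sums the flooded area of both maps within each zone and measures their
#' agreement with the coefficient of determination of an ordinary
#' least-squares fit of map B's areas on map A's.
#'
#' @param map_a,map_b Binary flood maps.
#' @param zones `fs_zones` with at least 2 zones.
#' @return List with `table` (tibble `zone_id`, `name`, `area_a_km2`,
#'   `area_b_km2`) and `r_squared` (`NA` with a flag when the predictor has
#'   zero variance).
#' @export
crossmap_agreement <- function(map_a, map_b, zones) {
  assert_same_geometry(map_a, map_b)
  if (nrow(zones) < 2L) stop("need at least two zones", call. = FALSE)
  ta <- zonal_area(map_a, zones, 1)
  tb <- zonal_area(map_b, zones, 1)
  tab <- dplyr::left_join(
    dplyr::rename(ta, area_a_km2 = "area_km2"),
    dplyr::select(dplyr::rename(tb, area_b_km2 = "area_km2"),
                  "zone_id", "area_b_km2"),
    by = "zone_id")
  degenerate <- stats::var(tab$area_a_km2) == 0 ||
    stats::var(tab$area_b_km2) == 0
  r2 <- if (degenerate) NA_real_ else
    suppressWarnings(  # summary.lm warns on a perfect 1:1 agreement
      summary(stats::lm(area_b_km2 ~ area_a_km2, data = tab))$r.squared)
  out <- list(table = tab, r_squared = r2)
  if (degenerate) out$flag <- "zero-variance zonal areas: R^2 undefined"
  out
}
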