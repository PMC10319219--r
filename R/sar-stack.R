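#' Convert linear backscatter power to decibels
#'
#' Applies the standard log scaling `10 * log10(x)`. Non-positive values have
#' no decibel representation and become nodata; their count is reported.
#'
#' @param linear `fs_raster` of linear power values.
#' @param quiet Suppress the message about non-positive pixels.
#' @return `fs_raster` in dB.
#' @export
to_decibel <- function(linear, quiet = FALSE) {
  stopifnot(is_raster(linear))
  v <- linear$values
  bad <- !is.na(v) & v <= 0
  if (any(bad) && !quiet)
    message(sum(bad), " non-positive pixel(s) set to nodata in dB conversion")
  v[bad] <- NA_real_
  with_values(linear, 10 * log10(v))
}

from_decibel <- function(db) with_values(db, 10^(db$values / 10))

#' Focal median speckle filter
#'
#' SAR speckle is multiplicative noise that flips individual pixels to
#' extreme values; a focal median suppresses it while preserving edges better
#' than a boxcar mean. Nodata neighbors are simply excluded from the
#' neighborhood; a pixel whose whole neighborhood is nodata stays nodata.
#'
#' @param r `fs_raster` to filter.
#' @param window Odd window edge length, at least 3.
#' @return Filtered `fs_raster`.
#' @export
speckle_filter <- function(r, window = 3) {
  stopifnot(is_raster(r))
  if (window < 3 || window %% 2 == 0)
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  k <- (window - 1L) / 2L
  v <- r$values
  neigh <- neighborhood_matrix(v, k)
  med <- apply(neigh, 1L, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else stats::median(x)
  })
  with_values(r, matrix(med, nrow = nrow(v)))
}

#' Stack the (2k+1)^2 shifted copies of a matrix as columns
#' (out-of-grid positions are NA), one row per pixel in column-major order.
#' @noRd
neighborhood_matrix <- function(v, k) {
  offs <- expand.grid(dr = -k:k, dc = -k:k)
  vapply(seq_len(nrow(offs)),
         function(i) as.vector(shift_matrix(v, offs$dr[i], offs$dc[i])),
         numeric(length(v)))
}

shift_matrix <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(NA_real_, n, p)
  rs <- seq_len(n) + dr; cs <- seq_len(p) + dc
  rok <- rs >= 1 & rs <= n; cok <- cs >= 1 & cs <= p
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

#' Temporal composites of a backscatter stack
#'
#' Per-pixel minimum / mean over the valid observations of a stack, computed
#' in the dB domain. Pixels with no valid observation in any layer become
#' nodata; pixels missing in only some layers use the layers they have, so
#' sparse coverage does not punch holes in the composite.
#'
#' @param s An `fs_stack`.
#' @return An `fs_raster` carrying attributes `statistic` (`"min"`, `"mean"`
#'   or `"median"`) for downstream contract checks.
#' @export
temporal_min <- function(s) temporal_composite(s, "min")

#' @rdname temporal_min
#' @export
temporal_mean <- function(s) temporal_composite(s, "mean")

#' @rdname temporal_min
#' @export
temporal_median <- function(s) temporal_composite(s, "median")

temporal_composite <- function(s, statistic) {
  if (!inherits(s, "fs_stack")) stop("`s` must be an fs_stack", call. = FALSE)
  arr <- vapply(s$rasters, function(r) as.vector(r$values),
                numeric(length(s$rasters[[1L]]$values)))
  arr <- matrix(arr, ncol = length(s$rasters))
  fun <- switch(statistic,
                min = function(x) if (all(is.na(x))) NA_real_ else
                  min(x, na.rm = TRUE),
                mean = function(x) if (all(is.na(x))) NA_real_ else
                  mean(x, na.rm = TRUE),
                median = function(x) if (all(is.na(x))) NA_real_ else
                  stats::median(x, na.rm = TRUE))
  vals <- apply(arr, 1L, fun)
  out <- with_values(s$rasters[[1L]], matrix(vals,
                                             nrow = nrow(s$rasters[[1L]]$values)))
  attr(out, "statistic") <- statistic
  out
}

composite_statistic <- function(r) attr(r, "statistic") %||% NA_character_

#' Per-pixel minimum over two stacks taken together
#'
#' The minimum over the concatenation of the reference and flood stacks,
#' which captures the lowest backscatter a pixel reached in either period.
#'
#' @param ref,flood `fs_stack` objects on the same grid.
#' @return Min-composite `fs_raster`.
#' @export
combined_min <- function(ref, flood) {
  assert_same_geometry(ref$rasters[[1L]], flood$rasters[[1L]])
  a <- temporal_min(ref)$values
  b <- temporal_min(flood)$values
  vals <- pmin(a, b, na.rm = TRUE)
  vals[is.na(a) & is.na(b)] <- NA_real_
  out <- with_values(ref$rasters[[1L]], vals)
  attr(out, "statistic") <- "min"
  out
}
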