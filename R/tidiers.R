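#' Tidy a threshold object
#'
#' One row per calibration repeat (for sample-calibrated thresholds) or a
#' single row (adaptive / fixed), with the resolved threshold and its
#' provenance.
#'
#' @param x An `fs_threshold`.
#' @param ... Unused.
#' @export
tidy.fs_threshold <- function(x, ...) {
  if (!is.null(x$repeats))
    return(dplyr::mutate(x$repeats, method = x$method,
                         algorithm = x$algorithm %||% NA_character_))
  tibble::tibble(T = x$T, method = x$method,
                 Kc = x$Kc %||% NA_real_,
                 mean = x$mean %||% NA_real_, sd = x$sd %||% NA_real_,
                 algorithm = x$algorithm %||% NA_character_)
}

#' @rdname tidy.fs_threshold
#' @export
glance.fs_threshold <- function(x, ...) {
  tibble::tibble(T = x$T, method = x$method,
                 oa = x$oa %||% NA_real_,
                 algorithm = x$algorithm %||% NA_character_)
}

#' Tidy a confusion matrix
#'
#' `tidy()` returns the four cells in long form; `glance()` returns the
#' accuracy metrics ([accuracy_metrics()]) in one row.
#'
#' @param x An `fs_confusion`.
#' @param ... Unused.
#' @export
tidy.fs_confusion <- function(x, ...) {
  tibble::tibble(
    prediction = c("flooded", "flooded", "non_flooded", "non_flooded"),
    truth = c("flooded", "non_flooded", "flooded", "non_flooded"),
    n = c(x$tp, x$fp, x$fn, x$tn))
}

#' @rdname tidy.fs_confusion
#' @export
glance.fs_confusion <- function(x, ...) accuracy_metrics(x)

#' Plot a raster with ggplot2
#'
#' Continuous rasters get a viridis fill; pass `discrete = TRUE` for
#' categorical maps (flood, intensity, damage classes).
#'
#' @param object An `fs_raster`.
#' @param discrete Treat values as classes.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fs_raster <- function(object, discrete = FALSE, ...) {
  ctr <- pixel_centers(object)
  df <- tidyr::expand_grid(y = ctr$y, x = ctr$x)
  df$value <- as.vector(t(object$values))
  if (discrete) df$value <- factor(df$value)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    (if (discrete) ggplot2::scale_fill_viridis_d(na.value = "grey90") else
      ggplot2::scale_fill_viridis_c(na.value = "grey90")) +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "value") +
    ggplot2::theme_minimal()
}

#' Bar chart of damage-class areas by crop type
#'
#' @param report Output of [damage_report()].
#' @return A ggplot.
#' @export
plot_damage_report <- function(report) {
  df <- dplyr::summarise(
    dplyr::group_by(report$by_zone, .data$class, .data$crop),
    area_km2 = sum(.data$area_km2), .groups = "drop")
  df$class <- factor(df$class, levels = c("slight", "moderate", "severe"))
  ggplot2::ggplot(df, ggplot2::aes(.data$class, .data$area_km2,
                                   fill = .data$crop)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "damage class", y = "area (km²)", fill = "crop") +
    ggplot2::theme_minimal()
}
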