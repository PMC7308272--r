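#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

bscan_to_df <- function(image) {
  px <- as_pixels(image)
  ls <- if (is_bscan(image)) image$lateral_scale else 0.0125
  as_ <- if (is_bscan(image)) image$axial_scale else 0.015625
  tibble::tibble(
    lateral_mm = rep((seq_len(ncol(px)) - 1) * ls, each = nrow(px)),
    axial_mm = rep((seq_len(nrow(px)) - 1) * as_, times = ncol(px)),
    intensity = as.vector(px)
  )
}

#' Plot a B-scan
#'
#' Greyscale raster of a [bscan()] in physical coordinates, anterior at
#' the top (the axial axis is reversed). Sentinel pixels render as blank.
#'
#' @param object A [bscan()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bscan
#' @export
autoplot.bscan <- function(object, ...) {
  df <- bscan_to_df(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lateral_mm, .data$axial_mm,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 na.value = "grey20") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "lateral (mm)", y = "axial depth (mm)",
                  fill = "intensity",
                  title = sprintf("B-scan %s (%s)", object$source_id,
                                  object$half)) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic scene with its ground-truth dots
#'
#' The phantom image overlaid with the true dot centroids, coloured by
#' central/peripheral status.
#'
#' @param object A `synthetic_scene`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot synthetic_scene
#' @export
autoplot.synthetic_scene <- function(object, ...) {
  p <- autoplot(object$image)
  if (nrow(object$dots) > 0) {
    dots <- dplyr::mutate(
      object$dots,
      lateral_mm = (.data$centroid_col - 1) * object$spec$lateral_scale,
      axial_mm = (.data$centroid_row - 1) * object$spec$axial_scale,
      location = ifelse(.data$central, "central", "peripheral")
    )
    p <- p +
      ggplot2::geom_point(
        data = dots,
        ggplot2::aes(.data$lateral_mm, .data$axial_mm,
                     colour = .data$location),
        inherit.aes = FALSE, shape = 1, size = 3
      ) +
      ggplot2::scale_colour_manual(values = c(central = "#00BFC4",
                                              peripheral = "#F8766D"))
  }
  p
}

#' Boxplot of a cohort variable by group
#'
#' @param records A cohort tibble (e.g. from [generate_cohort()]).
#' @param variable Column name to plot.
#' @param group_col Grouping column (default `"group"`).
#' @return A ggplot.
#' @export
plot_cohort_variable <- function(records, variable, group_col = "group") {
  records <- tibble::as_tibble(records)
  stopifnot(variable %in% names(records), group_col %in% names(records))
  ggplot2::ggplot(records, ggplot2::aes(.data[[group_col]],
                                        .data[[variable]],
                                        fill = .data[[group_col]])) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = 1) +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = variable) +
    ggplot2::theme_minimal()
}

#' Radial profile of dot opacities
#'
#' Histogram of per-dot lateral offsets from the lens axis, with the
#' central-window half-width marked; visualises the diffuse spread of the
#' punctate opacities.
#'
#' @param dots A per-dot tibble carrying `lateral_offset_mm` (from
#'   [label_dots()], [per_dot()] or a scene's `$dots`).
#' @param central_width_mm Central window width to mark (default 4.25).
#' @return A ggplot.
#' @export
plot_dot_profile <- function(dots, central_width_mm = 4.25) {
  dots <- tibble::as_tibble(dots)
  stopifnot("lateral_offset_mm" %in% names(dots))
  ggplot2::ggplot(dots, ggplot2::aes(.data$lateral_offset_mm)) +
    ggplot2::geom_histogram(binwidth = 0.25, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = central_width_mm / 2,
                        linetype = "dashed") +
    ggplot2::labs(x = "lateral offset from lens axis (mm)", y = "dots") +
    ggplot2::theme_minimal()
}
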