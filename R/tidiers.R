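#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-eye opacity metrics
#'
#' `tidy()` pivots a [quantify_eye()] result into a long
#' metric/value tibble; `glance()` returns the one-row wide record. The
#' per-dot profile attached to the metrics is available through
#' `per_dot()`.
#'
#' @param x An `opacity_metrics` object.
#' @param ... Unused.
#'
#' @return A tibble.
#' @method tidy opacity_metrics
#' @export
tidy.opacity_metrics <- function(x, ...) {
  wide <- tibble::as_tibble(unclass(x))
  tidyr::pivot_longer(wide, -dplyr::any_of("eye_id"),
                      names_to = "metric", values_to = "value",
                      values_transform = as.numeric)
}

#' @rdname tidy.opacity_metrics
#' @method glance opacity_metrics
#' @export
glance.opacity_metrics <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.opacity_metrics
#' @export
per_dot <- function(x) {
  attr(x, "per_dot")
}

#' Tidy a synthetic scene
#'
#' `tidy()` returns the scene's analytically expected metrics in long
#' form; `glance()` returns them as one wide row together with the seed
#' and raster shape.
#'
#' @param x A `synthetic_scene`.
#' @param ... Unused.
#'
#' @return A tibble.
#' @method tidy synthetic_scene
#' @export
tidy.synthetic_scene <- function(x, ...) {
  tidyr::pivot_longer(x$expected, dplyr::everything(),
                      names_to = "metric", values_to = "expected",
                      values_transform = as.numeric)
}

#' @rdname tidy.synthetic_scene
#' @method glance synthetic_scene
#' @export
glance.synthetic_scene <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(seed = x$spec$seed,
                   rows = x$spec$image_rows, cols = x$spec$image_cols,
                   speckle_cv = x$spec$speckle_cv),
    x$expected
  )
}
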