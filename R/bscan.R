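#' A single AS-OCT B-scan
#'
#' Container for one cross-sectional OCT intensity raster together with its
#' physical calibration and acquisition metadata. Rows are axial depth
#' (anterior at the top), columns are lateral position. Intensities are
#' detector amplitudes as exported; no log-compression or denoising is
#' applied by this package.
#'
#' Composed whole-lens images (see [compose_whole_lens()]) may contain `NA`
#' sentinel rows marking the unimaged gap between the anterior and posterior
#' acquisitions; all region statistics in this package exclude such pixels.
#' Apart from the sentinel, every intensity must be finite and non-negative.
#'
#' Indexing is 1-based as usual in R; the physical coordinate of column `c`
#' is `(c - 1) * lateral_scale` millimetres from the centre of the top-left
#' pixel (likewise for rows with `axial_scale`).
#'
#' @param pixels Numeric matrix of intensities (rows = depth, cols = lateral).
#' @param lateral_scale Millimetres per column. Default 0.0125 mm
#'   (a 16 mm scan width over 1280 display columns).
#' @param axial_scale Millimetres per row. Default 0.015625 mm
#'   (an 8 mm depth window over 512 rows).
#' @param half One of `"anterior"`, `"posterior"`, `"whole"`.
#' @param meridian_deg Acquisition meridian in degrees (scans are typically
#'   taken at 90 degrees, with 180 or other meridians added as needed).
#' @param source_id Free-text provenance tag (file name, eye id, ...).
#'
#' @return An object of class `bscan`.
#' @examples
#' img <- bscan(matrix(100, 64, 128))
#' dim(img)
#' @export
bscan <- function(pixels,
                  lateral_scale = 0.0125,
                  axial_scale = 0.015625,
                  half = c("anterior", "posterior", "whole"),
                  meridian_deg = 90,
                  source_id = "") {
  half <- match.arg(half)
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (length(pixels) == 0L) {
    stop("`pixels` must be a non-empty matrix", call. = FALSE)
  }
  v <- pixels[!is.na(pixels)]
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("all intensities must be finite and >= 0", call. = FALSE)
  }
  if (anyNA(pixels) && half != "whole") {
    stop("NA sentinel pixels are only allowed in composed `whole` images",
         call. = FALSE)
  }
  if (!is.numeric(lateral_scale) || length(lateral_scale) != 1L ||
      !is.finite(lateral_scale) || lateral_scale <= 0) {
    stop("`lateral_scale` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(axial_scale) || length(axial_scale) != 1L ||
      !is.finite(axial_scale) || axial_scale <= 0) {
    stop("`axial_scale` must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      pixels = pixels,
      lateral_scale = as.numeric(lateral_scale),
      axial_scale = as.numeric(axial_scale),
      half = half,
      meridian_deg = as.numeric(meridian_deg),
      source_id = as.character(source_id)
    ),
    class = "bscan"
  )
}

#' @export
dim.bscan <- function(x) dim(x$pixels)

#' @export
print.bscan <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<bscan> %d x %d (%s, %g deg)  pitch %.5g x %.5g mm  extent %.3g x %.3g mm\n",
    d[1], d[2], x$half, x$meridian_deg, x$axial_scale, x$lateral_scale,
    d[1] * x$axial_scale, d[2] * x$lateral_scale
  ))
  rng <- range(x$pixels, na.rm = TRUE)
  cat(sprintf("  intensity range [%g, %g]%s  source '%s'\n",
              rng[1], rng[2],
              if (anyNA(x$pixels)) sprintf(", %d sentinel px", sum(is.na(x$pixels))) else "",
              x$source_id))
  invisible(x)
}

is_bscan <- function(x) inherits(x, "bscan")

as_pixels <- function(image) {
  if (is_bscan(image)) image$pixels else as.matrix(image)
}

# mean intensity over a logical mask, NA-sentinel pixels excluded
mask_mean <- function(pixels, mask) {
  v <- pixels[mask]
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NA_real_)
  mean(v)
}
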