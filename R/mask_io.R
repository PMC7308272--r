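#' Read and write label-mask images
#'
#' Region masks travel as single-channel label images (TIFF or PNG, chosen
#' by file extension): 0 = background, 1 = aqueous, 2 = nucleus,
#' 3 = cortex, 4 = PSC zone, 5 = areal opacity; dot labels go in a second
#' image whose values are the dot identifiers. TIFF masks are written with
#' 16 bits per sample (labels up to 65535 round-trip exactly); PNG masks
#' are 8-bit, so PNG labels must stay below 256.
#'
#' @param labels Integer matrix of labels (>= 0).
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#'
#' @return `write_label_mask()`: `path` invisibly; `read_label_mask()`: an
#'   integer matrix.
#' @export
write_label_mask <- function(labels, path) {
  m <- as.matrix(labels)
  ext <- tolower(tools::file_ext(path))
  maxv <- if (ext == "png") 255 else 65535
  if (anyNA(m) || any(m < 0) || any(m > maxv) || any(m != round(m))) {
    stop(sprintf("labels must be integers in [0, %d] for %s output",
                 maxv, ext), call. = FALSE)
  }
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m / 65535, path, bits.per.sample = 16)
  } else if (ext == "png") {
    png::writePNG(m / 255, path)
  } else {
    stop("unsupported mask format: use .tif/.tiff or .png", call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("mask file not found: '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    stop("unsupported mask format: use .tif/.tiff or .png", call. = FALSE)
  }
  if (length(dim(m)) == 3L) m <- m[, , 1] # tolerate grey stored with channels
  out <- round(m * (if (ext == "png") 255 else 65535))
  storage.mode(out) <- "integer"
  out
}

# region label codes used on disk
REGION_LABELS <- c(background = 0L, aqueous = 1L, nucleus = 2L,
                   cortex = 3L, psc = 4L, opacity = 5L)

#' Convert a segmentation to/from disk label rasters
#'
#' `segmentation_to_labels()` flattens the boolean region masks into one
#' label raster using the on-disk codes (PSC zone and areal opacity, which
#' may overlap the cortex, take precedence in that order);
#' `segmentation_from_labels()` rebuilds a [lens_segmentation()] from the
#' region raster plus the dot-label raster. A segmentation whose PSC zone
#' overlaps the cortex survives the round trip with `psc` re-expanded into
#' the cortex via the `psc_in_cortex` flag.
#'
#' @param seg A [lens_segmentation()].
#' @param region_labels,dot_labels Integer matrices as written by
#'   [write_label_mask()].
#' @param lens_axis_col Axis column for the rebuilt segmentation.
#' @param psc_in_cortex Treat PSC-zone pixels as cortex pixels too
#'   (default `TRUE`, matching the generator's geometry).
#'
#' @return A label matrix, or a rebuilt [lens_segmentation()].
#' @export
segmentation_to_labels <- function(seg) {
  d <- dim(seg$aqueous_mask)
  lab <- matrix(REGION_LABELS[["background"]], d[1], d[2])
  lab[seg$aqueous_mask] <- REGION_LABELS[["aqueous"]]
  lab[seg$nucleus_mask] <- REGION_LABELS[["nucleus"]]
  lab[seg$cortex_mask] <- REGION_LABELS[["cortex"]]
  lab[seg$psc_mask] <- REGION_LABELS[["psc"]]
  lab[seg$opacity_mask] <- REGION_LABELS[["opacity"]]
  lab
}

#' @rdname segmentation_to_labels
#' @export
segmentation_from_labels <- function(region_labels, dot_labels = NULL,
                                     lens_axis_col = NULL,
                                     psc_in_cortex = TRUE) {
  rl <- as.matrix(region_labels)
  psc <- rl == REGION_LABELS[["psc"]]
  opacity <- rl == REGION_LABELS[["opacity"]]
  cortex <- rl == REGION_LABELS[["cortex"]]
  if (psc_in_cortex) cortex <- cortex | psc | opacity
  lens_segmentation(
    aqueous_mask = rl == REGION_LABELS[["aqueous"]],
    nucleus_mask = rl == REGION_LABELS[["nucleus"]],
    cortex_mask = cortex,
    psc_mask = psc,
    dot_labels = dot_labels,
    opacity_mask = opacity,
    lens_axis_col = lens_axis_col
  )
}
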