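#' Co-registered lens region segmentation
#'
#' Bundles the manually (or synthetically) delineated region masks for one
#' B-scan: aqueous humour (the background intensity reference), nucleus,
#' cortex, the posterior subcapsular (PSC) zone, a labelled raster of
#' punctate dot opacities, and an optional boolean mask of areal
#' cortical/PSC opacities. The PSC zone is the region in which PSC opacity
#' is graded and may lie inside the cortex band; aqueous, nucleus and cortex
#' must be mutually consistent (see [validate_segmentation()]).
#'
#' Dot opacities (the punctate cerulean class) and areal opacities are kept
#' as separate layers: dots are profiled individually by [dot_metrics()],
#' while `opacity_mask` feeds the cortical/PSC PIR and PAR of
#' [region_opacity_metrics()].
#'
#' @param aqueous_mask,nucleus_mask,cortex_mask,psc_mask Logical matrices,
#'   all the same shape as the image they annotate. `psc_mask` is the PSC
#'   *zone* (may be all-`FALSE` if the posterior capsule was not imaged).
#' @param dot_labels Integer matrix; 0 = background, `k > 0` = dot
#'   identifier. Defaults to no dots.
#' @param opacity_mask Logical matrix of areal (non-dot) cortical/PSC
#'   opacity pixels. Defaults to none.
#' @param lens_axis_col Column index (1-based) of the lens/visual axis;
#'   defaults to the centre column, matching corneal-reflex alignment.
#'
#' @return An object of class `lens_segmentation`.
#' @export
lens_segmentation <- function(aqueous_mask, nucleus_mask, cortex_mask,
                              psc_mask = NULL, dot_labels = NULL,
                              opacity_mask = NULL, lens_axis_col = NULL) {
  d <- dim(aqueous_mask)
  if (is.null(psc_mask)) psc_mask <- matrix(FALSE, d[1], d[2])
  if (is.null(dot_labels)) dot_labels <- matrix(0L, d[1], d[2])
  if (is.null(opacity_mask)) opacity_mask <- matrix(FALSE, d[1], d[2])
  if (is.null(lens_axis_col)) lens_axis_col <- ceiling(d[2] / 2)
  storage.mode(dot_labels) <- "integer"
  structure(
    list(
      aqueous_mask = as_logical_mask(aqueous_mask),
      nucleus_mask = as_logical_mask(nucleus_mask),
      cortex_mask = as_logical_mask(cortex_mask),
      psc_mask = as_logical_mask(psc_mask),
      dot_labels = dot_labels,
      opacity_mask = as_logical_mask(opacity_mask),
      lens_axis_col = as.integer(lens_axis_col)
    ),
    class = "lens_segmentation"
  )
}

as_logical_mask <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "logical"
  m[is.na(m)] <- FALSE
  m
}

#' @export
print.lens_segmentation <- function(x, ...) {
  d <- dim(x$aqueous_mask)
  cat(sprintf("<lens_segmentation> %d x %d, axis col %d\n", d[1], d[2],
              x$lens_axis_col))
  cat(sprintf(
    "  aqueous %d px, nucleus %d px, cortex %d px, PSC zone %d px, %d dot(s), opacity %d px\n",
    sum(x$aqueous_mask), sum(x$nucleus_mask), sum(x$cortex_mask),
    sum(x$psc_mask), length(setdiff(unique(as.vector(x$dot_labels)), 0L)),
    sum(x$opacity_mask)
  ))
  invisible(x)
}

#' Validate a segmentation against its image
#'
#' Checks the structural contract every downstream metric relies on:
#' all masks share the image shape; the aqueous mask is disjoint from
#' nucleus, cortex and PSC zone; nucleus and cortex are disjoint; every
#' dot-label pixel lies inside the lens (cortex or nucleus); areal opacity
#' pixels lie inside cortex or PSC zone; and the lens axis column is inside
#' the image. Violations are reported with the region names involved.
#'
#' @param seg A [lens_segmentation()].
#' @param image The [bscan()] (or matrix) the masks annotate.
#'
#' @return `seg`, invisibly, if all invariants hold; otherwise an error.
#' @export
validate_segmentation <- function(seg, image) {
  stopifnot(inherits(seg, "lens_segmentation"))
  d <- dim(as_pixels(image))
  masks <- list(aqueous = seg$aqueous_mask, nucleus = seg$nucleus_mask,
                cortex = seg$cortex_mask, psc = seg$psc_mask,
                opacity = seg$opacity_mask, dots = seg$dot_labels)
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]), d)) {
      stop(sprintf("mask '%s' has shape %dx%d but image is %dx%d",
                   nm, nrow(masks[[nm]]), ncol(masks[[nm]]), d[1], d[2]),
           call. = FALSE)
    }
  }
  disjoint <- list(
    c("aqueous", "nucleus"), c("aqueous", "cortex"), c("aqueous", "psc"),
    c("nucleus", "cortex")
  )
  for (pr in disjoint) {
    ov <- sum(masks[[pr[1]]] & masks[[pr[2]]])
    if (ov > 0) {
      stop(sprintf("regions '%s' and '%s' overlap on %d pixel(s)",
                   pr[1], pr[2], ov), call. = FALSE)
    }
  }
  lens <- seg$cortex_mask | seg$nucleus_mask
  outside <- sum(seg$dot_labels > 0L & !lens)
  if (outside > 0) {
    stop(sprintf("%d dot pixel(s) lie outside the lens (cortex or nucleus)",
                 outside), call. = FALSE)
  }
  op_outside <- sum(seg$opacity_mask & !(seg$cortex_mask | seg$psc_mask))
  if (op_outside > 0) {
    stop(sprintf("%d opacity pixel(s) lie outside cortex and PSC zone",
                 op_outside), call. = FALSE)
  }
  if (seg$lens_axis_col < 1L || seg$lens_axis_col > d[2]) {
    stop(sprintf("lens axis column %d is outside the image (1..%d)",
                 seg$lens_axis_col, d[2]), call. = FALSE)
  }
  invisible(seg)
}

# connected-component labelling on a logical mask (4- or 8-connectivity);
# labels are dense from 1 in order of first (column-major) occurrence
label_components <- function(mask, connectivity = 8) {
  mask <- as_logical_mask(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) return(out)
  if (!connectivity %in% c(4, 8)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  nr <- nrow(mask); nc <- ncol(mask)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- NULL
  for (o in offs) {
    rn <- r + o[1]; cn <- c + o[2]
    ok <- rn >= 1L & rn <= nr & cn >= 1L & cn <= nc
    nidx <- (cn[ok] - 1L) * nr + rn[ok]
    hit <- match(nidx, idx)
    keep <- !is.na(hit)
    if (any(keep)) {
      edges <- rbind(edges, cbind(which(ok)[keep], hit[keep]))
    }
  }
  if (is.null(edges) || nrow(edges) == 0L) {
    memb <- seq_along(idx)
  } else {
    g <- igraph::make_graph(as.vector(t(edges)), n = length(idx),
                            directed = FALSE)
    memb <- igraph::components(g)$membership
  }
  first_seen <- tapply(seq_along(idx), memb, min)
  relabel <- integer(length(first_seen))
  relabel[order(first_seen)] <- seq_along(first_seen)
  out[idx] <- relabel[memb]
  out
}

#' Identify dot opacities as connected components
#'
#' Labels the punctate dot opacities of a boolean mask as connected
#' components and profiles each one: pixel count, centroid in physical
#' coordinates, mean intensity (when the image is supplied) and unsigned
#' lateral offset of the centroid from the lens axis. Components smaller
#' than `min_pixels` are discarded (single-pixel speckle outliers should
#' not count as dots); surviving labels are dense from 1.
#'
#' @param dot_mask Logical matrix (or positive-valued matrix) of dot pixels.
#' @param image Optional [bscan()]; supplies intensities and pixel pitch.
#' @param connectivity 4 or 8 (default 8: diagonal neighbours touch).
#' @param min_pixels Minimum component size to count as a dot (default 2).
#' @param lens_axis_col Lens axis column; defaults to the centre column.
#' @param lateral_scale,axial_scale Pixel pitch in mm, used when `image` is
#'   not supplied.
#'
#' @return A tibble with one row per dot: `label`, `pixel_count`,
#'   `centroid_row`, `centroid_col`, `centroid_lateral_mm`,
#'   `centroid_axial_mm`, `mean_intensity`, `lateral_offset_mm`. The
#'   relabelled raster is attached as attribute `"labels"`.
#' @examples
#' m <- matrix(FALSE, 8, 8); m[2:3, 2:3] <- TRUE; m[6:7, 6:7] <- TRUE
#' label_dots(m)
#' @export
label_dots <- function(dot_mask, image = NULL, connectivity = 8,
                       min_pixels = 2, lens_axis_col = NULL,
                       lateral_scale = 0.0125, axial_scale = 0.015625) {
  if (!is.null(image) && is_bscan(image)) {
    lateral_scale <- image$lateral_scale
    axial_scale <- image$axial_scale
  }
  mask <- if (is.logical(dot_mask)) dot_mask else as.matrix(dot_mask) > 0
  if (is.null(lens_axis_col)) lens_axis_col <- ceiling(ncol(mask) / 2)
  labs <- label_components(mask, connectivity = connectivity)
  tbl <- dot_table_from_labels(labs, image = image,
                               lateral_scale = lateral_scale,
                               axial_scale = axial_scale,
                               lens_axis_col = lens_axis_col)
  keep <- tbl$pixel_count >= min_pixels
  tbl <- tbl[keep, , drop = FALSE]
  # re-densify labels after the size filter
  old <- tbl$label
  labs[!labs %in% old] <- 0L
  if (nrow(tbl) > 0L) {
    relabel <- integer(max(old))
    relabel[old] <- seq_len(nrow(tbl))
    pos <- labs > 0L
    labs[pos] <- relabel[labs[pos]]
    tbl$label <- seq_len(nrow(tbl))
  }
  attr(tbl, "labels") <- labs
  tbl
}

# per-label profile of an integer label raster
dot_table_from_labels <- function(labs, image = NULL,
                                  lateral_scale = 0.0125,
                                  axial_scale = 0.015625,
                                  lens_axis_col = NULL) {
  if (is.null(lens_axis_col)) lens_axis_col <- ceiling(ncol(labs) / 2)
  idx <- which(labs > 0L)
  if (length(idx) == 0L) {
    return(tibble::tibble(
      label = integer(), pixel_count = integer(),
      centroid_row = numeric(), centroid_col = numeric(),
      centroid_lateral_mm = numeric(), centroid_axial_mm = numeric(),
      mean_intensity = numeric(), lateral_offset_mm = numeric()
    ))
  }
  nr <- nrow(labs)
  lab <- labs[idx]
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  px <- if (is.null(image)) rep(NA_real_, length(idx)) else as_pixels(image)[idx]
  df <- tibble::tibble(lab = lab, r = r, c = c, px = px)
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$lab),
    pixel_count = dplyr::n(),
    centroid_row = mean(.data$r),
    centroid_col = mean(.data$c),
    mean_intensity = mean(.data$px),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$lab)
  tibble::tibble(
    label = as.integer(out$lab),
    pixel_count = as.integer(out$pixel_count),
    centroid_row = out$centroid_row,
    centroid_col = out$centroid_col,
    centroid_lateral_mm = (out$centroid_col - 1) * lateral_scale,
    centroid_axial_mm = (out$centroid_row - 1) * axial_scale,
    mean_intensity = out$mean_intensity,
    lateral_offset_mm = abs(out$centroid_col - lens_axis_col) * lateral_scale
  )
}

#' Mask of the central lens region
#'
#' Selects the columns of a B-scan lying in the central window of the lens
#' (the central 4–4.5 mm in the grading protocol; default width 4.25 mm).
#' A column is central when its lateral offset from the axis column falls in
#' the half-open interval `[-width/2, width/2)`, so a 4 mm window at
#' 0.0125 mm/column selects exactly 320 columns.
#'
#' @param image A [bscan()] (or matrix plus `lateral_scale`).
#' @param lens_axis_col Axis column (1-based); default centre column.
#' @param central_width_mm Window width in mm (>= 0).
#' @param lateral_scale mm per column when `image` is a plain matrix.
#'
#' @return Logical matrix, `TRUE` on central columns.
#' @export
central_region_mask <- function(image, lens_axis_col = NULL,
                                central_width_mm = 4.25,
                                lateral_scale = 0.0125) {
  m <- as_pixels(image)
  if (is_bscan(image)) lateral_scale <- image$lateral_scale
  if (is.null(lens_axis_col)) lens_axis_col <- ceiling(ncol(m) / 2)
  if (lens_axis_col < 1 || lens_axis_col > ncol(m)) {
    stop(sprintf("lens axis column %s is outside the image (1..%d)",
                 format(lens_axis_col), ncol(m)), call. = FALSE)
  }
  if (central_width_mm < 0) {
    stop("`central_width_mm` must be >= 0", call. = FALSE)
  }
  off <- (seq_len(ncol(m)) - lens_axis_col) * lateral_scale
  central_cols <- is_central_offset(off, central_width_mm)
  matrix(central_cols, nrow = nrow(m), ncol = ncol(m), byrow = TRUE)
}

# half-open centrality test shared by column masks and dot centroids
is_central_offset <- function(offset_mm, central_width_mm) {
  offset_mm >= -central_width_mm / 2 & offset_mm < central_width_mm / 2
}

#' Threshold-based automatic dot detection
#'
#' Convenience automation of the (manual, in practice) dot identification:
#' flags pixels brighter than a robust threshold derived from the opacity
#' -free cortex, then removes components smaller than `min_pixels`. The
#' threshold is `median + k_sigma * mad` of the cortex intensities
#' (`mad` with the usual 1.4826 consistency factor), robust against the dot
#' pixels that contaminate the cortex distribution.
#'
#' @param image A [bscan()].
#' @param cortex_mask Logical matrix of cortex pixels (must be nonempty);
#'   supplies the background distribution.
#' @param k_sigma Threshold multiplier (default 4).
#' @param min_pixels Minimum surviving component size (default 2).
#' @param search_mask Optional logical matrix restricting where dots are
#'   sought; defaults to `cortex_mask`.
#' @param connectivity 4 or 8 for the component cleaning step.
#'
#' @return Logical matrix of detected dot pixels.
#' @export
detect_dots <- function(image, cortex_mask, k_sigma = 4, min_pixels = 2,
                        search_mask = NULL, connectivity = 8) {
  px <- as_pixels(image)
  cortex_mask <- as_logical_mask(cortex_mask)
  bg <- px[cortex_mask]
  bg <- bg[!is.na(bg)]
  if (length(bg) == 0L) {
    stop("`cortex_mask` selects no pixels", call. = FALSE)
  }
  if (is.null(search_mask)) search_mask <- cortex_mask
  thr <- stats::median(bg) + k_sigma * stats::mad(bg)
  cand <- as_logical_mask(search_mask) & !is.na(px) & px > thr
  labs <- label_components(cand, connectivity = connectivity)
  if (max(labs) == 0L) return(cand & FALSE)
  sizes <- tabulate(labs[labs > 0L])
  keep <- which(sizes >= min_pixels)
  matrix(labs %in% keep, nrow(px), ncol(px))
}
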