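#' Nuclear pixel intensity ratio
#'
#' The mean pixel intensity of the nucleus divided by the mean intensity of
#' the aqueous humour, which serves as the background intensity reference.
#' Labelled dot pixels are excluded from the nucleus mean so that punctate
#' opacities — a separate class, occasionally found inside the nucleus — do
#' not inflate the nuclear opalescence measure. Sentinel (`NA`) pixels from
#' composed whole-lens images are always excluded. When the segmentation
#' covers both anterior and posterior halves of the lens in one composed
#' image, all nucleus pixels are pooled into a single mean.
#'
#' @param image A [bscan()].
#' @param seg A validated [lens_segmentation()].
#'
#' @return A single ratio (> 0 for any real scan).
#' @examples
#' px <- matrix(100, 20, 20); px[11:20, ] <- 120
#' seg <- lens_segmentation(
#'   aqueous_mask = row(px) <= 10, nucleus_mask = row(px) > 10,
#'   cortex_mask = matrix(FALSE, 20, 20))
#' nuclear_pir(bscan(px), seg) # 1.2
#' @export
nuclear_pir <- function(image, seg) {
  px <- as_pixels(image)
  nuc <- seg$nucleus_mask & !(seg$dot_labels > 0L)
  if (!any(nuc)) stop("nucleus mask is empty", call. = FALSE)
  if (!any(seg$aqueous_mask)) stop("aqueous mask is empty", call. = FALSE)
  aq_mean <- mask_mean(px, seg$aqueous_mask)
  nuc_mean <- mask_mean(px, nuc)
  if (is.na(aq_mean) || is.na(nuc_mean)) {
    stop("nucleus or aqueous mask contains only sentinel pixels", call. = FALSE)
  }
  if (aq_mean == 0) stop("aqueous mean intensity is zero", call. = FALSE)
  nuc_mean / aq_mean
}

#' Cortical / PSC opacity intensity and area ratios
#'
#' For the chosen region (cortex or PSC zone), computes the PIR — mean
#' intensity of the areal opacity pixels inside the region divided by the
#' mean intensity of the entire opacity-free cortex-or-region background —
#' and the PAR, the opacity area as a fraction of the region area. Labelled
#' dot pixels are excluded from the opacity-free background. When the region
#' carries no opacity both ratios are 0, the convention used for eyes with
#' no quantifiable cortical or PSC change.
#'
#' @param image A [bscan()].
#' @param seg A validated [lens_segmentation()]; areal opacities come from
#'   `seg$opacity_mask`.
#' @param region `"cortical"` or `"psc"`.
#'
#' @return A one-row tibble with columns `pir` and `par`.
#' @export
region_opacity_metrics <- function(image, seg, region = c("cortical", "psc")) {
  region <- match.arg(region)
  px <- as_pixels(image)
  rmask <- if (region == "cortical") seg$cortex_mask else seg$psc_mask
  if (!any(rmask)) {
    stop(sprintf("%s region mask is empty", region), call. = FALSE)
  }
  op <- seg$opacity_mask & rmask
  if (!any(op)) {
    return(tibble::tibble(pir = 0, par = 0))
  }
  bg <- rmask & !seg$opacity_mask & !(seg$dot_labels > 0L)
  bg_mean <- mask_mean(px, bg)
  if (!any(bg) || is.na(bg_mean)) {
    stop(sprintf("opacity covers the entire %s region: no opacity-free background, PIR undefined",
                 region), call. = FALSE)
  }
  tibble::tibble(
    pir = mask_mean(px, op) / bg_mean,
    par = sum(op) / sum(rmask)
  )
}

#' Dot opacity metrics for one eye
#'
#' Pools all labelled dot pixels and grades them against the opacity-free
#' cortex: `dot_pir` is the mean intensity over every dot pixel divided by
#' the mean over the opacity-free cortex (one background for all dots, even
#' those lying in the nucleus), and `dot_par` is the total dot area as a
#' fraction of the cortex area. Each dot is classified central or
#' peripheral by whether its centroid falls inside the central window (see
#' [central_region_mask()] for the half-open convention).
#'
#' @param image A [bscan()].
#' @param seg A validated [lens_segmentation()] with dots labelled.
#' @param central_width_mm Width of the central window (default 4.25 mm,
#'   the midpoint of the 4–4.5 mm grading window).
#'
#' @return A one-row tibble with `dot_pir`, `dot_par`, `dot_count`,
#'   `dot_count_central`, `central_proportion` (`NA` when there are no
#'   dots). The per-dot profile, including a per-dot `pir` column, is
#'   attached as attribute `"per_dot"`.
#' @export
dot_metrics <- function(image, seg, central_width_mm = 4.25) {
  px <- as_pixels(image)
  dmask <- seg$dot_labels > 0L
  if (!any(dmask)) {
    out <- tibble::tibble(dot_pir = 0, dot_par = 0, dot_count = 0L,
                          dot_count_central = 0L,
                          central_proportion = NA_real_)
    attr(out, "per_dot") <- dot_table_from_labels(
      seg$dot_labels, image = image, lens_axis_col = seg$lens_axis_col)
    return(out)
  }
  if (!any(seg$cortex_mask)) stop("cortex mask is empty", call. = FALSE)
  bg <- seg$cortex_mask & !dmask & !seg$opacity_mask
  bg_mean <- mask_mean(px, bg)
  if (!any(bg) || is.na(bg_mean)) {
    stop("opacities cover the entire cortex: no opacity-free background",
         call. = FALSE)
  }
  scales <- if (is_bscan(image)) {
    c(image$lateral_scale, image$axial_scale)
  } else {
    c(0.0125, 0.015625)
  }
  per_dot <- dot_table_from_labels(seg$dot_labels, image = image,
                                   lateral_scale = scales[1],
                                   axial_scale = scales[2],
                                   lens_axis_col = seg$lens_axis_col)
  per_dot$pir <- per_dot$mean_intensity / bg_mean
  signed_off <- (per_dot$centroid_col - seg$lens_axis_col) * scales[1]
  per_dot$central <- is_central_offset(signed_off, central_width_mm)
  n <- nrow(per_dot)
  n_central <- sum(per_dot$central)
  out <- tibble::tibble(
    dot_pir = mask_mean(px, dmask) / bg_mean,
    dot_par = sum(dmask) / sum(seg$cortex_mask),
    dot_count = as.integer(n),
    dot_count_central = as.integer(n_central),
    central_proportion = n_central / n
  )
  attr(out, "per_dot") <- per_dot
  out
}

#' Keep only true PSC components (central 3 mm rule)
#'
#' An opacity is considered a true posterior subcapsular cataract only when
#' it lies in the central 3 mm of the lens. Given a component table carrying
#' `lateral_offset_mm` (e.g. from [label_dots()]), retains exactly the
#' components whose centroid offset is at most `central_width_mm / 2`
#' (1.5 mm by default).
#'
#' @param components A data frame with a `lateral_offset_mm` column.
#' @param central_width_mm Width of the central zone (default 3 mm).
#'
#' @return The filtered tibble.
#' @export
filter_true_psc <- function(components, central_width_mm = 3) {
  stopifnot("lateral_offset_mm" %in% names(components))
  dplyr::filter(tibble::as_tibble(components),
                .data$lateral_offset_mm <= central_width_mm / 2)
}

#' Quantify all opacity metrics for one eye
#'
#' Orchestrates the full per-eye quantification: nuclear PIR against the
#' aqueous background, cortical and PSC PIR/PAR for areal opacities, and
#' the dot profile (pooled PIR/PAR, count, central/peripheral breakdown).
#' Deterministic for fixed inputs. A PSC zone that is empty of both region
#' and opacity pixels yields zeros — the convention for eyes with no
#' quantifiable PSC change — rather than an error.
#'
#' @param image A [bscan()].
#' @param seg A [lens_segmentation()]; validated first unless
#'   `validate = FALSE`.
#' @param central_width_mm Central window width for the dot breakdown.
#' @param validate Run [validate_segmentation()] first (default `TRUE`).
#'
#' @return A one-row tibble of class `opacity_metrics` with columns
#'   `eye_id`, `nuclear_pir`, `cortical_pir`, `cortical_par`, `psc_pir`,
#'   `psc_par`, `dot_pir`, `dot_par`, `dot_count`, `dot_count_central`,
#'   `central_proportion`; the per-dot table is attached as attribute
#'   `"per_dot"` (see [tidy.opacity_metrics()]).
#' @examples
#' scene <- generate_scene(scene_spec(image_rows = 96, image_cols = 192,
#'                                    lateral_scale = 16 / 192,
#'                                    axial_scale = 8 / 96,
#'                                    dot_count = 4, speckle_cv = 0))
#' quantify_eye(scene$image, scene$truth)
#' @export
quantify_eye <- function(image, seg, central_width_mm = 4.25,
                         validate = TRUE) {
  if (validate) validate_segmentation(seg, image)
  cort <- region_opacity_metrics(image, seg, "cortical")
  psc <- if (!any(seg$psc_mask)) {
    tibble::tibble(pir = 0, par = 0)
  } else {
    region_opacity_metrics(image, seg, "psc")
  }
  dots <- dot_metrics(image, seg, central_width_mm = central_width_mm)
  out <- tibble::tibble(
    eye_id = if (is_bscan(image)) image$source_id else NA_character_,
    nuclear_pir = nuclear_pir(image, seg),
    cortical_pir = cort$pir, cortical_par = cort$par,
    psc_pir = psc$pir, psc_par = psc$par,
    dot_pir = dots$dot_pir, dot_par = dots$dot_par,
    dot_count = dots$dot_count,
    dot_count_central = dots$dot_count_central,
    central_proportion = dots$central_proportion
  )
  attr(out, "per_dot") <- attr(dots, "per_dot")
  class(out) <- c("opacity_metrics", class(out))
  out
}

#' Write / read per-eye opacity metrics as CSV
#'
#' One row per eye with the canonical column names (`nuclear_pir`,
#' `cortical_pir`, `cortical_par`, `psc_pir`, `psc_par`, `dot_pir`,
#' `dot_par`, `dot_count`, `dot_count_central`, ...).
#'
#' @param metrics A tibble of per-eye metrics (e.g. rows from
#'   [quantify_eye()]).
#' @param path CSV file path.
#' @return `write_metrics()`: `path` invisibly; `read_metrics()`: a tibble.
#' @export
write_metrics <- function(metrics, path) {
  readr::write_csv(tibble::as_tibble(metrics), path)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
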