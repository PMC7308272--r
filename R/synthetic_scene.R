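# run code under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic phantom B-scan
#'
#' Declares the scene a phantom generator renders: a dark aqueous
#' background, an elliptical lens with a cortex band and a brighter
#' nucleus, hyper-reflective punctate dot opacities brighter than the
#' nucleus, and multiplicative speckle-like noise. Defaults mirror the
#' display-resolution geometry (512 x 1280 over a 16 x 8 mm field) and
#' intensity ratios typical of trisomy-21 lenses: nuclear PIR
#' `nucleus_level / aqueous_level = 1.19`, dot PIR
#' `dot_level / cortex_level = 1.33`, 9 dots per eye with roughly 47% of
#' them inside the central 4–4.5 mm window.
#'
#' @param image_rows,image_cols Raster shape.
#' @param lateral_scale,axial_scale Pixel pitch, mm (defaults preserve a
#'   16 mm wide x 8 mm deep field at any raster shape when set to
#'   `16 / image_cols` and `8 / image_rows`).
#' @param aqueous_level,cortex_level,nucleus_level Region intensities;
#'   paper-like scenes require `nucleus >= cortex >= aqueous > 0`.
#' @param dot_count Number of dots to place (0 for a clear lens).
#' @param dot_radius_px Inclusive integer range of dot radii in pixels.
#' @param dot_level Dot intensity (default `1.33 * cortex_level`).
#' @param central_fraction Target fraction of dots whose centroid falls in
#'   the central window (default 0.468, i.e. 53.2% peripheral).
#' @param central_width_mm Central window width (default 4.25 mm).
#' @param speckle_cv Coefficient of variation of the multiplicative
#'   speckle; 0 renders a noise-free scene. Default 0.05.
#' @param seed Integer seed making the scene fully reproducible.
#'
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(image_rows = 512, image_cols = 1280,
                       lateral_scale = 16 / image_cols,
                       axial_scale = 8 / image_rows,
                       aqueous_level = 100, cortex_level = 105,
                       nucleus_level = 119,
                       dot_count = 9, dot_radius_px = c(1, 3),
                       dot_level = 1.33 * cortex_level,
                       central_fraction = 0.468, central_width_mm = 4.25,
                       speckle_cv = 0.05, seed = 1) {
  if (aqueous_level <= 0) stop("`aqueous_level` must be > 0", call. = FALSE)
  if (!(nucleus_level >= cortex_level && cortex_level >= aqueous_level)) {
    stop("paper-like scenes require nucleus_level >= cortex_level >= aqueous_level",
         call. = FALSE)
  }
  if (central_fraction < 0 || central_fraction > 1) {
    stop("`central_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (speckle_cv < 0) stop("`speckle_cv` must be >= 0", call. = FALSE)
  dot_radius_px <- as.integer(round(range(dot_radius_px)))
  if (dot_radius_px[1] < 1L) stop("dot radii must be >= 1 pixel", call. = FALSE)
  structure(
    list(image_rows = as.integer(image_rows),
         image_cols = as.integer(image_cols),
         lateral_scale = lateral_scale, axial_scale = axial_scale,
         aqueous_level = aqueous_level, cortex_level = cortex_level,
         nucleus_level = nucleus_level,
         dot_count = as.integer(dot_count), dot_radius_px = dot_radius_px,
         dot_level = dot_level,
         central_fraction = central_fraction,
         central_width_mm = central_width_mm,
         speckle_cv = speckle_cv, seed = as.integer(seed)),
    class = "scene_spec"
  )
}

# region geometry for a spec: elliptical lens (semi-axes capped at
# 4.5 x 2.25 mm) with a concentric nucleus at 60% of the lens semi-axes,
# aqueous filling the field above the lens, PSC zone = posterior outer
# shell within the central 3 mm
scene_geometry <- function(spec) {
  nr <- spec$image_rows; nc <- spec$image_cols
  rmat <- matrix(seq_len(nr), nr, nc)
  cmat <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  c0 <- ceiling(nc / 2)
  r0 <- round(0.55 * nr)
  sa_lat <- min(4.5 / spec$lateral_scale, 0.35 * nc)
  sa_ax <- min(2.25 / spec$axial_scale, 0.30 * nr)
  en <- ((cmat - c0) / sa_lat)^2 + ((rmat - r0) / sa_ax)^2
  lens <- en <= 1
  nucleus <- ((cmat - c0) / (0.6 * sa_lat))^2 +
    ((rmat - r0) / (0.6 * sa_ax))^2 <= 1
  cortex <- lens & !nucleus
  aqueous <- !lens & rmat < r0
  psc <- cortex & en >= 0.8 & rmat > r0 &
    abs(cmat - c0) * spec$lateral_scale <= 1.5
  list(lens = lens, nucleus = nucleus, cortex = cortex, aqueous = aqueous,
       psc = psc, axis_col = c0, center_row = r0)
}

disk_offsets <- function(radius) {
  d <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  d[d$dr^2 + d$dc^2 <= radius^2, , drop = FALSE]
}

#' Generate a synthetic phantom scene with known ground truth
#'
#' Renders the phantom described by a [scene_spec()]: region masks,
#' non-overlapping dots placed by rejection sampling (split between the
#' central window and the periphery to hit `central_fraction` up to
#' rounding), optional multiplicative gamma speckle (unit mean,
#' CV = `speckle_cv`), and the analytically expected per-eye metrics
#' computed from the spec and the placed dots — never from the rendered
#' image. Bit-identical output for a fixed seed.
#'
#' @param spec A [scene_spec()].
#' @param max_tries Rejection-sampling budget per dot before the packing is
#'   declared infeasible.
#'
#' @return A `synthetic_scene` list: `image` ([bscan()]), `truth`
#'   ([lens_segmentation()], guaranteed to pass
#'   [validate_segmentation()]), `expected` (one-row tibble of analytic
#'   metrics), `dots` (per-dot truth table) and `spec`.
#' @examples
#' sc <- generate_scene(scene_spec(image_rows = 96, image_cols = 192,
#'                                 dot_count = 5, speckle_cv = 0, seed = 7))
#' sc$expected$nuclear_pir # 119 / 100
#' @export
generate_scene <- function(spec, max_tries = 500) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    geo <- scene_geometry(spec)
    nr <- spec$image_rows; nc <- spec$image_cols
    labs <- matrix(0L, nr, nc)
    rmin <- spec$dot_radius_px[1]; rmax <- spec$dot_radius_px[2]
    n_dots <- spec$dot_count
    # binomial split hits central_fraction in expectation
    n_central <- stats::rbinom(1L, n_dots, spec$central_fraction)
    col_off <- (seq_len(nc) - geo$axis_col) * spec$lateral_scale
    central_cols <- which(is_central_offset(col_off, spec$central_width_mm))
    cortex_idx <- which(geo$cortex)
    idx_col <- ((cortex_idx - 1L) %/% nr) + 1L
    centers <- NULL # placed dot centres (row, col, radius)
    placed <- 0L
    if (n_dots > 0L && length(cortex_idx) == 0L) {
      stop("cortex region is empty; cannot place dots", call. = FALSE)
    }
    while (placed < n_dots) {
      want_central <- placed < n_central
      pool <- if (want_central) {
        cortex_idx[idx_col %in% central_cols]
      } else {
        cortex_idx[!(idx_col %in% central_cols)]
      }
      if (length(pool) == 0L) {
        stop("infeasible dot packing: no eligible cortex pixels for the requested central/peripheral split",
             call. = FALSE)
      }
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        rad <- if (rmax > rmin) sample(rmin:rmax, 1L) else rmin
        cand <- pool[sample.int(length(pool), 1L)]
        cr <- ((cand - 1L) %% nr) + 1L
        cc <- ((cand - 1L) %/% nr) + 1L
        offs <- disk_offsets(rad)
        dr <- cr + offs$dr; dc <- cc + offs$dc
        if (any(dr < 1L | dr > nr | dc < 1L | dc > nc)) next
        pix <- (dc - 1L) * nr + dr
        if (!all(geo$cortex[pix])) next # disk must sit fully in the cortex
        if (!is.null(centers)) {
          # gap of > 1 px keeps dots 8-disconnected
          dist_ok <- sqrt((centers[, 1] - cr)^2 + (centers[, 2] - cc)^2) >
            centers[, 3] + rad + 1.5
          if (!all(dist_ok)) next
        }
        placed <- placed + 1L
        labs[pix] <- placed
        centers <- rbind(centers, c(cr, cc, rad))
        ok <- TRUE
        break
      }
      if (!ok) {
        stop(sprintf("infeasible dot packing: gave up after %d tries for dot %d of %d",
                     max_tries, placed + 1L, n_dots), call. = FALSE)
      }
    }
    img <- matrix(spec$aqueous_level, nr, nc)
    img[geo$cortex] <- spec$cortex_level
    img[geo$nucleus] <- spec$nucleus_level
    img[labs > 0L] <- spec$dot_level
    if (spec$speckle_cv > 0) {
      shape <- 1 / spec$speckle_cv^2
      img <- img * matrix(stats::rgamma(nr * nc, shape = shape, rate = shape),
                          nr, nc)
    }
    image <- bscan(img, lateral_scale = spec$lateral_scale,
                   axial_scale = spec$axial_scale, half = "whole",
                   meridian_deg = 90,
                   source_id = sprintf("synthetic-seed-%d", spec$seed))
    truth <- lens_segmentation(
      aqueous_mask = geo$aqueous, nucleus_mask = geo$nucleus,
      cortex_mask = geo$cortex, psc_mask = geo$psc,
      dot_labels = labs, lens_axis_col = geo$axis_col
    )
    dots <- scene_dot_truth(spec, labs, centers, geo$axis_col)
    expected <- scene_expected_metrics(spec, geo, dots)
    structure(
      list(image = image, truth = truth, expected = expected, dots = dots,
           spec = spec),
      class = "synthetic_scene"
    )
  })
}

# per-dot truth table from placed centres (disks are symmetric, so the
# centroid is the centre pixel exactly)
scene_dot_truth <- function(spec, labs, centers, axis_col) {
  if (is.null(centers)) {
    return(tibble::tibble(label = integer(), pixel_count = integer(),
                          centroid_row = numeric(), centroid_col = numeric(),
                          radius_px = integer(), lateral_offset_mm = numeric(),
                          central = logical()))
  }
  counts <- tabulate(labs[labs > 0L], nbins = nrow(centers))
  signed_off <- (centers[, 2] - axis_col) * spec$lateral_scale
  tibble::tibble(
    label = seq_len(nrow(centers)),
    pixel_count = as.integer(counts),
    centroid_row = centers[, 1],
    centroid_col = centers[, 2],
    radius_px = as.integer(centers[, 3]),
    lateral_offset_mm = abs(signed_off),
    central = is_central_offset(signed_off, spec$central_width_mm)
  )
}

# analytic noise-free expectations (spec arithmetic, not image statistics)
scene_expected_metrics <- function(spec, geo, dots) {
  n_dot_px <- sum(dots$pixel_count)
  n_cortex <- sum(geo$cortex)
  n <- nrow(dots)
  tibble::tibble(
    nuclear_pir = spec$nucleus_level / spec$aqueous_level,
    cortical_pir = 0, cortical_par = 0,
    psc_pir = 0, psc_par = 0,
    dot_pir = if (n > 0) spec$dot_level / spec$cortex_level else 0,
    dot_par = if (n > 0) n_dot_px / n_cortex else 0,
    dot_count = as.integer(n),
    dot_count_central = as.integer(sum(dots$central)),
    central_proportion = if (n > 0) sum(dots$central) / n else NA_real_
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> seed %d, %d x %d, %d dot(s), speckle CV %g\n",
              x$spec$seed, x$spec$image_rows, x$spec$image_cols,
              x$expected$dot_count, x$spec$speckle_cv))
  cat(sprintf("  expected nuclear PIR %.4g, dot PIR %.4g, dot PAR %.4g\n",
              x$expected$nuclear_pir, x$expected$dot_pir, x$expected$dot_par))
  invisible(x)
}
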