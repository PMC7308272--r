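#' Compose a whole-lens image from anterior and posterior halves
#'
#' Anterior and posterior B-scans are acquired separately and aligned
#' vertically to present the whole lens. The composed image stacks the
#' anterior half on top of the posterior half, optionally separated by an
#' unimaged axial gap. Gap rows are filled with the `NA` sentinel — never
#' zero, which would bias background means — and are excluded from every
#' statistic computed by this package. No intensity of either half is
#' altered.
#'
#' @param anterior,posterior [bscan()] halves sharing pixel pitch, meridian
#'   and column count.
#' @param axial_offset_mm Physical gap between the two acquisitions, in mm;
#'   converted to `round(axial_offset_mm / axial_scale)` sentinel rows.
#'
#' @return A [bscan()] with `half = "whole"` and
#'   `nrow(anterior) + gap + nrow(posterior)` rows.
#' @export
compose_whole_lens <- function(anterior, posterior, axial_offset_mm = 0) {
  stopifnot(is_bscan(anterior), is_bscan(posterior))
  if (!isTRUE(all.equal(anterior$lateral_scale, posterior$lateral_scale)) ||
      !isTRUE(all.equal(anterior$axial_scale, posterior$axial_scale))) {
    stop("anterior and posterior halves must share lateral and axial pixel pitch",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(anterior$meridian_deg, posterior$meridian_deg))) {
    stop("anterior and posterior halves must share the acquisition meridian",
         call. = FALSE)
  }
  if (ncol(anterior$pixels) != ncol(posterior$pixels)) {
    stop("anterior and posterior halves must have the same number of columns",
         call. = FALSE)
  }
  if (axial_offset_mm < 0) {
    stop("`axial_offset_mm` must be >= 0", call. = FALSE)
  }
  gap <- as.integer(round(axial_offset_mm / anterior$axial_scale))
  nc <- ncol(anterior$pixels)
  px <- rbind(anterior$pixels,
              matrix(NA_real_, gap, nc),
              posterior$pixels)
  bscan(px,
        lateral_scale = anterior$lateral_scale,
        axial_scale = anterior$axial_scale,
        half = "whole",
        meridian_deg = anterior$meridian_deg,
        source_id = paste0(anterior$source_id, "+", posterior$source_id))
}
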