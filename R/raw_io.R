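#' Describe the binary layout of a raw detector export
#'
#' Raw B-scans arrive as headerless binary dumps of the detector matrix; the
#' instrument's export format is not published, so every aspect of the layout
#' is configurable. The default is a 512 x 512 matrix of 8-bit samples in
#' row-major order, little-endian.
#'
#' @param rows,cols Matrix shape of the exported scan.
#' @param sample_depth `"8-bit"` or `"16-bit"` unsigned samples.
#' @param byte_order `"little"` or `"big"` (relevant for 16-bit samples).
#' @param layout `"row-major"` (C order) or `"column-major"` (Fortran order).
#'
#' @return A `raw_dialect` list.
#' @export
raw_dialect <- function(rows = 512, cols = 512,
                        sample_depth = c("8-bit", "16-bit"),
                        byte_order = c("little", "big"),
                        layout = c("row-major", "column-major")) {
  sample_depth <- match.arg(sample_depth)
  byte_order <- match.arg(byte_order)
  layout <- match.arg(layout)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop("`rows` and `cols` must be >= 1", call. = FALSE)
  structure(
    list(rows = rows, cols = cols, sample_depth = sample_depth,
         byte_order = byte_order, layout = layout),
    class = "raw_dialect"
  )
}

dialect_bytes_per_sample <- function(dialect) {
  if (dialect$sample_depth == "8-bit") 1L else 2L
}

#' Read a raw detector matrix as a B-scan
#'
#' Reads a headerless binary detector export according to `dialect` and wraps
#' it as a [bscan()]. Intensities are preserved losslessly; a payload size
#' that disagrees with the dialect is reported as an error since it almost
#' always means the wrong dialect was supplied.
#'
#' @param path Path to the raw file.
#' @param dialect A [raw_dialect()] describing the binary layout.
#' @param lateral_scale,axial_scale Physical pixel pitch in mm (see [bscan()]).
#' @param half,meridian_deg,source_id Acquisition metadata; `source_id`
#'   defaults to the file name.
#'
#' @return A [bscan()] of shape `dialect$rows` x `dialect$cols`.
#' @seealso [write_raw_scan()] for the inverse operation.
#' @export
read_raw_scan <- function(path, dialect = raw_dialect(),
                          lateral_scale = 0.0125, axial_scale = 0.015625,
                          half = "anterior", meridian_deg = 90,
                          source_id = basename(path)) {
  if (!file.exists(path)) {
    stop(sprintf("raw scan file not found: '%s'", path), call. = FALSE)
  }
  bps <- dialect_bytes_per_sample(dialect)
  n <- dialect$rows * dialect$cols
  expected <- as.numeric(n) * bps
  actual <- file.info(path)$size
  if (!isTRUE(actual == expected)) {
    stop(sprintf(
      "payload size mismatch: file '%s' has %d bytes but dialect %dx%d %s requires %d (wrong dialect?)",
      path, actual, dialect$rows, dialect$cols, dialect$sample_depth, expected
    ), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "integer", n = n, size = bps,
                  signed = FALSE, endian = dialect$byte_order)
  m <- matrix(as.double(vals), nrow = dialect$rows, ncol = dialect$cols,
              byrow = dialect$layout == "row-major")
  bscan(m, lateral_scale = lateral_scale, axial_scale = axial_scale,
        half = half, meridian_deg = meridian_deg, source_id = source_id)
}

#' Write a detector matrix as a headerless raw file
#'
#' The exact inverse of [read_raw_scan()]: integer intensities within the
#' sample-depth range round-trip bit-exactly.
#'
#' @param image A [bscan()] or plain matrix of non-negative integers.
#' @param path Output file path.
#' @param dialect A [raw_dialect()]; its shape must match the image.
#'
#' @return `path`, invisibly.
#' @export
write_raw_scan <- function(image, path, dialect = raw_dialect()) {
  m <- as_pixels(image)
  if (nrow(m) != dialect$rows || ncol(m) != dialect$cols) {
    stop(sprintf("image is %dx%d but dialect says %dx%d",
                 nrow(m), ncol(m), dialect$rows, dialect$cols), call. = FALSE)
  }
  bps <- dialect_bytes_per_sample(dialect)
  maxv <- 2^(8L * bps) - 1
  if (anyNA(m) || any(m < 0) || any(m > maxv) || any(m != round(m))) {
    stop(sprintf("raw export requires integer intensities in [0, %d]", maxv),
         call. = FALSE)
  }
  vec <- if (dialect$layout == "row-major") as.vector(t(m)) else as.vector(m)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(vec), con, size = bps, endian = dialect$byte_order)
  invisible(path)
}
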