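#' Bicubic resampling of a B-scan
#'
#' Resizes a scan to the display resolution (the instrument's recommended
#' 512 x 1280 for a 512 x 512 raw matrix) by separable cubic convolution.
#' The kernel is the Keys cubic with `a = -0.5` — the conventional "bicubic"
#' default of mainstream imaging stacks — with symmetric (half-sample mirror)
#' boundary handling and no antialiasing prefilter. Output coordinates are
#' mapped to input coordinates by pixel-centre alignment,
#' `src = (dst + 0.5) * n_src / n_dst - 0.5` (0-based), so resizing to the
#' input's own shape is the identity. Interpolation overshoot below zero is
#' clamped to zero; pixel pitch is rescaled so the physical extent of the
#' scan is preserved.
#'
#' @param image A [bscan()] (or plain matrix, in which case a matrix is
#'   returned).
#' @param target_rows,target_cols Output shape; each must be at least 4
#'   (the support of the cubic kernel).
#'
#' @return The resized [bscan()] (or matrix) of shape
#'   `target_rows` x `target_cols`.
#' @examples
#' img <- bscan(matrix(runif(64 * 64, 0, 255), 64, 64))
#' big <- resize_bicubic(img, 64, 160)
#' dim(big)
#' @export
resize_bicubic <- function(image, target_rows, target_cols) {
  target_rows <- as.integer(target_rows)
  target_cols <- as.integer(target_cols)
  if (target_rows < 4L || target_cols < 4L) {
    stop("target dimensions must be >= 4 in each axis (bicubic support)",
         call. = FALSE)
  }
  m <- as_pixels(image)
  if (anyNA(m)) {
    stop("resize_bicubic does not accept sentinel (NA) pixels; resize halves before composing",
         call. = FALSE)
  }
  wr <- cubic_weight_matrix(nrow(m), target_rows)
  wc <- cubic_weight_matrix(ncol(m), target_cols)
  out <- wr %*% m %*% t(wc)
  out[out < 0] <- 0
  if (!is_bscan(image)) return(out)
  bscan(out,
        lateral_scale = image$lateral_scale * ncol(m) / target_cols,
        axial_scale = image$axial_scale * nrow(m) / target_rows,
        half = image$half, meridian_deg = image$meridian_deg,
        source_id = image$source_id)
}

# Keys cubic convolution kernel, a = -0.5
cubic_kernel <- function(t, a = -0.5) {
  at <- abs(t)
  w <- numeric(length(at))
  i1 <- at <= 1
  i2 <- !i1 & at < 2
  w[i1] <- (a + 2) * at[i1]^3 - (a + 3) * at[i1]^2 + 1
  w[i2] <- a * (at[i2]^3 - 5 * at[i2]^2 + 8 * at[i2] - 4)
  w
}

# symmetric (half-sample) mirror: ... 2 1 | 1 2 ... n-1 n | n n-1 ...
mirror_index <- function(i, n) {
  p <- (i - 1L) %% (2L * n)
  p <- ifelse(p < 0L, p + 2L * n, p)
  ifelse(p < n, p, 2L * n - 1L - p) + 1L
}

# dense n_dst x n_src matrix of 4-tap cubic weights
cubic_weight_matrix <- function(n_src, n_dst) {
  scale <- n_src / n_dst
  centers <- (seq_len(n_dst) - 1 + 0.5) * scale - 0.5 # 0-based src coords
  base <- floor(centers)
  w <- matrix(0, n_dst, n_src)
  rows <- seq_len(n_dst)
  for (k in -1:2) {
    idx0 <- base + k
    wk <- cubic_kernel(centers - idx0)
    idx <- mirror_index(as.integer(idx0) + 1L, n_src)
    ij <- cbind(rows, idx)
    w[ij] <- w[ij] + wk
  }
  w
}
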