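# Independent oracles used across the suite. These deliberately do not
# share code with the package: flood fill instead of graph components,
# per-pixel loops instead of weight matrices, pairwise U counting instead
# of rank sums.

# recursive flood fill connected-component labelling
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  lab <- 0L
  for (cc in seq_len(nc)) {
    for (rr in seq_len(nr)) {
      if (mask[rr, cc] && out[rr, cc] == 0L) {
        lab <- lab + 1L
        stack <- list(c(rr, cc))
        out[rr, cc] <- lab
        while (length(stack) > 0) {
          p <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          for (k in seq_len(nrow(offs))) {
            r2 <- p[1] + offs[k, 1]; c2 <- p[2] + offs[k, 2]
            if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
                mask[r2, c2] && out[r2, c2] == 0L) {
              out[r2, c2] <- lab
              stack[[length(stack) + 1]] <- c(r2, c2)
            }
          }
        }
      }
    }
  }
  out
}

# direct per-pixel Keys cubic convolution (a = -0.5), symmetric mirror
naive_bicubic <- function(m, target_rows, target_cols) {
  kern <- function(t) {
    a <- -0.5; at <- abs(t)
    if (at <= 1) (a + 2) * at^3 - (a + 3) * at^2 + 1
    else if (at < 2) a * (at^3 - 5 * at^2 + 8 * at - 4)
    else 0
  }
  refl <- function(i, n) { # 0-based symmetric mirror
    p <- i %% (2 * n)
    if (p < 0) p <- p + 2 * n
    if (p < n) p else 2 * n - 1 - p
  }
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, target_rows, target_cols)
  for (i in seq_len(target_rows)) {
    sy <- (i - 1 + 0.5) * nr / target_rows - 0.5
    by <- floor(sy)
    for (j in seq_len(target_cols)) {
      sx <- (j - 1 + 0.5) * nc / target_cols - 0.5
      bx <- floor(sx)
      acc <- 0
      for (ky in -1:2) {
        wy <- kern(sy - (by + ky))
        if (wy == 0) next
        ry <- refl(by + ky, nr) + 1
        for (kx in -1:2) {
          wx <- kern(sx - (bx + kx))
          if (wx == 0) next
          rx <- refl(bx + kx, nc) + 1
          acc <- acc + wy * wx * m[ry, rx]
        }
      }
      out[i, j] <- max(acc, 0)
    }
  }
  out
}

# exact two-sided rank-sum p via exhaustive label assignments, scored by
# the Mann-Whitney U statistic counted pairwise (ties count 1/2)
permutation_ranksum_p <- function(a, b) {
  u_stat <- function(x, y) {
    sum(outer(x, y, function(u, v) (u > v) + 0.5 * (u == v)))
  }
  pool <- c(a, b)
  na <- length(a)
  eu <- na * length(b) / 2
  d_obs <- abs(u_stat(a, b) - eu)
  splits <- utils::combn(length(pool), na)
  ds <- apply(splits, 2, function(ix) {
    abs(u_stat(pool[ix], pool[-ix]) - eu)
  })
  mean(ds >= d_obs - 1e-12)
}

# small scene spec sized for tests; keeps the 16 x 8 mm field of view
test_scene_spec <- function(seed, rows = 96, cols = 192, dot_count = 6,
                            speckle_cv = 0, ...) {
  scene_spec(image_rows = rows, image_cols = cols,
             dot_count = dot_count, speckle_cv = speckle_cv,
             seed = seed, ...)
}

# randomized integer-level noise-free spec for exact-equality checks
random_exact_spec <- function(seed) {
  set.seed(seed)
  aq <- sample(60:120, 1)
  cort <- aq + sample(1:30, 1)
  nuc <- cort + sample(0:40, 1)
  dot <- nuc + sample(5:60, 1)
  scene_spec(
    image_rows = sample(80:128, 1), image_cols = sample(160:256, 1),
    aqueous_level = aq, cortex_level = cort, nucleus_level = nuc,
    dot_level = dot, dot_count = sample(0:10, 1),
    dot_radius_px = c(1, 2), central_fraction = runif(1),
    speckle_cv = 0, seed = seed
  )
}
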