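make_seg <- function(n = 20) {
  aq <- matrix(FALSE, n, n); aq[1:5, ] <- TRUE
  nuc <- matrix(FALSE, n, n); nuc[9:12, 8:13] <- TRUE
  cort <- matrix(FALSE, n, n); cort[7:14, 5:16] <- TRUE
  cort[nuc] <- FALSE
  list(aq = aq, nuc = nuc, cort = cort)
}

test_that("segmentation validation enforces shape, disjointness, containment", {
  m <- make_seg()
  img <- bscan(matrix(100, 20, 20))
  seg <- lens_segmentation(m$aq, m$nuc, m$cort)
  expect_no_error(validate_segmentation(seg, img))

  bad_shape <- lens_segmentation(m$aq[1:10, ], m$nuc[1:10, ], m$cort[1:10, ])
  expect_error(validate_segmentation(bad_shape, img), "shape")

  overlap <- m$nuc; overlap[1, 1] <- TRUE # one aqueous pixel
  seg_ov <- lens_segmentation(m$aq, overlap, m$cort)
  expect_error(validate_segmentation(seg_ov, img), "aqueous.*nucleus")

  dots <- matrix(0L, 20, 20); dots[2, 2] <- 1L # on an aqueous pixel
  seg_dot <- lens_segmentation(m$aq, m$nuc, m$cort, dot_labels = dots)
  expect_error(validate_segmentation(seg_dot, img), "outside the lens")

  seg_axis <- lens_segmentation(m$aq, m$nuc, m$cort, lens_axis_col = 99)
  expect_error(validate_segmentation(seg_axis, img), "axis")
})

test_that("dot labelling matches a flood-fill oracle for both connectivities", {
  set.seed(21)
  for (rep in 1:8) {
    mask <- matrix(runif(18 * 18) < 0.25, 18, 18)
    for (conn in c(4, 8)) {
      got <- label_dots(mask, connectivity = conn, min_pixels = 1)
      oracle <- flood_fill_label(mask, connectivity = conn)
      expect_identical(nrow(got), max(oracle))
      # same partition: per-component pixel count multisets agree
      expect_identical(sort(got$pixel_count),
                       sort(as.integer(table(oracle[oracle > 0]))))
      # identical pixel partition, not just matching sizes
      labs <- attr(got, "labels")
      expect_identical(labs > 0L, oracle > 0L)
      expect_true(all(tapply(oracle[oracle > 0], labs[labs > 0],
                             function(v) length(unique(v))) == 1))
    }
  }
})

test_that("diagonal touching merges under 8- but not 4-connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_identical(nrow(label_dots(m, connectivity = 8, min_pixels = 1)), 1L)
  expect_identical(nrow(label_dots(m, connectivity = 4, min_pixels = 1)), 2L)
})

test_that("min_pixels filters small components and labels stay dense", {
  m <- matrix(FALSE, 10, 10)
  m[2, 2] <- TRUE                    # isolated single pixel
  m[5:6, 5:6] <- TRUE                # 4-pixel square
  m[9, 2:4] <- TRUE                  # 3-pixel line
  got <- label_dots(m, min_pixels = 2)
  expect_identical(nrow(got), 2L)
  expect_identical(got$label, 1:2)
  expect_setequal(got$pixel_count, c(4L, 3L))
  expect_identical(nrow(label_dots(m, min_pixels = 5)), 0L)
  # counted + discarded pixels account for every mask pixel
  kept <- sum(got$pixel_count)
  expect_identical(kept + 1L, sum(m))
})

test_that("dot centroids and offsets are reported in physical units", {
  m <- matrix(FALSE, 20, 40)
  m[10:11, 30:31] <- TRUE # centroid col 30.5
  img <- bscan(matrix(100, 20, 40), lateral_scale = 0.1, axial_scale = 0.2)
  got <- label_dots(m, image = img, lens_axis_col = 20)
  expect_equal(got$centroid_lateral_mm, (30.5 - 1) * 0.1)
  expect_equal(got$centroid_axial_mm, (10.5 - 1) * 0.2)
  expect_equal(got$lateral_offset_mm, abs(30.5 - 20) * 0.1)
  expect_equal(got$mean_intensity, 100)
})

test_that("central region mask follows the half-open physical window", {
  img <- bscan(matrix(0, 4, 1280), lateral_scale = 0.0125)
  m <- central_region_mask(img, lens_axis_col = 640, central_width_mm = 4)
  expect_identical(sum(m[1, ]), 320L) # 4.0 / 0.0125
  expect_true(all(colSums(m) %in% c(0L, 4L)))
  expect_identical(sum(central_region_mask(img, 640, 0)), 0L)
  wide <- central_region_mask(img, 640, 100)
  expect_true(all(wide))
  expect_error(central_region_mask(img, 2000, 4), "outside")
})

test_that("central masks are monotone in the window width", {
  img <- bscan(matrix(0, 2, 101), lateral_scale = 0.05)
  widths <- sort(runif(6, 0, 6))
  prev <- central_region_mask(img, 51, widths[1])
  for (w in widths[-1]) {
    cur <- central_region_mask(img, 51, w)
    expect_true(all(cur[prev])) # prev subset of cur
    prev <- cur
  }
})

test_that("detect_dots recovers bright blobs against a noisy cortex", {
  set.seed(5)
  px <- matrix(100 + rnorm(60 * 60, 0, 5), 60, 60)
  px[px < 0] <- 0
  cortex <- matrix(TRUE, 60, 60)
  px[20:22, 20:22] <- 160 # bright blob
  px[40:42, 40:42] <- 110 # below threshold
  img <- bscan(px)
  det <- detect_dots(img, cortex, k_sigma = 4, min_pixels = 2)
  expect_true(all(det[20:22, 20:22]))
  expect_false(any(det[40:42, 40:42]))

  uniform <- bscan(matrix(100, 30, 30))
  expect_identical(sum(detect_dots(uniform, matrix(TRUE, 30, 30))), 0L)
  expect_error(detect_dots(img, matrix(FALSE, 60, 60)), "no pixels")
})

test_that("detect_dots + label_dots recover generator truth on clean scenes", {
  for (seed in c(2, 13)) {
    sc <- generate_scene(test_scene_spec(seed, dot_count = 5))
    det <- detect_dots(sc$image, sc$truth$cortex_mask, k_sigma = 4,
                       min_pixels = 2)
    got <- label_dots(det, image = sc$image,
                      lens_axis_col = sc$truth$lens_axis_col)
    expect_identical(nrow(got), 5L)
    expect_identical(sort(got$pixel_count), sort(sc$dots$pixel_count))
  }
})

test_that("dot count is invariant under intensity rescaling of the image", {
  sc <- generate_scene(test_scene_spec(4, dot_count = 7))
  mask <- sc$truth$dot_labels > 0L
  n1 <- nrow(label_dots(mask, image = sc$image))
  scaled <- bscan(sc$image$pixels * 3.7)
  n2 <- nrow(label_dots(mask, image = scaled))
  expect_identical(n1, n2)
})
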