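test_that("scenes are bit-identical for a fixed seed", {
  s1 <- generate_scene(test_scene_spec(42, speckle_cv = 0.05))
  s2 <- generate_scene(test_scene_spec(42, speckle_cv = 0.05))
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$truth$dot_labels, s2$truth$dot_labels)
  expect_identical(s1$expected, s2$expected)
  s3 <- generate_scene(test_scene_spec(43, speckle_cv = 0.05))
  expect_false(identical(s1$image$pixels, s3$image$pixels))
})

test_that("generated truth always validates and dots land in the cortex", {
  for (seed in c(1, 2, 3, 14)) {
    sc <- generate_scene(test_scene_spec(seed, dot_count = seed + 2))
    expect_no_error(validate_segmentation(sc$truth, sc$image))
    expect_true(all(sc$truth$cortex_mask[sc$truth$dot_labels > 0L]))
  }
})

test_that("noise-free scenes reproduce their analytic expectations exactly", {
  sp <- scene_spec(image_rows = 120, image_cols = 240,
                   aqueous_level = 100, nucleus_level = 119,
                   cortex_level = 105, dot_count = 7, speckle_cv = 0,
                   seed = 77)
  sc <- generate_scene(sp)
  m <- quantify_eye(sc$image, sc$truth,
                    central_width_mm = sp$central_width_mm)
  expect_identical(m$nuclear_pir, 1.19)
  for (v in names(sc$expected)) {
    expect_identical(m[[v]], sc$expected[[v]])
  }
})

test_that("label_dots on truth recovers the constructed dot count", {
  sp <- test_scene_spec(6, rows = 128, cols = 256, dot_count = 15)
  sc <- generate_scene(sp)
  got <- label_dots(sc$truth$dot_labels > 0L, image = sc$image,
                    lens_axis_col = sc$truth$lens_axis_col)
  expect_identical(nrow(got), 15L)
  expect_identical(sort(got$pixel_count), sort(sc$dots$pixel_count))
})

test_that("recovered metrics converge to expectations as speckle shrinks", {
  errs <- vapply(c(0.2, 0.05, 0.0125), function(cv) {
    e <- vapply(1:5, function(s) {
      sc <- generate_scene(test_scene_spec(s, speckle_cv = cv))
      m <- quantify_eye(sc$image, sc$truth)
      abs(m$nuclear_pir - sc$expected$nuclear_pir)
    }, numeric(1))
    mean(e)
  }, numeric(1))
  expect_true(errs[2] < errs[1])
  expect_true(errs[3] < errs[2])
})

test_that("infeasible dot packings fail loudly", {
  sp <- test_scene_spec(1, rows = 80, cols = 160, dot_count = 400,
                        dot_radius_px = c(3, 3))
  expect_error(generate_scene(sp, max_tries = 20), "infeasible")
})

test_that("cohorts are deterministic, group-labelled and control-clean", {
  c1 <- generate_cohort(n_ds = 20, n_control = 15, seed = 5)
  c2 <- generate_cohort(n_ds = 20, n_control = 15, seed = 5)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_identical(nrow(c1), 35L)
  ct <- dplyr::filter(c1, group == "control")
  expect_true(all(ct$cortical_par == 0 & ct$psc_par == 0 & ct$dot_count == 0))
  expect_true(all(c1$age_years > 0))
  expect_no_error(validate_locs(c1))
})

test_that("dot prevalence in DS eyes is binomial around one half", {
  hits <- vapply(1:20, function(s) {
    co <- generate_cohort(n_ds = 54, n_control = 2, seed = s)
    sum(dplyr::filter(co, group == "DS")$dot_count > 0)
  }, numeric(1))
  # 99% binomial band for n = 54, p = 0.5 is roughly [18, 36]
  expect_true(all(hits >= qbinom(0.005, 54, 0.5) - 1))
  expect_true(all(hits <= qbinom(0.995, 54, 0.5) + 1))
  expect_gt(mean(hits) / 54, 0.40)
  expect_lt(mean(hits) / 54, 0.60)
})

test_that("age and nuclear PIR are positively associated in DS eyes", {
  pos <- vapply(1:20, function(s) {
    co <- generate_cohort(n_ds = 54, n_control = 2, seed = 100 + s)
    ds <- dplyr::filter(co, group == "DS")
    spearman_assoc(ds$age_years, ds$nuclear_pir)$rho > 0
  }, logical(1))
  expect_true(all(pos))
})

test_that("cohort records map to renderable, quantifiable scene specs", {
  co <- generate_cohort(n_ds = 6, n_control = 2, seed = 9)
  rec <- dplyr::filter(co, dot_count > 0, dot_count <= 12)[1, ]
  sp <- scene_spec_from_record(rec, image_rows = 96, image_cols = 192,
                               speckle_cv = 0)
  sc <- generate_scene(sp)
  m <- quantify_eye(sc$image, sc$truth,
                    central_width_mm = sp$central_width_mm)
  expect_equal(m$nuclear_pir, rec$nuclear_pir, tolerance = 1e-12)
  expect_equal(m$dot_pir, rec$dot_pir, tolerance = 1e-12)
  expect_identical(m$dot_count, rec$dot_count)
})

test_that("scene tidiers and plots expose the expected structure", {
  sc <- generate_scene(test_scene_spec(2, dot_count = 4))
  expect_identical(nrow(tidy(sc)), 10L)
  expect_identical(glance(sc)$seed, 2L)
  p1 <- ggplot2::autoplot(sc)
  expect_s3_class(p1, "ggplot")
  co <- generate_cohort(n_ds = 8, n_control = 8, seed = 2)
  p2 <- plot_cohort_variable(co, "nuclear_pir")
  expect_s3_class(p2, "ggplot")
  p3 <- plot_dot_profile(sc$dots)
  expect_s3_class(p3, "ggplot")
})
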