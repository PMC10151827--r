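# Cell segmentation, ridge QC and morphometry.

test_that("preprocessing leaves constant images unchanged on both paths", {
  flat <- matrix(0.5, 40, 40)
  expect_equal(preprocess(projection(flat, "apical", 1))$image, flat)
  expect_equal(preprocess(projection(flat, "basal", 1))$image, flat)
})

test_that("apical reconstruction filtering removes sub-element peaks", {
  img <- matrix(0.2, 40, 40)
  img[20, 20] <- 0.9
  out <- preprocess(projection(img, "apical", 1))$image
  expect_equal(out[20, 20], 0.2)
})

test_that("basal adaptive filter matches a direct local-statistics oracle", {
  set.seed(8)
  img <- matrix(0.4, 30, 30)
  img[10:20, 10:20] <- 0.7
  img <- img + matrix(rnorm(900, sd = 0.03), 30, 30)
  params <- segmentation_params("basal", wiener_window_px = 5L)
  out <- preprocess(projection(img, "basal", 1), params)$image
  # direct (slow) adaptive-Wiener oracle with replicated edges
  pad <- 2L
  padded <- img[pmin(pmax(seq_len(30 + 4) - pad, 1), 30),
                pmin(pmax(seq_len(30 + 4) - pad, 1), 30)]
  mu <- s2 <- matrix(0, 30, 30)
  for (r in 1:30) for (c in 1:30) {
    w <- padded[r:(r + 4), c:(c + 4)]
    mu[r, c] <- mean(w)
    s2[r, c] <- mean(w^2) - mean(w)^2
  }
  nu <- mean(s2)
  gain <- ifelse(s2 > nu, (s2 - nu) / s2, 0)
  oracle <- mu + gain * (img - mu)
  expect_equal(out, oracle, tolerance = 1e-10)
})

test_that("watershed recovers every cell of a noise-free boundary field", {
  cf <- generate_cell_field(cell_field_spec(fov_width_um = 200,
                                            fov_height_um = 150,
                                            n_cells = 50, rng_seed = 3))
  proj <- projection(cf$image, "apical", 1)
  lmap <- segment_cells(proj)
  expect_equal(max(lmap$labels), 50L)
  expect_identical(segment_cells(proj)$labels, lmap$labels)

  # independent route: h-maxima watershed from the imaging toolbox agrees
  inv <- max(cf$image) - cf$image
  ref <- EBImage::watershed(EBImage::Image(inv), tolerance = 0.1)
  expect_equal(max(ref), 50)
})

test_that("a uniform image degrades to a single label with a warning", {
  expect_warning(
    lm <- segment_cells(projection(matrix(0.3, 30, 30), "apical", 1)),
    "uniform")
  expect_true(all(lm$labels == 1L))
})

test_that("ridge QC dissolves exactly the failing boundaries", {
  fx <- quadrant_fixture(60, dim_ridge = 0.2)
  lmap <- cell_label_map(fx$labels, 1)
  proj <- projection(fx$image, "basal", 1)
  rt <- ujtmorph:::ridge_table(fx$labels, fx$image, 1)
  expect_equal(nrow(rt$table), 4L)
  expect_true(all(rt$table$tortuosity == 1))   # straight ridges exactly
  qc <- qc_boundaries(lmap, proj, segmentation_params("basal"))
  expect_equal(max(qc$labels), 3L)             # one merge, count -1

  # all-pass fixture: label map returned unchanged
  fx2 <- quadrant_fixture(60)
  lmap2 <- cell_label_map(fx2$labels, 1)
  qc2 <- qc_boundaries(lmap2, projection(fx2$image, "basal", 1),
                       segmentation_params("basal",
                                           qc_intensity_percentile = 0))
  expect_identical(qc2$labels, lmap2$labels)
})

test_that("QC and area filtering never increase the label count", {
  cf <- generate_cell_field(cell_field_spec(fov_width_um = 150,
                                            fov_height_um = 120,
                                            n_cells = 40, rng_seed = 9))
  proj <- projection(cf$image, "apical", 1)
  lmap <- segment_cells(proj)
  qc <- qc_boundaries(lmap, proj, segmentation_params("apical"))
  expect_lte(max(qc$labels), max(lmap$labels))
  af <- filter_by_area(qc, 50, 2000)
  expect_lte(max(af$labels), max(qc$labels))
})

test_that("area filtering removes only out-of-bounds cells", {
  labels <- matrix(0L, 40, 40)
  labels[2:21, 2:21] <- 1L       # 400 um2
  labels[30:31, 30:32] <- 2L     # 6 um2
  lmap <- cell_label_map(labels, 1)
  expect_identical(filter_by_area(lmap, 0, Inf)$labels, labels)
  small_gone <- filter_by_area(lmap, 50, Inf)
  expect_equal(max(small_gone$labels), 1L)
  expect_equal(sum(small_gone$labels == 1L), 400L)
  none <- filter_by_area(lmap, 1e5, Inf)
  expect_equal(max(none$labels), 0L)
  expect_equal(cell_morphology(none)$summary$n_cells, 0L)
})

test_that("ellipse-fit morphology matches closed-form oracles", {
  lab <- matrix(0L, 60, 80)
  lab[21:40, 21:60] <- 1L        # 40 x 20 px rectangle
  expect_equal(region_shape(lab, 1)$aspect_ratio, 2)

  n <- 50
  xx <- matrix(rep(1:n, each = n), n, n) - 25.5
  yy <- matrix(rep(1:n, times = n), n, n) - 25.5
  disk <- matrix(0L, n, n)
  disk[xx^2 + yy^2 <= 400] <- 1L
  expect_equal(region_shape(disk, 1)$aspect_ratio, 1, tolerance = 0.02)

  px <- matrix(0L, 5, 5); px[3, 3] <- 1L
  expect_equal(region_shape(px, 1)$aspect_ratio, 1)
})

test_that("density uses the field-of-view area in cells per mm2", {
  labels <- matrix(1L, 10, 10)
  labels[5, ] <- 0L
  labels[6:10, ] <- 2L
  lmap <- cell_label_map(labels, 1,
                         fov_width_um = 563, fov_height_um = 356)
  m <- cell_morphology(lmap)
  expect_equal(m$summary$n_cells, 2L)
  expect_equal(m$summary$density_per_mm2, 2 / (563 * 356 / 1e6),
               tolerance = 1e-9)
})

test_that("aspect ratio is invariant under rotation and pixel rescaling", {
  cf <- generate_cell_field(cell_field_spec(fov_width_um = 100,
                                            fov_height_um = 100,
                                            n_cells = 12, target_ar = 1.8,
                                            rng_seed = 13))
  ars <- region_shape(cf$truth$labels, 1)$aspect_ratio
  rot <- region_shape(t(cf$truth$labels)[ncol(cf$truth$labels):1, ],
                      1)$aspect_ratio
  expect_equal(sort(ars), sort(rot), tolerance = 1e-9)
  scaled <- region_shape(cf$truth$labels, 2.5)$aspect_ratio
  expect_equal(ars, scaled, tolerance = 1e-12)
  expect_true(all(ars >= 1))
  # summed cell areas never exceed the field area
  m <- cell_morphology(cell_label_map(cf$truth$labels, 1))
  expect_lte(sum(m$cells$area_um2), 100 * 100)
})
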