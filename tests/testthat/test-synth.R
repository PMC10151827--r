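# Synthetic generators: validation, determinism and ground-truth fidelity.

test_that("cell-field generation is deterministic and validates its spec", {
  expect_error(cell_field_spec(target_ar = 0.5), "target_ar")
  expect_error(cell_field_spec(boundary_intensity = 0.1,
                               background_intensity = 0.2), "exceed")
  expect_error(generate_cell_field(
    cell_field_spec(fov_width_um = 10, fov_height_um = 10, n_cells = 100)),
    "too large")
  spec <- cell_field_spec(fov_width_um = 80, fov_height_um = 80,
                          n_cells = 20, noise_sd = 0.05, rng_seed = 5)
  a <- generate_cell_field(spec)
  b <- generate_cell_field(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$labels, b$truth$labels)
})

test_that("a single cell covers the whole field of view", {
  cf <- generate_cell_field(cell_field_spec(fov_width_um = 40,
                                            fov_height_um = 30, n_cells = 1))
  expect_equal(sort(unique(as.vector(cf$truth$labels))), 1L)
  expect_equal(nrow(cf$truth$cells), 1L)
})

test_that("isotropic Voronoi cells are near-round by the moment oracle", {
  cf <- generate_cell_field(cell_field_spec(n_cells = 100, target_ar = 1,
                                            rng_seed = 7))
  ars <- oracle_ar(cf$truth$labels)
  expect_equal(length(ars), 100L)
  expect_gte(mean(ars), 1.0)
  expect_lte(mean(ars), 1.35)
  # the package's truth table agrees with the independent oracle
  expect_equal(cf$truth$cells$aspect_ratio, ars, tolerance = 1e-8)
})

test_that("mean true aspect ratio is monotone in target_ar", {
  means <- vapply(c(1, 1.5, 2, 3), function(ar) {
    cf <- generate_cell_field(cell_field_spec(n_cells = 100, target_ar = ar,
                                              rng_seed = 3))
    mean(cf$truth$cells$aspect_ratio)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("fiber-field truth records exact lengths and orientations", {
  spec <- fiber_field_spec(fov_width_um = 80, fov_height_um = 80,
                           n_fibers = 1, length_mean_um = 50,
                           length_sd_um = 0,
                           orientation_mode = "globally-aligned",
                           rng_seed = 2)
  ff <- generate_fiber_field(spec)
  expect_equal(ff$truth$fibers$length_um, 50)
  expect_equal(sum(ff$truth$fibers$length_um), 50)
  # globally aligned: zero circular variance of true orientations
  many <- generate_fiber_field(fiber_field_spec(
    n_fibers = 40, orientation_mode = "globally-aligned", rng_seed = 4))
  th <- many$truth$fibers$orientation_rad
  R <- sqrt(mean(cos(2 * th))^2 + mean(sin(2 * th))^2)
  expect_equal(R, 1, tolerance = 1e-12)
  # determinism
  expect_identical(generate_fiber_field(spec)$image, ff$image)
  expect_error(fiber_field_spec(fov_width_um = 30, fov_height_um = 30,
                                length_mean_um = 100), "diagonal")
})

test_that("patchwise truth alignment is +1 within and -1 across orthogonal
          patches in double-angle space", {
  po <- matrix(c(0, pi / 2), 1, 2)  # two patches forced orthogonal
  spec <- fiber_field_spec(fov_width_um = 60, fov_height_um = 30,
                           pixel_size_um = 0.25, n_fibers = 60,
                           length_mean_um = 3,
                           orientation_mode = "patchwise-aligned",
                           patch_size_um = 30, patch_orientations = po,
                           rng_seed = 6)
  ff <- generate_fiber_field(spec)
  f <- ff$truth$fibers
  left <- f$orientation_rad[f$midpoint_x_um < 30]
  right <- f$orientation_rad[f$midpoint_x_um >= 30]
  expect_gt(length(left), 5)
  expect_gt(length(right), 5)
  expect_equal(pairwise_alignment(left, left), 1, tolerance = 1e-9)
  expect_equal(pairwise_alignment(right, right), 1, tolerance = 1e-9)
  expect_equal(pairwise_alignment(left, right), -1, tolerance = 1e-9)
})

test_that("rendered fiber foreground scales linearly with truth length", {
  fg <- vapply(c(20, 40, 60), function(L) {
    ff <- generate_fiber_field(fiber_field_spec(
      fov_width_um = 100, fov_height_um = 100, n_fibers = 1,
      length_mean_um = L, length_sd_um = 0, rng_seed = 1))
    sum(ff$image > 0.45)
  }, numeric(1))
  # foreground ~ a + b * L: residual of the linear fit is small
  fit <- lm(fg ~ c(20, 40, 60))
  expect_lt(max(abs(residuals(fit))) / mean(fg), 0.02)
})

test_that("time-lapse generation matches its analytic truth", {
  st <- generate_timelapse(flow_spec("static", n_frames = 3))
  expect_identical(st$frames[, , 1], st$frames[, , 3])

  tr <- flow_spec("translation", speed_um_per_h = 4, n_frames = 16,
                  frame_interval_min = 6)
  tl <- generate_timelapse(tr)
  pts <- cbind(c(30, 64, 90), c(40, 64, 100))
  expect_equal(tl$truth$net_displacement_um(pts), rep(6, 3))

  rot <- generate_timelapse(flow_spec("rotation",
                                      angular_rate_rad_per_h = 0.2))
  p <- cbind(c(74, 84, 104), 64)   # 10, 20, 40 um from the centre
  sp <- rot$truth$speed(p)
  expect_equal(sp / c(10, 20, 40), rep(0.2, 3), tolerance = 1e-12)

  expect_error(flow_spec("translation", speed_um_per_h = 4000), "25%")
  expect_error(flow_spec("static", n_frames = 1), "n_frames")
})
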