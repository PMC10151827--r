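# Fiber tracing, fragment joining and length metrics.

test_that("boundary masking zeroes the dilated ridge band and tracks the
          searched area", {
  img <- matrix(0.5, 60, 60)
  proj <- projection(img, "fiber", 0.5)

  empty <- cell_label_map(matrix(0L, 60, 60), 0.5)
  m0 <- mask_cell_boundaries(proj, empty, 1.5)
  expect_equal(m0$image, img)
  expect_equal(sum(m0$excluded), 0L)

  labels <- matrix(1L, 60, 60)
  labels[30, ] <- 0L            # single straight ridge
  labels[31:60, ] <- 2L
  lmap <- cell_label_map(labels, 0.5)
  m1 <- mask_cell_boundaries(proj, lmap, 1.5)   # 1.5 um at 0.5 um/px = 3 px
  expect_equal(sum(m1$excluded), 3L * 60L)
  expect_true(all(m1$image[29:31, ] == 0))
  m2 <- mask_cell_boundaries(m1, lmap, 1.5)     # idempotent
  expect_identical(m2$image, m1$image)
  expect_identical(m2$excluded, m1$excluded)
})

test_that("a single straight fiber traces as one full-length fragment", {
  spec <- fiber_field_spec(fov_width_um = 80, fov_height_um = 80,
                           pixel_size_um = 0.25, n_fibers = 1,
                           length_mean_um = 50, length_sd_um = 0,
                           orientation_mode = "globally-aligned",
                           rng_seed = 2)
  ff <- generate_fiber_field(spec)
  frags <- trace_fragments(projection(ff$image, "fiber", 0.25))
  expect_length(frags, 1L)
  expect_equal(frags[[1]]$length_um, 50, tolerance = 1 / 50)
})

test_that("crossing fibers trace as two fragments, not four arms", {
  px <- 0.25
  img <- blank_image(320)
  c0 <- 40; L <- 40; ang <- pi / 4
  img <- draw_segment(img, c0 - L / 2 * cos(ang), c0 - L / 2 * sin(ang),
                      c0 + L / 2 * cos(ang), c0 + L / 2 * sin(ang), px)
  img <- draw_segment(img, c0 - L / 2 * cos(ang), c0 + L / 2 * sin(ang),
                      c0 + L / 2 * cos(ang), c0 - L / 2 * sin(ang), px)
  frags <- trace_fragments(projection(img, "fiber", px))
  expect_length(frags, 2L)
  lens <- sort(vapply(frags, `[[`, 0, "length_um"))
  expect_true(all(abs(lens - L) / L < 0.05))
})

test_that("blank images yield no fragments", {
  expect_length(trace_fragments(projection(blank_image(80), "fiber", 0.25)),
                0L)
})

test_that("joining respects gap, orientation and intensity continuity", {
  px <- 0.25
  base <- blank_image(320)
  base <- draw_segment(base, 20, 40, 30, 40, px)
  base <- draw_segment(base, 32, 40, 42, 40, px)

  # dark connector: geometry fine, intensity constraint rejects
  pd <- projection(base, "fiber", px)
  fd <- trace_fragments(pd)
  expect_length(fd, 2L)
  expect_equal(join_fragments(fd, pd)$n, 2L)
  # ... and with the intensity constraint disabled the same pair joins,
  # proving intensity was the decisive check
  loose <- join_params(intensity_ratio = 0.01)
  expect_equal(join_fragments(fd, pd, loose)$n, 1L)

  # bright connector: joined into one fiber whose length spans the gap
  bright <- draw_segment(base, 30, 40, 32, 40, px)
  pb <- projection(bright, "fiber", px)
  fb <- trace_fragments(pb)
  fsb <- join_fragments(fb, pb)
  expect_equal(fsb$n, 1L)
  expect_equal(fsb$fibers[[1]]$length_um, 22, tolerance = 0.05)

  # perpendicular nearby fragments: orientation constraint rejects
  perp <- blank_image(320)
  perp <- draw_segment(perp, 20, 40, 30, 40, px)
  perp <- draw_segment(perp, 32, 42, 32, 52, px)
  pp <- projection(perp, "fiber", px)
  expect_equal(join_fragments(trace_fragments(pp), pp)$n, 2L)
})

test_that("joining conserves fragment length and ignores order", {
  px <- 0.25
  img <- blank_image(320)
  img <- draw_segment(img, 20, 40, 30, 40, px)
  img <- draw_segment(img, 31.5, 40, 41.5, 40, px)
  img <- draw_segment(img, 30, 40, 31.5, 40, px)
  pj <- projection(img, "fiber", px)
  frags <- trace_fragments(pj)
  fs1 <- join_fragments(frags, pj)
  fs2 <- join_fragments(rev(frags), pj)
  tot1 <- sum(vapply(fs1$fibers, `[[`, 0, "length_um"))
  in_sum <- sum(vapply(frags, `[[`, 0, "length_um"))
  expect_gte(tot1 + 1e-9, in_sum)
  expect_equal(fs1$n, fs2$n)
  expect_equal(sort(vapply(fs1$fibers, `[[`, 0, "length_um")),
               sort(vapply(fs2$fibers, `[[`, 0, "length_um")),
               tolerance = 1e-9)
})

test_that("length metrics follow their definitions", {
  fs <- fiber_set(list(list(points_um = cbind(c(0, 3), c(0, 0)),
                            length_um = 3),
                       list(points_um = cbind(c(0, 5), c(1, 1)),
                            length_um = 5)),
                  searched_area_um2 = 100)
  lm <- length_metrics(fs)
  expect_equal(lm$mean_length_um, 4)
  expect_equal(lm$total_length_density_per_um, 0.08)

  empty <- fiber_set(list(), 100)
  expect_true(is.na(length_metrics(empty)$mean_length_um))
  expect_equal(length_metrics(empty)$total_length_density_per_um, 0)
  expect_error(length_metrics(fiber_set(list(), 0)), "positive")
})

test_that("fiber recovery on a dense synthetic field stays within 10%", {
  spec <- fiber_field_spec(rng_seed = 11)   # 200 fibers, truth mean 3 um
  ff <- generate_fiber_field(spec)
  proj <- projection(ff$image, "fiber", spec$pixel_size_um)
  fs <- join_fragments(trace_fragments(proj), proj)
  truth_mean <- mean(ff$truth$fibers$length_um)
  truth_den <- sum(ff$truth$fibers$length_um) /
    (spec$fov_width_um * spec$fov_height_um)
  expect_within(fs$mean_length_um, truth_mean, 0.10)
  expect_within(fs$total_length_density_per_um, truth_den, 0.10)
})
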