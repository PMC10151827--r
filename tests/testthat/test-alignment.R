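# Orientation fields and the alignment-versus-distance statistic.

test_that("structure tensor recovers the stripe orientation", {
  px <- 0.5; n <- 240
  xx <- matrix(rep(seq_len(n) - 0.5, each = n), n, n)
  yy <- matrix(rep(seq_len(n) - 0.5, times = n), n, n)
  th <- 30 * pi / 180
  img <- 0.5 + 0.4 * sin((-xx * sin(th) + yy * cos(th)) * 2 * pi / 16)
  of <- orientation_field(projection(img, "fiber", px), subregion_um = 3,
                          intensity_percentile = 0)
  errs <- ujtmorph:::axial_diff(of$theta[of$valid], th) * 180 / pi
  expect_gt(sum(of$valid), 100)
  expect_lt(max(errs), 2)

  # axial equivalence: stripes at theta and theta + 180 deg are identical
  img2 <- 0.5 + 0.4 * sin((-xx * sin(th + pi) + yy * cos(th + pi)) *
                            2 * pi / 16)
  of2 <- orientation_field(projection(img2, "fiber", px), 3, 0)
  expect_lt(max(ujtmorph:::axial_diff(of2$theta[of2$valid], th)) * 180 / pi,
            2)
})

test_that("constant images have no valid subregions", {
  of <- orientation_field(projection(matrix(0.5, 60, 60), "fiber", 0.5))
  expect_equal(sum(of$valid), 0L)
  expect_error(alignment_auc(of), "valid subregions")
  expect_error(orientation_field(projection(matrix(0.5, 4, 4), "fiber", 1),
                                 subregion_um = 50), "larger")
})

test_that("excluded-region and percentile masking invalidate subregions", {
  # dim band covers 30% of the field (below the 35th percentile of block
  # means); the bright remainder carries oriented texture
  img <- 0.8 + 0.1 * sin(matrix(rep(seq_len(120) / 2, times = 120), 120))
  img[, 1:36] <- 0.1
  excl <- matrix(FALSE, 120, 120)
  excl[109:120, 109:120] <- TRUE
  of <- orientation_field(projection(img, "fiber", 0.5, excluded = excl),
                          subregion_um = 3, intensity_percentile = 35)
  expect_false(any(of$valid[19:20, 19:20]))      # excluded blocks
  expect_false(any(of$valid[, 1:6]))             # dim band below percentile
  expect_gt(sum(of$valid), 50)                   # bright half mostly valid
})

test_that("identical orientations give exactly zero alignment AUC", {
  f <- orientation_field_grid(matrix(0.7, 15, 15), matrix(TRUE, 15, 15),
                              (1:15) * 3 - 1.5, (1:15) * 3 - 1.5, 3)
  a <- alignment_auc(f, 1, 30, 5, rng_seed = 1)
  expect_equal(a$auc, 0)
  expect_true(all(abs(a$experimental[a$n_pairs > 0] - 1) < 1e-12))
})

test_that("i.i.d. orientations give AUC within repositioning noise", {
  set.seed(4)
  f <- orientation_field_grid(matrix(runif(400, 0, pi), 20, 20),
                              matrix(TRUE, 20, 20),
                              (1:20) * 3 - 1.5, (1:20) * 3 - 1.5, 3)
  a <- alignment_auc(f, 1, 30, 20, rng_seed = 1)
  expect_lt(abs(a$auc), 3 * a$null_auc_sd)
})

test_that("alignment values stay in [-1, 1] and AUC is rotation-invariant", {
  set.seed(6)
  th <- matrix(runif(225, 0, pi), 15, 15)
  f <- orientation_field_grid(th, matrix(TRUE, 15, 15),
                              (1:15) * 3 - 1.5, (1:15) * 3 - 1.5, 3)
  a <- alignment_auc(f, 1, 20, 10, rng_seed = 3)
  ok <- a$n_pairs > 0
  expect_true(all(a$experimental[ok] >= -1 & a$experimental[ok] <= 1))
  g <- orientation_field_grid(th + 1.1, matrix(TRUE, 15, 15),
                              (1:15) * 3 - 1.5, (1:15) * 3 - 1.5, 3)
  b <- alignment_auc(g, 1, 20, 10, rng_seed = 3)
  expect_equal(a$auc, b$auc, tolerance = 1e-9)
})

test_that("patchwise-aligned fields beat their shuffled counterparts", {
  sp <- fiber_field_spec(fov_width_um = 120, fov_height_um = 120,
                         pixel_size_um = 0.25, n_fibers = 500,
                         length_mean_um = 5, length_sd_um = 1,
                         orientation_mode = "patchwise-aligned",
                         patch_size_um = 30, rng_seed = 9)
  ff <- generate_fiber_field(sp)
  of <- orientation_field(projection(ff$image, "fiber", 0.25), 3, 35)
  a <- alignment_auc(of, 1, 50, 20, rng_seed = 2)
  shuf <- of
  set.seed(5)
  shuf$theta[shuf$valid] <- sample(of$theta[of$valid])
  b <- alignment_auc(shuf, 1, 50, 20, rng_seed = 2)
  expect_gt(a$auc, b$auc)
  expect_gt(a$auc, 1)      # strong local alignment signal
  expect_lt(abs(b$auc), 3 * b$null_auc_sd)

  # truth-based field from generator internals agrees in sign and scale
  tf <- truth_orientation_field(ff, 3)
  at <- alignment_auc(tf, 1, 50, 10, rng_seed = 2)
  expect_gt(at$auc, 1)
})
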