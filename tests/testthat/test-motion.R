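# Dense optical flow, trajectory integration and migration speed.

test_that("identical frames give near-zero flow", {
  tl <- generate_timelapse(flow_spec("static", n_frames = 2))
  fl <- compute_flow(tl)
  expect_lt(max(abs(fl$u)) / tl$pixel_size_um, 0.05)
  expect_lt(max(abs(fl$v)) / tl$pixel_size_um, 0.05)
})

test_that("synthetic translation is recovered to sub-pixel accuracy", {
  # 10 um/h at 6 min = 1 um/frame = 2 px/frame at 0.5 um/px
  tl <- generate_timelapse(flow_spec("translation", speed_um_per_h = 10,
                                     direction_deg = 25, n_frames = 2))
  fl <- compute_flow(tl)
  n <- dim(fl$u)[1]
  int <- ceiling(n * 0.1):floor(n * 0.9)
  mag <- sqrt(fl$u[int, int, 1]^2 + fl$v[int, int, 1]^2) / tl$pixel_size_um
  expect_lt(abs(median(mag) - 2), 0.2)
})

test_that("reversed frame order negates the flow", {
  tl <- generate_timelapse(flow_spec("translation", speed_um_per_h = 10,
                                     n_frames = 2))
  fwd <- compute_flow(tl)
  rev_tl <- list(frames = tl$frames[, , 2:1],
                 pixel_size_um = tl$pixel_size_um,
                 frame_interval_min = tl$frame_interval_min)
  bwd <- compute_flow(rev_tl)
  n <- dim(fwd$u)[1]
  int <- ceiling(n * 0.1):floor(n * 0.9)
  resid <- abs(fwd$u[int, int, 1] + bwd$u[int, int, 1]) / tl$pixel_size_um
  expect_lt(mean(resid), 0.3)
})

test_that("flow errors are rejected early", {
  expect_error(compute_flow(list(frames = array(0, c(8, 8, 1)),
                                 pixel_size_um = 1,
                                 frame_interval_min = 6)), "2 frames")
})

test_that("trajectory integration follows the flow field definitions", {
  zero <- structure(list(u = array(0, c(40, 40, 3)),
                         v = array(0, c(40, 40, 3)),
                         pixel_size_um = 1, frame_interval_min = 30,
                         fov_width_um = 40, fov_height_um = 40),
                    class = "FlowField")
  tr <- integrate_trajectories(zero, 10)
  expect_true(all(tr$speed_um_per_h == 0))
  expect_true(all(tr$retained))

  # uniform 6 um net translation over 1.5 h: every speed exactly 4 um/h
  upf <- 6 / 15
  uni <- structure(list(u = array(upf, c(200, 200, 15)),
                        v = array(0, c(200, 200, 15)),
                        pixel_size_um = 1, frame_interval_min = 6,
                        fov_width_um = 200, fov_height_um = 200),
                   class = "FlowField")
  tru <- integrate_trajectories(uni, 20)
  expect_equal(unique(round(tru$speed_um_per_h[tru$retained], 10)), 4)
})

test_that("net displacement, not path length, defines speed", {
  pos <- array(0, c(1, 16, 2))
  pos[1, , 1] <- 50 + 10 * sin(seq(0, 2 * pi, length.out = 16))
  pos[1, , 2] <- 50 + 10 * (cos(seq(0, 2 * pi, length.out = 16)) - 1)
  traj <- structure(list(seeds_um = cbind(50, 50), positions_um = pos,
                         net_displacement_um = 0, speed_um_per_h = 0,
                         path_length_um = sum(sqrt(diff(pos[1, , 1])^2 +
                                                   diff(pos[1, , 2])^2)),
                         retained = TRUE, elapsed_h = 1.5),
                    class = "TrajectorySet")
  expect_equal(mean_speed(traj), 0)
  expect_gt(mean_speed(traj, "path"), 0)

  two <- structure(list(seeds_um = cbind(c(10, 20), c(10, 20)),
                        positions_um = NULL,
                        net_displacement_um = c(0, 6),
                        speed_um_per_h = c(0, 4),
                        path_length_um = c(0, 6),
                        retained = c(TRUE, TRUE), elapsed_h = 1.5),
                   class = "TrajectorySet")
  expect_equal(mean_speed(two), 2)
  none <- two; none$retained <- c(FALSE, FALSE)
  expect_error(mean_speed(none), "excluded")
})

test_that("rigid-rotation speeds track omega times radius", {
  tl <- generate_timelapse(flow_spec("rotation",
                                     angular_rate_rad_per_h = 0.15))
  traj <- integrate_trajectories(compute_flow(tl), 10)
  truth <- tl$truth$speed(traj$seeds_um)
  ok <- traj$retained & truth > 2
  rel <- abs(traj$speed_um_per_h[ok] - truth[ok]) / truth[ok]
  expect_lt(max(rel), 0.10)
})
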