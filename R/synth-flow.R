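#' Specify a synthetic time-lapse sequence
#'
#' Describes a phase-contrast-like time-lapse created by advecting a fixed
#' random texture with an analytic flow field. Supported flows: `static`
#' (no motion), `translation` (uniform velocity), `rotation` (rigid rotation
#' about the field centre), and `swirl` (rotation whose angular rate decays
#' with radius, mimicking the swirling migration patterns of unjammed
#' epithelium). Because all supported flows are circular or uniform, the
#' backward advection map is closed-form and frames are rendered exactly.
#'
#' @param flow_kind one of `"static"`, `"translation"`, `"rotation"`,
#'   `"swirl"`.
#' @param fov_width_um,fov_height_um,pixel_size_um field geometry.
#' @param n_frames number of frames (>= 2).
#' @param frame_interval_min minutes between frames.
#' @param speed_um_per_h translation speed (micrometres/hour).
#' @param direction_deg translation direction (degrees, 0 = +x).
#' @param angular_rate_rad_per_h rotation/swirl angular rate (radians/hour).
#' @param swirl_radius_um e-folding radius of the swirl's angular-rate decay.
#' @param texture_blur_px Gaussian blur s.d. (pixels) of the random texture.
#' @param texture_seed,rng_seed integer seeds (texture is drawn from
#'   `texture_seed` so different flows can share one texture).
#' @return A `FlowSpec` object.
#' @export
flow_spec <- function(flow_kind = c("static", "translation", "rotation",
                                    "swirl"),
                      fov_width_um = 128, fov_height_um = 128,
                      pixel_size_um = 0.5, n_frames = 16,
                      frame_interval_min = 6, speed_um_per_h = 4,
                      direction_deg = 0, angular_rate_rad_per_h = 0.1,
                      swirl_radius_um = NULL, texture_blur_px = 2,
                      texture_seed = 99L, rng_seed = 1L) {
  flow_kind <- match.arg(flow_kind)
  stopifnot_scalar(frame_interval_min, "frame_interval_min")
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (is.null(swirl_radius_um))
    swirl_radius_um <- min(fov_width_um, fov_height_um) / 4
  sp <- structure(list(flow_kind = flow_kind, fov_width_um = fov_width_um,
                       fov_height_um = fov_height_um,
                       pixel_size_um = pixel_size_um,
                       n_frames = as.integer(n_frames),
                       frame_interval_min = frame_interval_min,
                       speed_um_per_h = speed_um_per_h,
                       direction_deg = direction_deg,
                       angular_rate_rad_per_h = angular_rate_rad_per_h,
                       swirl_radius_um = swirl_radius_um,
                       texture_blur_px = texture_blur_px,
                       texture_seed = as.integer(texture_seed),
                       rng_seed = as.integer(rng_seed)),
                  class = "FlowSpec")
  # reject displacements unrecoverable by flow estimation
  dt_h <- frame_interval_min / 60
  step_um <- switch(flow_kind,
    static = 0,
    translation = abs(speed_um_per_h) * dt_h,
    rotation = ,
    swirl = abs(angular_rate_rad_per_h) * dt_h *
      sqrt(fov_width_um^2 + fov_height_um^2) / 2)
  if (step_um > 0.25 * min(fov_width_um, fov_height_um))
    stop("per-frame displacement exceeds 25% of the field of view")
  sp
}

# Backward map: positions (x, y) in um at elapsed time t_h mapped to their
# location at time 0. `pts` is an n x 2 matrix.
.advect_back <- function(spec, pts, t_h) .advect(spec, pts, -t_h)

# Forward analytic advection by t_h hours.
.advect <- function(spec, pts, t_h) {
  cx <- spec$fov_width_um / 2; cy <- spec$fov_height_um / 2
  switch(spec$flow_kind,
    static = pts,
    translation = {
      a <- spec$direction_deg * pi / 180
      v <- spec$speed_um_per_h
      cbind(pts[, 1] + v * cos(a) * t_h, pts[, 2] + v * sin(a) * t_h)
    },
    rotation = {
      ang <- spec$angular_rate_rad_per_h * t_h
      dx <- pts[, 1] - cx; dy <- pts[, 2] - cy
      cbind(cx + dx * cos(ang) - dy * sin(ang),
            cy + dx * sin(ang) + dy * cos(ang))
    },
    swirl = {
      dx <- pts[, 1] - cx; dy <- pts[, 2] - cy
      r2 <- dx^2 + dy^2
      # angular rate depends only on radius, which the flow preserves,
      # so rotation by the accumulated angle is exact
      ang <- spec$angular_rate_rad_per_h *
        exp(-r2 / (2 * spec$swirl_radius_um^2)) * t_h
      cbind(cx + dx * cos(ang) - dy * sin(ang),
            cy + dx * sin(ang) + dy * cos(ang))
    })
}

# Analytic speed magnitude (um/h) at positions `pts`.
.analytic_speed <- function(spec, pts) {
  cx <- spec$fov_width_um / 2; cy <- spec$fov_height_um / 2
  switch(spec$flow_kind,
    static = rep(0, nrow(pts)),
    translation = rep(abs(spec$speed_um_per_h), nrow(pts)),
    rotation = {
      r <- sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2)
      abs(spec$angular_rate_rad_per_h) * r
    },
    swirl = {
      r <- sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2)
      abs(spec$angular_rate_rad_per_h) *
        exp(-r^2 / (2 * spec$swirl_radius_um^2)) * r
    })
}

#' Generate a synthetic time-lapse with analytic ground truth
#'
#' @param spec a [flow_spec()].
#' @return A list with `frames` (3D array \[y, x, frame\]), `pixel_size_um`,
#'   `frame_interval_min`, `truth` (list of functions: `positions(pts, t_min)`
#'   advects micrometre points forward analytically, `speed(pts)` gives the
#'   analytic speed field in um/h; plus `net_displacement_um(pts)` over the
#'   whole sequence), and `spec`.
#' @export
generate_timelapse <- function(spec) {
  stopifnot(inherits(spec, "FlowSpec"))
  px <- spec$pixel_size_um
  nx <- max(2L, round(spec$fov_width_um / px))
  ny <- max(2L, round(spec$fov_height_um / px))
  tex <- NULL
  with_seed(spec$texture_seed, {
    tex <- matrix(runif(ny * nx), ny, nx)
    tex <- sep_conv(tex, gauss_kernel(spec$texture_blur_px))
    tex <- 0.15 + 0.7 * (tex - min(tex)) / (max(tex) - min(tex))
  })
  dt_h <- spec$frame_interval_min / 60
  frames <- array(0, dim = c(ny, nx, spec$n_frames))
  pxx <- rep((seq_len(nx) - 0.5) * px, each = ny)
  pyy <- rep((seq_len(ny) - 0.5) * px, times = nx)
  pts <- cbind(pxx, pyy)
  for (k in seq_len(spec$n_frames)) {
    if (spec$flow_kind == "static" || k == 1L) {
      frames[, , k] <- tex
    } else {
      p0 <- .advect_back(spec, pts, (k - 1) * dt_h)
      frames[, , k] <- matrix(
        bilinear(tex, p0[, 2] / px + 0.5, p0[, 1] / px + 0.5), ny, nx)
    }
  }
  total_h <- (spec$n_frames - 1) * dt_h
  truth <- list(
    positions = function(pts, t_min) .advect(spec, pts, t_min / 60),
    speed = function(pts) .analytic_speed(spec, pts),
    net_displacement_um = function(pts) {
      p1 <- .advect(spec, pts, total_h)
      sqrt(rowSums((p1 - pts)^2))
    })
  structure(list(frames = frames, pixel_size_um = px,
                 frame_interval_min = spec$frame_interval_min,
                 truth = truth, spec = spec),
            class = "Timelapse")
}
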