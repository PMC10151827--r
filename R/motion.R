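# Collective migration speed from dense optical flow.
#
# Flow between consecutive frames is estimated with polynomial-expansion
# (Farneback) optical flow: every neighbourhood of each frame is
# approximated by a quadratic polynomial under Gaussian weighting, and the
# displacement field follows from how the expansion coefficients shift
# between frames, aggregated over a Gaussian integration window, refined
# iteratively over an image pyramid.

#' Optical-flow parameters
#'
#' @param poly_sigma Gaussian applicability s.d. (pixels) of the polynomial
#'   expansion.
#' @param win_sigma Gaussian s.d. (pixels) of the displacement integration
#'   window.
#' @param iterations refinement iterations per pyramid level.
#' @param pyr_levels number of pyramid levels (1 = no pyramid).
#' @return A `FlowParams` object.
#' @export
flow_params <- function(poly_sigma = 1.5, win_sigma = 6, iterations = 3L,
                        pyr_levels = 3L) {
  structure(list(poly_sigma = poly_sigma, win_sigma = win_sigma,
                 iterations = as.integer(iterations),
                 pyr_levels = as.integer(pyr_levels)), class = "FlowParams")
}

# Quadratic polynomial expansion of an image under Gaussian applicability.
# Returns list of coefficient matrices: c, bx, by, axx, ayy, axy for the
# local model f ~ c + bx*x + by*y + axx*x^2 + ayy*y^2 + axy*x*y
# (x = column offset, y = row offset).
poly_expansion <- function(img, sigma) {
  radius <- ceiling(3 * sigma)
  t <- seq(-radius, radius)
  g <- exp(-t^2 / (2 * sigma^2))
  # 1D moment kernels (correlation form: value at offset t is weight for
  # the pixel at +t, so kernels are used unflipped with symmetric g)
  g0 <- g; g1 <- g * t; g2 <- g * t^2
  cor1 <- function(m, k, along) {
    h <- radius
    out <- matrix(0, nrow(m), ncol(m))
    if (along == "x") {
      idx <- seq_len(ncol(m))
      for (j in seq_along(k)) {
        off <- j - 1L - h
        cols <- pmin(pmax(idx + off, 1L), ncol(m))
        out <- out + k[j] * m[, cols, drop = FALSE]
      }
    } else {
      idx <- seq_len(nrow(m))
      for (j in seq_along(k)) {
        off <- j - 1L - h
        rows <- pmin(pmax(idx + off, 1L), nrow(m))
        out <- out + k[j] * m[rows, , drop = FALSE]
      }
    }
    out
  }
  # separable moment images m_ij = sum w * f(p+d) * x^i * y^j
  fy0 <- list(cor1(img, g0, "y"), cor1(img, g1, "y"), cor1(img, g2, "y"))
  m00 <- cor1(fy0[[1]], g0, "x"); m10 <- cor1(fy0[[1]], g1, "x")
  m20 <- cor1(fy0[[1]], g2, "x")
  m01 <- cor1(fy0[[2]], g0, "x"); m11 <- cor1(fy0[[2]], g1, "x")
  m02 <- cor1(fy0[[3]], g0, "x")
  # Gram matrix of the basis (1, x, y, x^2, y^2, xy) under w, from the
  # separable Gaussian moments
  s0 <- sum(g); s2 <- sum(g * t^2); s4 <- sum(g * t^4)
  G <- matrix(0, 6, 6)
  G[1, 1] <- s0 * s0
  G[1, 4] <- G[4, 1] <- s2 * s0
  G[1, 5] <- G[5, 1] <- s0 * s2
  G[2, 2] <- s2 * s0
  G[3, 3] <- s0 * s2
  G[4, 4] <- s4 * s0
  G[5, 5] <- s0 * s4
  G[4, 5] <- G[5, 4] <- s2 * s2
  G[6, 6] <- s2 * s2
  Ginv <- solve(G)
  # r = Ginv %*% (m00, m10, m01, m20, m02, m11) per pixel; exploit sparsity
  r1 <- Ginv[1, 1] * m00 + Ginv[1, 4] * m20 + Ginv[1, 5] * m02
  r2 <- Ginv[2, 2] * m10
  r3 <- Ginv[3, 3] * m01
  r4 <- Ginv[4, 1] * m00 + Ginv[4, 4] * m20 + Ginv[4, 5] * m02
  r5 <- Ginv[5, 1] * m00 + Ginv[5, 4] * m20 + Ginv[5, 5] * m02
  r6 <- Ginv[6, 6] * m11
  list(c = r1, bx = r2, by = r3, axx = r4, ayy = r5, axy = r6)
}

# Warp an image by sampling at (x + u, y + v) bilinearly.
warp_image <- function(img, u, v) {
  nr <- nrow(img); nc <- ncol(img)
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  rr <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  matrix(bilinear(img, as.vector(rr + v), as.vector(cc + u)), nr, nc)
}

# Single-level Farneback displacement update given a prior flow (u0, v0).
flow_update <- function(f1, f2, u0, v0, params) {
  p1 <- poly_expansion(f1, params$poly_sigma)
  f2w <- warp_image(f2, u0, v0)
  p2 <- poly_expansion(f2w, params$poly_sigma)
  # local quadratic models: A = [[axx, axy/2], [axy/2, ayy]], b = (bx, by)
  a11 <- (p1$axx + p2$axx) / 2
  a22 <- (p1$ayy + p2$ayy) / 2
  a12 <- (p1$axy + p2$axy) / 4
  db_x <- -(p2$bx - p1$bx) / 2
  db_y <- -(p2$by - p1$by) / 2
  # normal equations, integrated over a Gaussian window
  gxx <- a11 * a11 + a12 * a12
  gxy <- a12 * (a11 + a22)
  gyy <- a22 * a22 + a12 * a12
  hx <- a11 * db_x + a12 * db_y
  hy <- a12 * db_x + a22 * db_y
  k <- gauss_kernel(params$win_sigma)
  gxx <- sep_conv(gxx, k); gxy <- sep_conv(gxy, k); gyy <- sep_conv(gyy, k)
  hx <- sep_conv(hx, k); hy <- sep_conv(hy, k)
  det <- gxx * gyy - gxy * gxy
  det[abs(det) < 1e-12] <- Inf
  du <- (gyy * hx - gxy * hy) / det
  dv <- (gxx * hy - gxy * hx) / det
  list(u = u0 + du, v = v0 + dv)
}

# Dense flow between one frame pair (pixels/frame).
farneback_pair <- function(f1, f2, params) {
  levels <- params$pyr_levels
  pyr1 <- list(f1); pyr2 <- list(f2)
  for (l in seq_len(levels - 1L)) {
    if (min(dim(pyr1[[l]])) < 24L) { levels <- l; break }
    pyr1[[l + 1L]] <- eb_mat(EBImage::resize(pyr1[[l]],
                                             w = nrow(pyr1[[l]]) %/% 2L,
                                             h = ncol(pyr1[[l]]) %/% 2L))
    pyr2[[l + 1L]] <- eb_mat(EBImage::resize(pyr2[[l]],
                                             w = nrow(pyr2[[l]]) %/% 2L,
                                             h = ncol(pyr2[[l]]) %/% 2L))
  }
  u <- matrix(0, nrow(pyr1[[levels]]), ncol(pyr1[[levels]]))
  v <- u
  for (l in rev(seq_len(levels))) {
    if (l < levels) {
      u <- 2 * eb_mat(EBImage::resize(u, w = nrow(pyr1[[l]]),
                                      h = ncol(pyr1[[l]])))
      v <- 2 * eb_mat(EBImage::resize(v, w = nrow(pyr1[[l]]),
                                      h = ncol(pyr1[[l]])))
    }
    for (it in seq_len(params$iterations)) {
      fl <- flow_update(pyr1[[l]], pyr2[[l]], u, v, params)
      u <- fl$u; v <- fl$v
    }
  }
  list(u = u, v = v)
}

#' Dense optical flow of a time-lapse
#'
#' Computes polynomial-expansion dense optical flow between each pair of
#' consecutive frames; displacements are converted to micrometres per frame
#' interval via the pixel size.
#'
#' @param tl a `Timelapse` (from [generate_timelapse()]) or list with
#'   `frames` (3D array \[y, x, t\]), `pixel_size_um`, `frame_interval_min`.
#' @param params a [flow_params()].
#' @return A `FlowField`: list with `u`, `v` (3D arrays \[y, x, pair\], in
#'   micrometres per frame interval), `pixel_size_um`,
#'   `frame_interval_min`.
#' @export
compute_flow <- function(tl, params = flow_params()) {
  frames <- tl$frames
  if (length(dim(frames)) != 3L || dim(frames)[3] < 2L)
    stop("need at least 2 frames of identical shape")
  nt <- dim(frames)[3]
  u <- array(0, dim = c(dim(frames)[1:2], nt - 1L))
  v <- u
  for (k in seq_len(nt - 1L)) {
    fl <- farneback_pair(frames[, , k], frames[, , k + 1L], params)
    u[, , k] <- fl$u * tl$pixel_size_um
    v[, , k] <- fl$v * tl$pixel_size_um
  }
  structure(list(u = u, v = v, pixel_size_um = tl$pixel_size_um,
                 frame_interval_min = tl$frame_interval_min,
                 fov_width_um = dim(frames)[2] * tl$pixel_size_um,
                 fov_height_um = dim(frames)[1] * tl$pixel_size_um),
            class = "FlowField")
}

#' Integrate migration trajectories from a flow field
#'
#' Seeds a regular grid of points and forward-integrates the flow: at each
#' step the displacement is sampled at the current position by bilinear
#' interpolation and added. Trajectories leaving the frame are frozen and
#' flagged excluded from the field-of-view mean.
#'
#' @param flow a `FlowField` from [compute_flow()].
#' @param grid_spacing_um seed grid spacing (micrometres; default 10).
#' @return A `TrajectorySet`: list with `seeds_um` (n x 2), `positions_um`
#'   (array \[n, frames, 2\]), `net_displacement_um`, `speed_um_per_h`,
#'   `path_length_um`, `retained`, `elapsed_h`.
#' @export
integrate_trajectories <- function(flow, grid_spacing_um = 10) {
  stopifnot(inherits(flow, "FlowField"))
  stopifnot_scalar(grid_spacing_um, "grid_spacing_um")
  W <- flow$fov_width_um; H <- flow$fov_height_um
  gx <- seq(grid_spacing_um / 2, W - grid_spacing_um / 2,
            by = grid_spacing_um)
  gy <- seq(grid_spacing_um / 2, H - grid_spacing_um / 2,
            by = grid_spacing_um)
  seeds <- cbind(x = rep(gx, times = length(gy)),
                 y = rep(gy, each = length(gx)))
  n <- nrow(seeds)
  npair <- dim(flow$u)[3]
  px <- flow$pixel_size_um
  pos <- array(NA_real_, dim = c(n, npair + 1L, 2L))
  pos[, 1L, ] <- seeds
  active <- rep(TRUE, n)
  x <- seeds[, 1L]; y <- seeds[, 2L]
  for (k in seq_len(npair)) {
    ux <- bilinear(flow$u[, , k], y / px + 0.5, x / px + 0.5)
    vy <- bilinear(flow$v[, , k], y / px + 0.5, x / px + 0.5)
    x[active] <- x[active] + ux[active]
    y[active] <- y[active] + vy[active]
    out <- x < 0 | x > W | y < 0 | y > H
    if (any(out & active)) {
      # freeze at the boundary crossing and exclude from the mean
      x[out & active] <- pmin(pmax(x[out & active], 0), W)
      y[out & active] <- pmin(pmax(y[out & active], 0), H)
      active[out] <- FALSE
    }
    pos[, k + 1L, 1L] <- x
    pos[, k + 1L, 2L] <- y
  }
  elapsed_h <- npair * flow$frame_interval_min / 60
  net <- sqrt((pos[, npair + 1L, 1L] - pos[, 1L, 1L])^2 +
              (pos[, npair + 1L, 2L] - pos[, 1L, 2L])^2)
  dx <- pos[, -1L, 1L, drop = FALSE] - pos[, -(npair + 1L), 1L, drop = FALSE]
  dy <- pos[, -1L, 2L, drop = FALSE] - pos[, -(npair + 1L), 2L, drop = FALSE]
  path <- rowSums(sqrt(dx[, , 1L]^2 + dy[, , 1L]^2))
  structure(list(seeds_um = seeds, positions_um = pos,
                 net_displacement_um = net,
                 speed_um_per_h = net / elapsed_h,
                 path_length_um = path,
                 retained = active, elapsed_h = elapsed_h),
            class = "TrajectorySet")
}

#' Field-of-view mean migration speed
#'
#' Per-seed speed is the net displacement (start to end, not path length)
#' divided by elapsed hours; the mean is unweighted over retained seeds.
#' Use `measure = "path"` for the summed path-length alternative.
#'
#' @param traj a `TrajectorySet`.
#' @param measure `"net"` (default) or `"path"`.
#' @return Mean speed in micrometres per hour.
#' @export
mean_speed <- function(traj, measure = c("net", "path")) {
  stopifnot(inherits(traj, "TrajectorySet"))
  measure <- match.arg(measure)
  if (!any(traj$retained)) stop("all trajectories were excluded")
  if (measure == "net") {
    mean(traj$speed_um_per_h[traj$retained])
  } else {
    mean(traj$path_length_um[traj$retained] / traj$elapsed_h)
  }
}

#' @export
print.TrajectorySet <- function(x, ...) {
  cat(sprintf(
    "TrajectorySet: %d seeds (%d retained), %.2f h, mean speed %.3f um/h\n",
    nrow(x$seeds_um), sum(x$retained), x$elapsed_h,
    mean(x$speed_um_per_h[x$retained])))
  invisible(x)
}
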