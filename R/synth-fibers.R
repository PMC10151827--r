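#' Specify a synthetic stress-fiber field
#'
#' Describes a basal fiber-plane image: straight fibers rendered as
#' anti-aliased bright line segments with a Gaussian cross-section on a dark
#' background. Orientations can be independent (`"uniform-random"`), shared
#' across the field (`"globally-aligned"`), or locally correlated
#' (`"patchwise-aligned"`: all fibers whose midpoint falls in the same
#' square patch share that patch's orientation), giving a controllable
#' orientation-correlation length for alignment statistics.
#'
#' @param fov_width_um,fov_height_um,pixel_size_um field geometry.
#' @param n_fibers number of fibers.
#' @param length_mean_um,length_sd_um Gaussian fiber-length distribution
#'   (micrometres), truncated below at `0.5` um.
#' @param orientation_mode one of `"uniform-random"`, `"globally-aligned"`,
#'   `"patchwise-aligned"`.
#' @param patch_size_um patch edge for patchwise mode (micrometres).
#' @param patch_orientations optional matrix of fixed patch orientations in
#'   radians (rows = patch rows, cols = patch cols); when `NULL` patch
#'   orientations are drawn uniformly.
#' @param fiber_width_um fiber full width at half maximum (micrometres).
#' @param fiber_intensity,background_intensity grayscale levels on \[0, 1\].
#' @param noise_sd additive Gaussian noise s.d.
#' @param rng_seed integer seed.
#' @return A `FiberFieldSpec` object.
#' @export
fiber_field_spec <- function(fov_width_um = 200, fov_height_um = 200,
                             pixel_size_um = 0.2, n_fibers = 200,
                             length_mean_um = 3, length_sd_um = 0.5,
                             orientation_mode = c("uniform-random",
                                                  "globally-aligned",
                                                  "patchwise-aligned"),
                             patch_size_um = 30, patch_orientations = NULL,
                             fiber_width_um = 0.5, fiber_intensity = 0.9,
                             background_intensity = 0.05, noise_sd = 0,
                             rng_seed = 1L) {
  orientation_mode <- match.arg(orientation_mode)
  stopifnot_scalar(length_mean_um, "length_mean_um")
  stopifnot_scalar(fiber_width_um, "fiber_width_um")
  if (orientation_mode == "patchwise-aligned")
    stopifnot_scalar(patch_size_um, "patch_size_um")
  diag_um <- sqrt(fov_width_um^2 + fov_height_um^2)
  if (length_mean_um > diag_um)
    stop("fibers longer than the field-of-view diagonal are not supported")
  if (length_sd_um < 0) stop("length_sd_um must be non-negative")
  structure(list(fov_width_um = fov_width_um, fov_height_um = fov_height_um,
                 pixel_size_um = pixel_size_um, n_fibers = as.integer(n_fibers),
                 length_mean_um = length_mean_um, length_sd_um = length_sd_um,
                 orientation_mode = orientation_mode,
                 patch_size_um = patch_size_um,
                 patch_orientations = patch_orientations,
                 fiber_width_um = fiber_width_um,
                 fiber_intensity = fiber_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
            class = "FiberFieldSpec")
}

# Render one Gaussian-profile segment into img (pixel units), using a
# max-composite so crossing fibers stay intensity-continuous.
.render_segment <- function(img, x0, y0, x1, y1, sigma_px, bg, peak) {
  ny <- nrow(img); nx <- ncol(img)
  pad <- ceiling(3 * sigma_px) + 1
  cmin <- max(1L, floor(min(x0, x1) - pad)); cmax <- min(nx, ceiling(max(x0, x1) + pad))
  rmin <- max(1L, floor(min(y0, y1) - pad)); rmax <- min(ny, ceiling(max(y0, y1) + pad))
  if (cmin > cmax || rmin > rmax) return(img)
  cs <- cmin:cmax; rs <- rmin:rmax
  pxx <- rep(cs - 0.5, each = length(rs))
  pyy <- rep(rs - 0.5, times = length(cs))
  dx <- x1 - x0; dy <- y1 - y0
  len <- sqrt(dx * dx + dy * dy)
  # segment convolved with a Gaussian PSF: Gaussian cross-section with erf
  # caps, so the axial profile crosses half maximum exactly at the endpoints
  if (len == 0) {
    prof <- bg + (peak - bg) *
      exp(-((pxx - x0)^2 + (pyy - y0)^2) / (2 * sigma_px^2))
  } else {
    ux <- dx / len; uy <- dy / len
    t <- (pxx - x0) * ux + (pyy - y0) * uy          # axial coordinate
    d <- -(pxx - x0) * uy + (pyy - y0) * ux         # radial coordinate
    cap <- stats::pnorm(t / sigma_px) - stats::pnorm((t - len) / sigma_px)
    prof <- bg + (peak - bg) * exp(-d^2 / (2 * sigma_px^2)) * cap
  }
  sub <- img[rs, cs]
  img[rs, cs] <- pmax(sub, matrix(prof, length(rs), length(cs)))
  img
}

#' Generate a synthetic fiber-plane image with ground truth
#'
#' @param spec a [fiber_field_spec()].
#' @return A list with `image` (numeric matrix), `truth` (list with
#'   `fibers` data frame of exact endpoints, lengths and orientations, and
#'   `patches` data frame of patch orientations for patchwise mode), and
#'   `spec`.
#' @export
generate_fiber_field <- function(spec) {
  stopifnot(inherits(spec, "FiberFieldSpec"))
  px <- spec$pixel_size_um
  nx <- max(2L, round(spec$fov_width_um / px))
  ny <- max(2L, round(spec$fov_height_um / px))
  diag_um <- sqrt(spec$fov_width_um^2 + spec$fov_height_um^2)
  n <- spec$n_fibers
  fibers <- NULL; patches <- NULL; image <- NULL
  with_seed(spec$rng_seed, {
    len <- rnorm(n, spec$length_mean_um, spec$length_sd_um)
    len <- pmin(pmax(len, 0.5), diag_um)
    # midpoints sampled so both endpoints stay inside the field: rendered
    # foreground then scales linearly with true total length (no clipping)
    margin <- spec$fiber_width_um + 1
    mx <- runif(n, 0, spec$fov_width_um)
    my <- runif(n, 0, spec$fov_height_um)
    if (spec$orientation_mode == "uniform-random") {
      theta <- runif(n, 0, pi)
    } else if (spec$orientation_mode == "globally-aligned") {
      theta <- rep(runif(1, 0, pi), n)
    } else {
      npr <- ceiling(spec$fov_height_um / spec$patch_size_um)
      npc <- ceiling(spec$fov_width_um / spec$patch_size_um)
      po <- spec$patch_orientations
      if (is.null(po)) {
        po <- matrix(runif(npr * npc, 0, pi), npr, npc)
      } else if (nrow(po) != npr || ncol(po) != npc) {
        stop(sprintf("patch_orientations must be %d x %d for this geometry",
                     npr, npc))
      }
      pr <- pmin(floor(my / spec$patch_size_um) + 1L, npr)
      pc <- pmin(floor(mx / spec$patch_size_um) + 1L, npc)
      theta <- po[cbind(pr, pc)]
      patches <- data.frame(patch_row = rep(seq_len(npr), times = npc),
                            patch_col = rep(seq_len(npc), each = npr),
                            orientation_rad = as.vector(po))
    }
    # rejection-resample midpoints whose fiber would leave the field
    for (i in seq_len(n)) {
      hx <- abs(len[i] / 2 * cos(theta[i])) + margin
      hy <- abs(len[i] / 2 * sin(theta[i])) + margin
      if (2 * hx < spec$fov_width_um && 2 * hy < spec$fov_height_um) {
        if (mx[i] < hx || mx[i] > spec$fov_width_um - hx)
          mx[i] <- runif(1, hx, spec$fov_width_um - hx)
        if (my[i] < hy || my[i] > spec$fov_height_um - hy)
          my[i] <- runif(1, hy, spec$fov_height_um - hy)
        if (spec$orientation_mode == "patchwise-aligned") {
          # keep the patch assignment consistent with the moved midpoint
          pr_i <- min(floor(my[i] / spec$patch_size_um) + 1L, nrow(po))
          pc_i <- min(floor(mx[i] / spec$patch_size_um) + 1L, ncol(po))
          theta[i] <- po[pr_i, pc_i]
        }
      }
    }
    x0 <- mx - len / 2 * cos(theta); x1 <- mx + len / 2 * cos(theta)
    y0 <- my - len / 2 * sin(theta); y1 <- my + len / 2 * sin(theta)
    fibers <- data.frame(fiber = seq_len(n), x0_um = x0, y0_um = y0,
                         x1_um = x1, y1_um = y1, length_um = len,
                         orientation_rad = axial(theta),
                         midpoint_x_um = mx, midpoint_y_um = my)
    img <- matrix(spec$background_intensity, ny, nx)
    sigma_px <- spec$fiber_width_um / px / (2 * sqrt(2 * log(2)))
    for (i in seq_len(n)) {
      img <- .render_segment(img, x0[i] / px, y0[i] / px, x1[i] / px,
                             y1[i] / px, sigma_px,
                             spec$background_intensity, spec$fiber_intensity)
    }
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(ny * nx, sd = spec$noise_sd), ny, nx)
    image <- clip01(img)
  })
  list(image = image,
       truth = list(fibers = fibers, patches = patches),
       spec = spec)
}
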