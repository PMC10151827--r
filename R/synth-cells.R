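#' Specify a synthetic cell-boundary field
#'
#' Describes a field of view tiled by epithelial cells whose boundaries are
#' rendered as bright cortical-actin-like ridges on a dark interior, the way
#' F-actin staining outlines cells in a maximum-intensity projection. Cells
#' are a Lloyd-relaxed Voronoi tessellation; elongation is imposed by
#' measuring seed distances in a coordinate frame stretched along x by
#' `target_ar`, which gives an analytic handle on the expected elongation
#' axis.
#'
#' @param fov_width_um,fov_height_um physical field-of-view size (micrometres).
#' @param pixel_size_um pixel pitch (micrometres per pixel).
#' @param n_cells number of cells (>= 1).
#' @param target_ar target mean cell aspect ratio (>= 1); 1 gives isotropic
#'   cells.
#' @param boundary_intensity,background_intensity grayscale levels on
#'   \[0, 1\]; boundary must exceed background.
#' @param noise_sd additive Gaussian noise s.d. (grayscale units; 0 = clean).
#' @param boundary_blur_px Gaussian blur s.d. (pixels) applied to the
#'   rendered ridges so they resemble diffraction-limited boundaries.
#' @param rng_seed integer seed; identical specs and seeds give bit-identical
#'   output.
#' @return A `CellFieldSpec` object.
#' @export
cell_field_spec <- function(fov_width_um = 563, fov_height_um = 356,
                            pixel_size_um = 1, n_cells = 100,
                            target_ar = 1, boundary_intensity = 0.8,
                            background_intensity = 0.1, noise_sd = 0,
                            boundary_blur_px = 0.7, rng_seed = 1L) {
  stopifnot_scalar(fov_width_um, "fov_width_um")
  stopifnot_scalar(fov_height_um, "fov_height_um")
  stopifnot_scalar(pixel_size_um, "pixel_size_um")
  stopifnot_scalar(n_cells, "n_cells")
  stopifnot_scalar(target_ar, "target_ar")
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (target_ar < 1) stop("target_ar must be >= 1")
  if (boundary_intensity <= background_intensity)
    stop("boundary_intensity must exceed background_intensity")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(fov_width_um = fov_width_um, fov_height_um = fov_height_um,
                 pixel_size_um = pixel_size_um, n_cells = as.integer(n_cells),
                 target_ar = target_ar,
                 boundary_intensity = boundary_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, boundary_blur_px = boundary_blur_px,
                 rng_seed = as.integer(rng_seed)),
            class = "CellFieldSpec")
}

# Poisson-disk-ish dart throwing in the squeezed frame, returning seed
# positions in real pixel coordinates (x, y).
.sample_seeds <- function(nx, ny, n, ar) {
  wx <- nx / ar
  rmin <- 0.65 * sqrt(wx * ny / n)
  sx <- numeric(0); sy <- numeric(0)
  attempts <- 0L
  while (length(sx) < n && attempts < 200L * n) {
    attempts <- attempts + 1L
    px <- runif(1, 0, wx); py <- runif(1, 0, ny)
    if (length(sx) == 0L ||
        min((sx - px)^2 + (sy - py)^2) >= rmin^2) {
      sx <- c(sx, px); sy <- c(sy, py)
    } else if (attempts %% (50L * n) == 0L) {
      rmin <- rmin * 0.8  # relax if the darts stall
    }
  }
  while (length(sx) < n) {          # fall back to plain uniform fill-in
    sx <- c(sx, runif(1, 0, wx)); sy <- c(sy, runif(1, 0, ny))
  }
  cbind(x = sx * ar, y = sy)
}

#' Generate a synthetic cell-boundary image with ground truth
#'
#' Renders a Lloyd-relaxed Voronoi tessellation as bright cell boundaries on
#' a dark background and returns the exact ground-truth label map together
#' with per-cell area and ellipse-fit aspect ratio computed from the label
#' map (generator internals), never from the rendered pixels.
#'
#' @param spec a [cell_field_spec()].
#' @return A list with elements `image` (numeric matrix, \[0,1\]), `truth`
#'   (list with `labels` integer matrix and `cells` per-cell data frame),
#'   and `spec`.
#' @export
generate_cell_field <- function(spec) {
  stopifnot(inherits(spec, "CellFieldSpec"))
  px <- spec$pixel_size_um
  nx <- max(2L, round(spec$fov_width_um / px))
  ny <- max(2L, round(spec$fov_height_um / px))
  if (nx * ny / spec$n_cells < 4)
    stop("n_cells too large for the field of view (mean cell area < 4 px^2)")
  ar <- spec$target_ar
  labels <- NULL
  image <- NULL
  with_seed(spec$rng_seed, {
    seeds <- .sample_seeds(nx, ny, spec$n_cells, ar)
    # Lloyd relaxation (2 iterations): centroid update is identical in the
    # squeezed and real frames because the squeeze is linear.
    for (it in 1:2) {
      lab <- cpp_nearest_seed(ny, nx, seeds[, 1], seeds[, 2], ar)
      cx <- rowsum(rep(seq_len(nx) - 0.5, each = ny), as.vector(lab))
      cy <- rowsum(rep(seq_len(ny) - 0.5, times = nx), as.vector(lab))
      cnt <- tabulate(as.vector(lab), nbins = spec$n_cells)
      keep <- cnt > 0
      seeds[keep, 1] <- cx[, 1] / cnt[keep]
      seeds[keep, 2] <- cy[, 1] / cnt[keep]
    }
    labels <- cpp_nearest_seed(ny, nx, seeds[, 1], seeds[, 2], ar)
    present <- sort(unique(as.vector(labels)))
    if (length(present) < spec$n_cells) {   # compact away empty seeds
      remap <- integer(max(present)); remap[present] <- seq_along(present)
      labels <- matrix(remap[labels], ny, nx)
    }
    # render boundaries: pixels with a 4-neighbour of a different label
    b <- matrix(FALSE, ny, nx)
    b[-ny, ] <- b[-ny, ] | (labels[-ny, ] != labels[-1, ])
    b[-1, ]  <- b[-1, ]  | (labels[-1, ] != labels[-ny, ])
    b[, -nx] <- b[, -nx] | (labels[, -nx] != labels[, -1])
    b[, -1]  <- b[, -1]  | (labels[, -1] != labels[, -nx])
    img <- matrix(spec$background_intensity, ny, nx)
    img[b] <- spec$boundary_intensity
    if (spec$boundary_blur_px > 0)
      img <- sep_conv(img, gauss_kernel(spec$boundary_blur_px))
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(ny * nx, sd = spec$noise_sd), ny, nx)
    image <- clip01(img)
  })
  cells <- region_shape(labels, px)
  list(image = image,
       truth = list(labels = labels, cells = cells),
       spec = spec)
}

#' Ellipse-fit shape descriptors of labelled regions
#'
#' For every positive label, fits the ellipse with the same normalized
#' second central moments as the pixel region (the standard regionprops
#' definition, including the 1/12 per-pixel variance term, so a w x h
#' axis-aligned rectangle of pixels yields axis lengths proportional to w
#' and h exactly) and reports centroid, area, axis lengths, aspect ratio
#' and axial orientation.
#'
#' @param labels integer matrix of region labels (0 = background).
#' @param pixel_size_um micrometres per pixel.
#' @return Data frame with one row per label: `label`, `n_px`, `area_um2`,
#'   `centroid_x_um`, `centroid_y_um`, `major_um`, `minor_um`,
#'   `aspect_ratio`, `orientation_rad`.
#' @export
region_shape <- function(labels, pixel_size_um = 1) {
  lab <- as.vector(labels)
  pos <- lab > 0
  if (!any(pos)) {
    return(data.frame(label = integer(0), n_px = integer(0),
                      area_um2 = numeric(0), centroid_x_um = numeric(0),
                      centroid_y_um = numeric(0), major_um = numeric(0),
                      minor_um = numeric(0), aspect_ratio = numeric(0),
                      orientation_rad = numeric(0)))
  }
  ny <- nrow(labels); nx <- ncol(labels)
  xs <- rep(seq_len(nx) - 0.5, each = ny)[pos]
  ys <- rep(seq_len(ny) - 0.5, times = nx)[pos]
  g <- lab[pos]
  ids <- sort(unique(g))
  n <- tabulate(factor(g, levels = ids))
  sx <- rowsum(xs, g)[, 1]; sy <- rowsum(ys, g)[, 1]
  mx <- sx / n; my <- sy / n
  dx <- xs - mx[match(g, ids)]
  dy <- ys - my[match(g, ids)]
  # normalized second central moments with the 1/12 pixel correction
  uxx <- rowsum(dx * dx, g)[, 1] / n + 1 / 12
  uyy <- rowsum(dy * dy, g)[, 1] / n + 1 / 12
  uxy <- rowsum(dx * dy, g)[, 1] / n
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  l1 <- (uxx + uyy + common) / 2
  l2 <- (uxx + uyy - common) / 2
  l2 <- pmax(l2, 1e-12)
  theta <- 0.5 * atan2(2 * uxy, uxx - uyy)
  data.frame(label = ids, n_px = n,
             area_um2 = n * pixel_size_um^2,
             centroid_x_um = mx * pixel_size_um,
             centroid_y_um = my * pixel_size_um,
             major_um = 4 * sqrt(l1) * pixel_size_um,
             minor_um = 4 * sqrt(l2) * pixel_size_um,
             aspect_ratio = sqrt(l1 / l2),
             orientation_rad = axial(theta))
}
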