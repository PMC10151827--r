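#' Read a calibrated z-stack from a multi-page grayscale TIFF
#'
#' Pages map to ascending z (substrate to apical surface). Intensities are
#' returned on \[0, 1\] as stored by the TIFF reader; no rescaling beyond
#' the format's own bit depth is applied.
#'
#' @param path multi-page grayscale TIFF file.
#' @param pixel_size_um micrometres per pixel in x/y.
#' @param z_step_um micrometres between consecutive slices.
#' @param metadata optional named list attached to the stack.
#' @return An `ImageStack`: list with `voxels` (3D array \[y, x, z\]),
#'   `pixel_size_um`, `z_step_um`, `metadata`.
#' @export
read_stack <- function(path, pixel_size_um, z_step_um, metadata = list()) {
  stopifnot_scalar(pixel_size_um, "pixel_size_um")
  stopifnot_scalar(z_step_um, "z_step_um")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("not a readable TIFF file: ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2, logical(1))))
    stop("RGB/multi-channel pages are not supported; expected grayscale")
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("pages have inconsistent shapes")
  voxels <- array(unlist(pages), dim = c(dims[1, 1], dims[2, 1],
                                         length(pages)))
  image_stack(voxels, pixel_size_um, z_step_um, metadata)
}

#' Construct an ImageStack from an in-memory array
#'
#' @param voxels 3D array \[y, x, z\] (a 2D matrix is treated as one slice).
#' @inheritParams read_stack
#' @return An `ImageStack`.
#' @export
image_stack <- function(voxels, pixel_size_um, z_step_um, metadata = list()) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  stopifnot(length(dim(voxels)) == 3, all(dim(voxels) >= 1))
  stopifnot_scalar(pixel_size_um, "pixel_size_um")
  stopifnot_scalar(z_step_um, "z_step_um")
  structure(list(voxels = voxels, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um, metadata = metadata),
            class = "ImageStack")
}

#' Define a projection slab
#'
#' Depth windows are measured in micrometres downward from the top-of-stack
#' (apical-most) slice; a slice at depth d is selected when
#' `z_lo_um <= d < z_hi_um` (half-open window).
#'
#' @param plane_name one of `"apical"`, `"basal"`, `"fiber"`.
#' @param z_lo_um,z_hi_um depth window bounds (micrometres, `z_lo < z_hi`).
#' @return A `SlabSpec`.
#' @export
slab_spec <- function(plane_name = c("apical", "basal", "fiber"),
                      z_lo_um, z_hi_um) {
  plane_name <- match.arg(plane_name)
  if (!is.finite(z_lo_um) || !is.finite(z_hi_um) || z_lo_um >= z_hi_um)
    stop("slab window requires z_lo_um < z_hi_um")
  structure(list(plane_name = plane_name, z_lo_um = z_lo_um,
                 z_hi_um = z_hi_um), class = "SlabSpec")
}

#' Default slab windows for the three analysis planes
#'
#' Apical = top 4 um of the stack; basal = a 3-um slab starting 13 um below
#' the apical reference; fiber = a 1.5-um slab starting 2.2 um below the top
#' of the basal slab. All offsets are configurable per field of view by
#' passing explicit [slab_spec()] objects instead.
#'
#' @param basal_offset_um depth of the basal slab top below the apical
#'   reference (default 13).
#' @param fiber_offset_um depth of the fiber slab top below the basal slab
#'   top (default 2.2).
#' @return Named list of three `SlabSpec` objects.
#' @export
default_slabs <- function(basal_offset_um = 13, fiber_offset_um = 2.2) {
  list(apical = slab_spec("apical", 0, 4),
       basal = slab_spec("basal", basal_offset_um, basal_offset_um + 3),
       fiber = slab_spec("fiber", basal_offset_um + fiber_offset_um,
                         basal_offset_um + fiber_offset_um + 1.5))
}

#' Maximum-intensity projection of a slab
#'
#' Each output pixel is the maximum over the slab's z-slices at that (y, x).
#' Slice i (1-based, ascending z) lies at depth `(nz - i) * z_step_um` below
#' the top slice.
#'
#' @param stack an [image_stack()].
#' @param slab a [slab_spec()]; defaults to the full stack as "apical".
#' @return A `Projection`: list with `image` (matrix), `plane_name`, `slab`,
#'   `pixel_size_um`.
#' @export
max_project <- function(stack, slab = NULL) {
  stopifnot(inherits(stack, "ImageStack"))
  nz <- dim(stack$voxels)[3]
  depth <- (nz - seq_len(nz)) * stack$z_step_um
  if (is.null(slab))
    slab <- slab_spec("apical", 0, max(depth) + stack$z_step_um)
  stopifnot(inherits(slab, "SlabSpec"))
  sel <- which(depth >= slab$z_lo_um & depth < slab$z_hi_um)
  if (length(sel) == 0L)
    stop("slab window [", slab$z_lo_um, ", ", slab$z_hi_um,
         ") selects no z-slice")
  sub <- stack$voxels[, , sel, drop = FALSE]
  img <- apply(sub, c(1, 2), max)
  projection(img, slab$plane_name, stack$pixel_size_um, slab = slab)
}

#' Construct a Projection from a plain image matrix
#'
#' @param image 2D numeric matrix \[y, x\].
#' @param plane_name plane label (`"apical"`, `"basal"`, `"fiber"`).
#' @param pixel_size_um micrometres per pixel.
#' @param slab optional source [slab_spec()].
#' @param excluded optional logical matrix of pixels excluded from analysis.
#' @return A `Projection`.
#' @export
projection <- function(image, plane_name, pixel_size_um, slab = NULL,
                       excluded = NULL) {
  stopifnot(is.matrix(image))
  stopifnot_scalar(pixel_size_um, "pixel_size_um")
  structure(list(image = image, plane_name = plane_name,
                 pixel_size_um = pixel_size_um, slab = slab,
                 excluded = excluded),
            class = "Projection")
}

#' Write a projection (or any image matrix) as 16-bit grayscale TIFF
#'
#' @param x a `Projection` or numeric matrix on \[0, 1\].
#' @param path output file.
#' @export
write_projection <- function(x, path) {
  img <- if (inherits(x, "Projection")) x$image else x
  tiff::writeTIFF(clip01(img), path, bits.per.sample = 16L)
  invisible(path)
}

#' @export
print.Projection <- function(x, ...) {
  cat(sprintf("Projection [%s]: %d x %d px, %.3g um/px\n", x$plane_name,
              nrow(x$image), ncol(x$image), x$pixel_size_um))
  invisible(x)
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ImageStack: %d x %d px, %d slices, %.3g um/px, %.3g um z-step\n",
              d[1], d[2], d[3], x$pixel_size_um, x$z_step_um))
  invisible(x)
}
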