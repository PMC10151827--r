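# Simple base-graphics visualizations.

#' Map a per-cell metric onto the segmentation
#'
#' Renders the label map with each cell colored by the chosen metric
#' (viridis-like palette), ridges in black.
#'
#' @param lmap a `CellLabelMap`.
#' @param metrics a `CellMetrics` from [cell_morphology()].
#' @param metric column of `metrics$cells` to map (default
#'   `"aspect_ratio"`).
#' @param file optional PNG path; when `NULL`, plots to the active device.
#' @export
plot_cell_metric <- function(lmap, metrics, metric = "aspect_ratio",
                             file = NULL) {
  vals <- metrics$cells[[metric]]
  if (is.null(vals)) stop("unknown metric: ", metric)
  if (!is.null(file)) {
    grDevices::png(file, width = ncol(lmap$labels), height = nrow(lmap$labels))
    on.exit(grDevices::dev.off())
  }
  pal <- grDevices::hcl.colors(256, "viridis")
  rng <- range(vals)
  col_of <- if (diff(rng) > 0) {
    pal[1 + round(255 * (vals - rng[1]) / diff(rng))]
  } else rep(pal[128], length(vals))
  img <- matrix("#000000", nrow(lmap$labels), ncol(lmap$labels))
  pos <- lmap$labels > 0
  img[pos] <- col_of[match(lmap$labels[pos], metrics$cells$label)]
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(img), 0, 0, 1, 1)
  invisible(NULL)
}

#' Overlay migration paths colored by speed
#'
#' @param traj a `TrajectorySet`.
#' @param file optional PNG path.
#' @export
plot_trajectories <- function(traj, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 640)
    on.exit(grDevices::dev.off())
  }
  pal <- grDevices::hcl.colors(256, "plasma")
  sp <- traj$speed_um_per_h
  rng <- range(sp)
  col_of <- if (diff(rng) > 0) {
    pal[1 + round(255 * (sp - rng[1]) / diff(rng))]
  } else rep(pal[128], length(sp))
  graphics::plot(NA, xlim = range(traj$positions_um[, , 1]),
                 ylim = rev(range(traj$positions_um[, , 2])),
                 xlab = "x (um)", ylab = "y (um)", asp = 1)
  for (i in seq_len(nrow(traj$seeds_um))) {
    graphics::lines(traj$positions_um[i, , 1], traj$positions_um[i, , 2],
                    col = col_of[i])
  }
  invisible(NULL)
}
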