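# Cell-boundary segmentation and morphometry.
#
# Boundaries stained by cortical actin appear as bright ridges; cells are
# the dark catchment basins in between. Segmentation is marker-controlled
# watershed: regional minima of the h-minima-suppressed boundary surface
# seed the basins, watershed lines (label 0) separate them.

#' Segmentation parameters
#'
#' @param plane_name `"apical"` or `"basal"`; chooses the preprocessing
#'   path (opening-closing by reconstruction vs. adaptive Wiener filter).
#' @param smooth_radius_px disk radius (pixels) of the reconstruction
#'   structuring element (apical path).
#' @param wiener_window_px odd local-window size (pixels) for the adaptive
#'   noise filter (basal path).
#' @param marker_h h-minima depth (grayscale units) for marker suppression;
#'   larger values merge shallow minima into fewer markers.
#' @param qc_max_tortuosity ridges more tortuous than this (path length /
#'   endpoint chord) are dissolved.
#' @param qc_min_ridge_um,qc_max_ridge_um ridge length bounds (micrometres);
#'   ridges outside are dissolved.
#' @param qc_intensity_percentile ridges whose mean image intensity falls
#'   strictly below this percentile of all ridge intensities are dissolved;
#'   0 disables the intensity cut.
#' @param min_area_um2,max_area_um2 retained cell-area bounds (micrometres
#'   squared).
#' @return A `SegmentationParams` object.
#' @export
segmentation_params <- function(plane_name = c("apical", "basal"),
                                smooth_radius_px = 2L,
                                wiener_window_px = 5L,
                                marker_h = 0.1,
                                qc_max_tortuosity = 1.6,
                                qc_min_ridge_um = 3,
                                qc_max_ridge_um = Inf,
                                qc_intensity_percentile = 30,
                                min_area_um2 = 10,
                                max_area_um2 = 2000) {
  plane_name <- match.arg(plane_name)
  stopifnot_scalar(marker_h, "marker_h")
  stopifnot_scalar(qc_max_tortuosity, "qc_max_tortuosity")
  if (min_area_um2 > max_area_um2) stop("area bounds must be ordered")
  if (qc_intensity_percentile < 0 || qc_intensity_percentile >= 100)
    stop("qc_intensity_percentile must be in [0, 100)")
  structure(list(plane_name = plane_name,
                 smooth_radius_px = as.integer(smooth_radius_px),
                 wiener_window_px = as.integer(wiener_window_px),
                 marker_h = marker_h,
                 qc_max_tortuosity = qc_max_tortuosity,
                 qc_min_ridge_um = qc_min_ridge_um,
                 qc_max_ridge_um = qc_max_ridge_um,
                 qc_intensity_percentile = qc_intensity_percentile,
                 min_area_um2 = min_area_um2,
                 max_area_um2 = max_area_um2),
            class = "SegmentationParams")
}

eb_mat <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}

#' Preprocess a projection before watershed segmentation
#'
#' Apical projections are filtered by morphological opening-by-reconstruction
#' followed by closing-by-reconstruction with a disk structuring element,
#' which flattens texture smaller than the disk while preserving boundary
#' ridges exactly. Basal projections are filtered with a local adaptive
#' (Wiener-type) filter: each pixel is shrunk towards its local window mean
#' in proportion to the local variance relative to the estimated noise
#' variance.
#'
#' @param proj a [projection()] with `plane_name` `"apical"` or `"basal"`.
#' @param params a [segmentation_params()].
#' @return The filtered `Projection`.
#' @export
preprocess <- function(proj, params = segmentation_params(proj$plane_name)) {
  stopifnot(inherits(proj, "Projection"))
  img <- proj$image
  if (params$plane_name == "apical") {
    kern <- disk_brush(params$smooth_radius_px)
    er <- eb_mat(EBImage::erode(img, kern))
    opened <- reconstruct_dilate(er, img)
    di <- eb_mat(EBImage::dilate(opened, kern))
    out <- reconstruct_erode(di, opened)
  } else if (params$plane_name == "basal") {
    w <- params$wiener_window_px
    r <- (w - 1L) %/% 2L
    mu <- box_mean(img, r)
    s2 <- pmax(box_mean(img * img, r) - mu^2, 0)
    nu <- mean(s2)
    gain <- ifelse(s2 > nu, (s2 - nu) / pmax(s2, 1e-12), 0)
    out <- mu + gain * (img - mu)
  } else {
    stop("unknown plane_name: ", params$plane_name)
  }
  projection(out, proj$plane_name, proj$pixel_size_um, slab = proj$slab,
             excluded = proj$excluded)
}

#' Marker-controlled watershed segmentation of cell boundaries
#'
#' Markers are the regional minima of the boundary surface after h-minima
#' suppression at depth `marker_h`; watershed flooding of that surface
#' assigns each pixel to a basin, with ridge pixels kept at label 0. Basins
#' are grown 4-connected so ridges are 8-connected curves. A uniform image
#' (a single regional minimum spanning the field) yields one label covering
#' the field of view, with a warning.
#'
#' @param proj a (preprocessed) [projection()].
#' @param params a [segmentation_params()].
#' @return A `CellLabelMap`: list with `labels` (integer matrix, 0 = ridge),
#'   `pixel_size_um`, `fov_width_um`, `fov_height_um`, `params`.
#' @export
segment_cells <- function(proj, params = segmentation_params()) {
  stopifnot(inherits(proj, "Projection"))
  surf <- hmin_transform(proj$image, params$marker_h)
  markers <- cpp_regional_minima(surf, 8L)
  nmark <- max(markers)
  if (nmark == 0L) stop("no watershed markers found")
  if (nmark == 1L && all(markers > 0L)) {
    warning("uniform image: returning a single label covering the field")
    labels <- matrix(1L, nrow(proj$image), ncol(proj$image))
  } else {
    labels <- cpp_watershed(surf, markers, 4L)
  }
  cell_label_map(labels, proj$pixel_size_um, params = params)
}

#' Construct a CellLabelMap
#'
#' @param labels integer matrix, 0 = ridge/background.
#' @param pixel_size_um micrometres per pixel.
#' @param fov_width_um,fov_height_um field size; defaults to the pixel grid
#'   extent.
#' @param params optional provenance ([segmentation_params()]).
#' @return A `CellLabelMap`.
#' @export
cell_label_map <- function(labels, pixel_size_um,
                           fov_width_um = ncol(labels) * pixel_size_um,
                           fov_height_um = nrow(labels) * pixel_size_um,
                           params = NULL) {
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, pixel_size_um = pixel_size_um,
                 fov_width_um = fov_width_um, fov_height_um = fov_height_um,
                 params = params),
            class = "CellLabelMap")
}

#' @export
print.CellLabelMap <- function(x, ...) {
  cat(sprintf("CellLabelMap: %d cells, %d x %d px, %.3g um/px\n",
              length(setdiff(unique(as.vector(x$labels)), 0L)),
              nrow(x$labels), ncol(x$labels), x$pixel_size_um))
  invisible(x)
}

# Compact positive labels to 1..k preserving order.
compact_labels <- function(labels) {
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (length(ids) == 0L) return(labels * 0L)
  remap <- integer(max(ids))
  remap[ids] <- seq_along(ids)
  out <- labels
  pos <- labels > 0L
  out[pos] <- remap[labels[pos]]
  out
}

# Extract per-ridge descriptors: for each pair of adjacent labels, the ridge
# pixel set (label-0 pixels touching exactly those two labels), its traced
# path length, endpoint chord, tortuosity and mean image intensity.
ridge_table <- function(labels, image, pixel_size_um) {
  nr <- nrow(labels); nc <- ncol(labels)
  ridge_idx <- which(labels == 0L)
  if (length(ridge_idx) == 0L)
    return(list(table = data.frame(), pixels = list()))
  rr <- (ridge_idx - 1L) %% nr + 1L
  cc <- (ridge_idx - 1L) %/% nr + 1L
  # collect distinct positive labels in the 8-neighbourhood of each ridge px
  neigh <- matrix(0L, length(ridge_idx), 8L)
  k <- 0L
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                 c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))) {
    k <- k + 1L
    r2 <- rr + d[1L]; c2 <- cc + d[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    v <- integer(length(ridge_idx))
    v[ok] <- labels[cbind(r2[ok], c2[ok])]
    neigh[, k] <- v
  }
  pair_lo <- integer(length(ridge_idx)); pair_hi <- integer(length(ridge_idx))
  nlab <- integer(length(ridge_idx))
  for (i in seq_along(ridge_idx)) {
    u <- unique(neigh[i, ]); u <- u[u > 0L]
    nlab[i] <- length(u)
    if (length(u) == 2L) { pair_lo[i] <- min(u); pair_hi[i] <- max(u) }
  }
  sel <- nlab == 2L
  if (!any(sel)) return(list(table = data.frame(), pixels = list()))
  key <- paste(pair_lo[sel], pair_hi[sel], sep = "-")
  groups <- split(ridge_idx[sel], key)
  tab <- data.frame(pair = names(groups),
                    label_a = as.integer(sub("-.*", "", names(groups))),
                    label_b = as.integer(sub(".*-", "", names(groups))),
                    stringsAsFactors = FALSE)
  res <- t(vapply(groups, function(idx) {
    r <- (idx - 1L) %% nr + 1L
    c <- (idx - 1L) %/% nr + 1L
    g <- trace_path(r, c)
    path_px <- g$length
    chord_px <- g$chord
    c(path_px * pixel_size_um,
      if (chord_px > 0) path_px / chord_px else Inf,
      mean(image[idx]))
  }, numeric(3)))
  tab$length_um <- res[, 1]
  tab$tortuosity <- res[, 2]
  tab$mean_intensity <- res[, 3]
  list(table = tab, pixels = groups)
}

# Greedy ordered walk through an 8-connected pixel set; returns step-summed
# path length (px) and endpoint chord (px). Robust to small branches: walks
# from an endpoint (or an arbitrary pixel for loops) always to the nearest
# unvisited neighbour.
trace_path <- function(r, c) {
  n <- length(r)
  if (n == 1L) return(list(length = 0, chord = 0))
  pts <- cbind(r, c)
  d2 <- as.matrix(stats::dist(pts))^2
  adj <- d2 <= 2 + 1e-9 & d2 > 0
  deg <- rowSums(adj)
  start <- if (any(deg <= 1)) which(deg <= 1)[1L] else which.min(r + c)
  visited <- logical(n)
  cur <- start; visited[cur] <- TRUE
  len <- 0
  last <- cur
  repeat {
    nb <- which(adj[cur, ] & !visited)
    if (length(nb) == 0L) break
    nxt <- nb[which.min(d2[cur, nb])]
    len <- len + sqrt(d2[cur, nxt])
    visited[nxt] <- TRUE
    cur <- nxt
  }
  chord <- sqrt(sum((pts[cur, ] - pts[start, ])^2))
  list(length = len, chord = chord)
}

#' Quality control of watershed ridges
#'
#' For every watershed ridge separating two labels, computes (a) tortuosity
#' (traced path length / endpoint chord length), (b) ridge length in
#' micrometres, and (c) mean image intensity along the ridge. Ridges failing
#' any threshold — too tortuous, too short/long, or strictly dimmer than the
#' configured percentile of all ridge intensities — are dissolved by merging
#' their two labels; ridge pixels of dissolved boundaries join the merged
#' cell and labels are re-compacted. Merging never increases the label
#' count.
#'
#' @param lmap a `CellLabelMap` from [segment_cells()].
#' @param proj the intensity [projection()] the ridges are scored on.
#' @param params a [segmentation_params()].
#' @return The QC'd `CellLabelMap`.
#' @export
qc_boundaries <- function(lmap, proj,
                          params = lmap$params %||% segmentation_params()) {
  stopifnot(inherits(lmap, "CellLabelMap"), inherits(proj, "Projection"))
  rt <- ridge_table(lmap$labels, proj$image, lmap$pixel_size_um)
  if (nrow(rt$table) == 0L) return(lmap)
  tab <- rt$table
  fail <- tab$tortuosity > params$qc_max_tortuosity |
    tab$length_um < params$qc_min_ridge_um |
    tab$length_um > params$qc_max_ridge_um
  if (params$qc_intensity_percentile > 0) {
    cut <- stats::quantile(tab$mean_intensity,
                           params$qc_intensity_percentile / 100,
                           names = FALSE)
    fail <- fail | tab$mean_intensity < cut
  }
  if (!any(fail)) return(lmap)
  # union-find over labels
  nmax <- max(lmap$labels)
  parent <- seq_len(nmax)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in which(fail)) {
    a <- find(tab$label_a[i]); b <- find(tab$label_b[i])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nmax), find, integer(1))
  labels <- lmap$labels
  pos <- labels > 0L
  labels[pos] <- root[labels[pos]]
  # dissolve the failing ridges into the merged cells
  for (i in which(fail)) {
    labels[rt$pixels[[tab$pair[i]]]] <- root[tab$label_a[i]]
  }
  cell_label_map(compact_labels(labels), lmap$pixel_size_um,
                 lmap$fov_width_um, lmap$fov_height_um, params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove under- and over-segmented regions by area
#'
#' Labels with area outside `[min_um2, max_um2]` are set to background and
#' the remaining labels compacted. Never increases the label count.
#'
#' @param lmap a `CellLabelMap`.
#' @param min_um2,max_um2 area bounds (micrometres squared).
#' @return The filtered `CellLabelMap`.
#' @export
filter_by_area <- function(lmap, min_um2 = 0, max_um2 = Inf) {
  stopifnot(inherits(lmap, "CellLabelMap"))
  if (min_um2 > max_um2) stop("area bounds must be ordered")
  labels <- lmap$labels
  nmax <- max(labels)
  if (nmax == 0L) return(lmap)
  areas <- tabulate(labels[labels > 0L], nbins = nmax) * lmap$pixel_size_um^2
  drop <- which(areas < min_um2 | areas > max_um2)
  if (length(drop)) labels[labels %in% drop] <- 0L
  cell_label_map(compact_labels(labels), lmap$pixel_size_um,
                 lmap$fov_width_um, lmap$fov_height_um, lmap$params)
}

#' Per-cell and per-field morphology metrics
#'
#' Fits to each labelled region the ellipse with identical normalized second
#' central moments and reports area, centroid, axis lengths, aspect ratio
#' (major/minor, always >= 1; a degenerate single-pixel region reports 1)
#' and axial orientation. The field summary gives cell count, density over
#' the full field of view (cells per square millimetre; set
#' `density_denominator = "segmented"` to divide by the summed cell area
#' instead), and unweighted means of area and aspect ratio.
#'
#' @param lmap a `CellLabelMap`.
#' @param density_denominator `"fov"` (default) or `"segmented"`.
#' @return A `CellMetrics`: list with `cells` (per-cell data frame) and
#'   `summary` (one-row data frame: `n_cells`, `density_per_mm2`,
#'   `mean_area_um2`, `mean_ar`).
#' @export
cell_morphology <- function(lmap, density_denominator = c("fov", "segmented")) {
  stopifnot(inherits(lmap, "CellLabelMap"))
  density_denominator <- match.arg(density_denominator)
  cells <- region_shape(lmap$labels, lmap$pixel_size_um)
  n <- nrow(cells)
  area_mm2 <- if (density_denominator == "fov") {
    lmap$fov_width_um * lmap$fov_height_um / 1e6
  } else {
    sum(cells$area_um2) / 1e6
  }
  summary <- data.frame(
    n_cells = n,
    density_per_mm2 = if (area_mm2 > 0) n / area_mm2 else NA_real_,
    mean_area_um2 = if (n) mean(cells$area_um2) else NA_real_,
    mean_ar = if (n) mean(cells$aspect_ratio) else NA_real_)
  structure(list(cells = cells, summary = summary), class = "CellMetrics")
}

#' @export
print.CellMetrics <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "CellMetrics: %d cells, %.1f cells/mm2, mean area %.1f um2, mean AR %.2f\n",
    s$n_cells, s$density_per_mm2, s$mean_area_um2, s$mean_ar))
  invisible(x)
}

#' Run the full cell-shape pipeline on a projection
#'
#' Convenience wrapper: [preprocess()] (optional), [segment_cells()],
#' [qc_boundaries()], [filter_by_area()], [cell_morphology()].
#'
#' @param proj a [projection()].
#' @param params a [segmentation_params()].
#' @param preprocess_image apply the plane's preprocessing filter first?
#' @param qc apply ridge quality control?
#' @return List with `labels` (final `CellLabelMap`) and `metrics`
#'   (`CellMetrics`).
#' @export
segment_pipeline <- function(proj, params = segmentation_params(),
                             preprocess_image = TRUE, qc = TRUE) {
  p <- if (preprocess_image) preprocess(proj, params) else proj
  lmap <- segment_cells(p, params)
  if (qc) lmap <- qc_boundaries(lmap, p, params)
  lmap <- filter_by_area(lmap, params$min_area_um2, params$max_area_um2)
  list(labels = lmap, metrics = cell_morphology(lmap))
}
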