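# Structure-tensor orientation fields and the alignment-versus-distance
# statistic with a repositioning null.
#
# Orientations are axial (defined modulo 180 degrees) and all averaging and
# comparison happens in double-angle space: an orientation theta is
# represented by the unit vector (cos 2*theta, sin 2*theta), so theta and
# theta + 180 degrees are identical and the alignment of two orientations
# is cos 2*(theta_i - theta_j), +1 for parallel and -1 for perpendicular.

#' Construct an OrientationField
#'
#' @param theta matrix of axial orientations (radians, \[0, pi)) on the
#'   subregion grid (rows = y, cols = x).
#' @param valid logical matrix; invalid subregions are masked, never
#'   zero-filled.
#' @param centers_x_um,centers_y_um subregion centre coordinates.
#' @param subregion_um subregion edge length (micrometres).
#' @return An `OrientationField`.
#' @export
orientation_field_grid <- function(theta, valid, centers_x_um, centers_y_um,
                                   subregion_um) {
  stopifnot(all(dim(theta) == dim(valid)),
            length(centers_y_um) == nrow(theta),
            length(centers_x_um) == ncol(theta))
  structure(list(theta = axial(theta), valid = valid,
                 centers_x_um = centers_x_um, centers_y_um = centers_y_um,
                 subregion_um = subregion_um),
            class = "OrientationField")
}

#' @export
print.OrientationField <- function(x, ...) {
  cat(sprintf("OrientationField: %d x %d subregions (%g um), %d valid\n",
              nrow(x$theta), ncol(x$theta), x$subregion_um, sum(x$valid)))
  invisible(x)
}

#' Estimate the local fiber orientation field of an image
#'
#' Partitions the image into square subregions and reports, per subregion,
#' the dominant axial fiber orientation from the structure tensor of the
#' intensity gradients (the eigenvector of the smaller eigenvalue, i.e.
#' along the ridges, perpendicular to the dominant gradient). Subregions
#' overlapping the excluded mask, with mean intensity strictly below the
#' stated percentile of all subregion means (computed on the boundary-free
#' image), or with negligible gradient energy are masked invalid.
#'
#' @param proj fiber-plane [projection()] (possibly masked).
#' @param subregion_um subregion edge (micrometres; default 3).
#' @param intensity_percentile percentile cut in \[0, 100) (default 35).
#' @return An `OrientationField`.
#' @export
orientation_field <- function(proj, subregion_um = 3,
                              intensity_percentile = 35) {
  stopifnot(inherits(proj, "Projection"))
  stopifnot_scalar(subregion_um, "subregion_um")
  if (intensity_percentile < 0 || intensity_percentile >= 100)
    stop("intensity_percentile must be in [0, 100)")
  px <- proj$pixel_size_um
  img <- proj$image
  nr <- nrow(img); nc <- ncol(img)
  bs <- max(2L, round(subregion_um / px))
  nbr <- nr %/% bs; nbc <- nc %/% bs
  if (nbr < 1L || nbc < 1L)
    stop("subregion larger than the image")
  # central-difference gradients; the one-pixel border ring is dropped from
  # both components so border subregions are not skewed by one-sided data
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (img[, 3:nc] - img[, 1:(nc - 2)]) / 2
  gy[2:(nr - 1), ] <- (img[3:nr, ] - img[1:(nr - 2), ]) / 2
  gx[c(1, nr), ] <- 0; gx[, c(1, nc)] <- 0
  gy[c(1, nr), ] <- 0; gy[, c(1, nc)] <- 0
  rs <- seq_len(nbr * bs); cs <- seq_len(nbc * bs)
  bidx <- function(m) {
    # block index per pixel of the cropped image, column-major over blocks
    br <- (rep(seq_along(rs), times = length(cs)) - 1L) %/% bs
    bc <- (rep(seq_along(cs), each = length(rs)) - 1L) %/% bs
    matrix(br + nbr * bc + 1L, length(rs), length(cs))
  }
  bi <- as.vector(bidx(NULL))
  crop <- function(m) as.vector(m[rs, cs])
  jxx <- rowsum(crop(gx * gx), bi)[, 1]
  jyy <- rowsum(crop(gy * gy), bi)[, 1]
  jxy <- rowsum(crop(gx * gy), bi)[, 1]
  mint <- rowsum(crop(img), bi)[, 1] / (bs * bs)
  excl <- if (is.null(proj$excluded)) rep(FALSE, nbr * nbc) else
    rowsum(crop(proj$excluded * 1), bi)[, 1] > 0
  cut <- if (intensity_percentile > 0 && any(!excl)) {
    stats::quantile(mint[!excl], intensity_percentile / 100, names = FALSE)
  } else -Inf
  energy <- jxx + jyy
  valid <- !excl & mint >= cut & energy > 1e-10
  # fiber orientation: perpendicular to the dominant gradient direction
  phi_grad <- 0.5 * atan2(2 * jxy, jxx - jyy)
  theta <- axial(phi_grad + pi / 2)
  orientation_field_grid(matrix(theta, nbr, nbc),
                         matrix(valid, nbr, nbc),
                         centers_x_um = (seq_len(nbc) - 0.5) * bs * px,
                         centers_y_um = (seq_len(nbr) - 0.5) * bs * px,
                         subregion_um = bs * px)
}

#' Alignment-versus-distance curve and Alignment AUC
#'
#' For every pair of valid subregions within `max_distance_um`, computes
#' the alignment cos 2(theta_i - theta_j) (the dot product in double-angle
#' space), bins pairs by centre distance and averages per bin. The null
#' curve repeats this after randomly repositioning the orientations over
#' the valid subregion positions (a permutation, so the orientation
#' multiset is conserved), averaged over `n_null` replicates. The
#' Alignment AUC is the trapezoidal area between the experimental and null
#' curves over distance: it quantifies how much local alignment exceeds the
#' global alignment of the same orientations.
#'
#' @param field an [orientation_field()].
#' @param bin_width_um distance bin width (micrometres).
#' @param max_distance_um maximum pair distance considered.
#' @param n_null number of repositioning replicates.
#' @param rng_seed integer seed for the permutations.
#' @param normalize divide the area by `max_distance_um^2` (off by default;
#'   the unnormalized area has units of micrometres).
#' @return An `AlignmentCurve`: list with `bin_edges_um`, `bin_centers_um`,
#'   `n_pairs`, `experimental`, `null`, `null_se`, `auc`.
#' @export
alignment_auc <- function(field, bin_width_um = 1, max_distance_um = 50,
                          n_null = 20, rng_seed = 1L, normalize = FALSE) {
  stopifnot(inherits(field, "OrientationField"))
  vidx <- which(field$valid)
  n <- length(vidx)
  if (n < 2L) stop("need at least 2 valid subregions")
  nbr <- nrow(field$theta)
  cx <- field$centers_x_um[(vidx - 1L) %/% nbr + 1L]
  cy <- field$centers_y_um[(vidx - 1L) %% nbr + 1L]
  th <- field$theta[vidx]
  u1 <- cos(2 * th); u2 <- sin(2 * th)
  nbin <- ceiling(max_distance_um / bin_width_um)
  # collect pairs within range, chunked over rows to bound memory
  ii <- integer(0); jj <- integer(0); bb <- integer(0)
  chunk <- max(1L, floor(2e6 / n))
  i0 <- 1L
  while (i0 <= n - 1L) {
    i1 <- min(n - 1L, i0 + chunk - 1L)
    rows <- i0:i1
    dx <- outer(cx[rows], cx, "-")
    dy <- outer(cy[rows], cy, "-")
    d <- sqrt(dx^2 + dy^2)
    jmat <- matrix(rep(seq_len(n), each = length(rows)), length(rows), n)
    imat <- matrix(rep(rows, times = n), length(rows), n)
    keep <- jmat > imat & d > 0 & d <= max_distance_um
    ii <- c(ii, imat[keep]); jj <- c(jj, jmat[keep])
    bb <- c(bb, pmin(ceiling(d[keep] / bin_width_um), nbin))
    i0 <- i1 + 1L
  }
  if (length(ii) == 0L) stop("no subregion pairs within max_distance_um")
  counts <- tabulate(bb, nbins = nbin)
  binned_mean <- function(perm = NULL) {
    if (is.null(perm)) {
      a <- u1[ii] * u1[jj] + u2[ii] * u2[jj]
    } else {
      a <- u1[perm[ii]] * u1[perm[jj]] + u2[perm[ii]] * u2[perm[jj]]
    }
    s <- rep(NA_real_, nbin)
    m <- rowsum(a, bb)
    s[as.integer(rownames(m))] <- m[, 1]
    s / ifelse(counts > 0, counts, NA)
  }
  expt <- binned_mean()
  null_reps <- matrix(NA_real_, n_null, nbin)
  with_seed(rng_seed, {
    for (r in seq_len(n_null)) {
      null_reps[r, ] <- binned_mean(sample.int(n))
    }
  })
  null_mean <- colMeans(null_reps)
  null_se <- apply(null_reps, 2, stats::sd) / sqrt(n_null)
  centers <- (seq_len(nbin) - 0.5) * bin_width_um
  ok <- counts > 0 & !is.na(expt) & !is.na(null_mean)
  trapz <- function(x, y) {
    if (length(x) < 2L) return(0)
    sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  }
  x <- centers[ok]
  auc <- trapz(x, expt[ok] - null_mean[ok])
  # spread of the AUC under the null: per-replicate area against the
  # null mean, used to judge whether an observed AUC is distinguishable
  # from repositioning noise
  null_aucs <- apply(null_reps, 1,
                     function(nr) trapz(x, nr[ok] - null_mean[ok]))
  null_auc_sd <- stats::sd(null_aucs) * sqrt(1 + 1 / n_null)
  if (normalize) {
    auc <- auc / max_distance_um^2
    null_auc_sd <- null_auc_sd / max_distance_um^2
  }
  structure(list(bin_edges_um = seq(0, nbin) * bin_width_um,
                 bin_centers_um = centers, n_pairs = counts,
                 experimental = expt, null = null_mean, null_se = null_se,
                 auc = auc, null_auc_sd = null_auc_sd, n_valid = n,
                 normalized = normalize),
            class = "AlignmentCurve")
}

#' @export
print.AlignmentCurve <- function(x, ...) {
  cat(sprintf("AlignmentCurve: %d valid subregions, AUC = %.4g %s\n",
              x$n_valid, x$auc, if (x$normalized) "(normalized)" else "um"))
  invisible(x)
}

#' Orientation field of a patchwise synthetic fiber field's ground truth
#'
#' Builds an [orientation_field_grid()] directly from a patchwise
#' `FiberFieldSpec` truth table (one subregion per patch subdivision),
#' useful for testing the alignment statistic against exactly known
#' orientations.
#'
#' @param ff result of [generate_fiber_field()] with patchwise mode.
#' @param subregion_um subregion edge (micrometres).
#' @return An `OrientationField` whose subregion orientations equal the
#'   generating patch orientations.
#' @export
truth_orientation_field <- function(ff, subregion_um = 3) {
  spec <- ff$spec
  if (spec$orientation_mode != "patchwise-aligned" || is.null(ff$truth$patches))
    stop("truth orientation fields require patchwise-aligned mode")
  nbr <- floor(spec$fov_height_um / subregion_um)
  nbc <- floor(spec$fov_width_um / subregion_um)
  cy <- (seq_len(nbr) - 0.5) * subregion_um
  cx <- (seq_len(nbc) - 0.5) * subregion_um
  pr <- pmin(floor(rep(cy, times = nbc) / spec$patch_size_um) + 1L,
             max(ff$truth$patches$patch_row))
  pc <- pmin(floor(rep(cx, each = nbr) / spec$patch_size_um) + 1L,
             max(ff$truth$patches$patch_col))
  po <- matrix(NA_real_, max(ff$truth$patches$patch_row),
               max(ff$truth$patches$patch_col))
  po[cbind(ff$truth$patches$patch_row, ff$truth$patches$patch_col)] <-
    ff$truth$patches$orientation_rad
  theta <- matrix(po[cbind(pr, pc)], nbr, nbc)
  orientation_field_grid(theta, matrix(TRUE, nbr, nbc), cx, cy, subregion_um)
}
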