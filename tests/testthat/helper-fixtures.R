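# Fixture builders and independent oracles used across the suite.

# Render a Gaussian-profile segment into an image (micrometre coordinates).
draw_segment <- function(img, x0, y0, x1, y1, pixel_size_um = 0.25,
                         peak = 0.9, bg = 0.05, width_um = 0.5) {
  sigma_px <- width_um / pixel_size_um / (2 * sqrt(2 * log(2)))
  ujtmorph:::.render_segment(img, x0 / pixel_size_um, y0 / pixel_size_um,
                             x1 / pixel_size_um, y1 / pixel_size_um,
                             sigma_px, bg, peak)
}

blank_image <- function(n = 320, bg = 0.05) matrix(bg, n, n)

# Four-quadrant label map with one-pixel ridges, plus a matching ridge
# image where the ridge between labels 1 and 2 can be dimmed.
quadrant_fixture <- function(n = 60, bright = 0.8, dim_ridge = NULL) {
  labels <- matrix(0L, n, n)
  h <- n %/% 2
  labels[1:(h - 1), 1:(h - 1)] <- 1L
  labels[1:(h - 1), (h + 1):n] <- 2L
  labels[(h + 1):n, 1:(h - 1)] <- 3L
  labels[(h + 1):n, (h + 1):n] <- 4L
  img <- matrix(0.1, n, n)
  img[h, ] <- bright
  img[, h] <- bright
  if (!is.null(dim_ridge)) img[1:(h - 1), h] <- dim_ridge
  list(labels = labels, image = img)
}

# Independent second-moment ellipse oracle: per-label covariance of pixel
# coordinates (plus the 1/12 per-pixel term), axis ratio from eigenvalues.
# Deliberately written with base loops/cov, separate from the package path.
oracle_ar <- function(labels) {
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  vapply(ids, function(id) {
    w <- which(labels == id, arr.ind = TRUE)
    if (nrow(w) == 1L) return(1)
    cv <- stats::cov(w) * (nrow(w) - 1) / nrow(w) + diag(2) / 12
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    sqrt(max(ev) / max(min(ev), 1e-12))
  }, numeric(1))
}

# Brute-force pairwise double-angle alignment between two orientation sets.
pairwise_alignment <- function(theta_a, theta_b) {
  ua <- cbind(cos(2 * theta_a), sin(2 * theta_a))
  ub <- cbind(cos(2 * theta_b), sin(2 * theta_b))
  mean(ua %*% t(ub))
}

expect_within <- function(object, expected, rel_tol) {
  expect_lt(abs(object - expected), rel_tol * abs(expected))
}
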