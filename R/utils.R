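# Internal helpers shared across modules.
#
# Image convention: plain numeric matrices indexed [row = y, col = x],
# intensities on [0, 1] (16-bit TIFFs are read/written through that range).
# Physical coordinates are in micrometres; pixel (r, c) has its centre at
# x = (c - 0.5) * pixel_size, y = (r - 0.5) * pixel_size.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Separable convolution with replicated-edge padding; k is an odd-length
# 1D kernel applied along rows then columns (or given separately).
sep_conv <- function(img, kx, ky = kx) {
  conv1 <- function(m, k, along) {
    h <- (length(k) - 1L) %/% 2L
    if (along == "x") {
      idx <- seq_len(ncol(m))
      out <- matrix(0, nrow(m), ncol(m))
      for (j in seq_along(k)) {
        shift <- j - 1L - h
        cols <- pmin(pmax(idx + shift, 1L), ncol(m))
        out <- out + k[j] * m[, cols, drop = FALSE]
      }
    } else {
      idx <- seq_len(nrow(m))
      out <- matrix(0, nrow(m), ncol(m))
      for (j in seq_along(k)) {
        shift <- j - 1L - h
        rows <- pmin(pmax(idx + shift, 1L), nrow(m))
        out <- out + k[j] * m[rows, , drop = FALSE]
      }
    }
    out
  }
  conv1(conv1(img, kx, "x"), ky, "y")
}

gauss_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Box mean over a (2r+1) square window, replicated edges.
box_mean <- function(img, r) {
  k <- rep(1 / (2 * r + 1), 2 * r + 1)
  sep_conv(img, k)
}

# Bilinear sampling of matrix `img` at fractional (row, col) positions
# (1-based, matrix coordinates). Out-of-range positions are clamped.
bilinear <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  img[i00] * (1 - fr) * (1 - fc) + img[i10] * fr * (1 - fc) +
    img[i01] * (1 - fr) * fc + img[i11] * fr * fc
}

# Disk structuring element of the given pixel radius (EBImage brush).
disk_brush <- function(radius) {
  size <- 2L * as.integer(radius) + 1L
  EBImage::makeBrush(size, shape = "disc")
}

# Grayscale reconstruction wrappers ---------------------------------------

reconstruct_dilate <- function(marker, mask, conn = 8L) {
  cpp_reconstruct_dilate(marker, mask, as.integer(conn))
}

# Reconstruction by erosion via duality.
reconstruct_erode <- function(marker, mask, conn = 8L) {
  -cpp_reconstruct_dilate(-marker, -mask, as.integer(conn))
}

# Suppress minima shallower than depth h (h-minima transform).
hmin_transform <- function(img, h, conn = 8L) {
  reconstruct_erode(img + h, img, conn)
}

# Polyline helpers ----------------------------------------------------------

polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# Ramer-Douglas-Peucker simplification (tol in same units as pts).
simplify_polyline <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1L]; j <- seg[2L]
    if (j - i < 2L) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a
    len2 <- sum(ab^2)
    ids <- (i + 1L):(j - 1L)
    if (len2 == 0) {
      d <- sqrt(rowSums(sweep(pts[ids, , drop = FALSE], 2L, a)^2))
    } else {
      rel <- sweep(pts[ids, , drop = FALSE], 2L, a)
      t <- (rel %*% ab) / len2
      proj <- cbind(a[1L] + t * ab[1L], a[2L] + t * ab[2L])
      d <- sqrt(rowSums((pts[ids, , drop = FALSE] - proj)^2))
    }
    k <- which.max(d)
    if (d[k] > tol) {
      m <- ids[k]
      keep[m] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, m)
      stack[[length(stack) + 1L]] <- c(m, j)
    }
  }
  pts[keep, , drop = FALSE]
}

# Axial (mod-pi) angle normalisation to [0, pi).
axial <- function(theta) {
  t <- theta %% pi
  t[t < 0] <- t[t < 0] + pi
  t
}

# Smallest angle between two axial orientations, in radians [0, pi/2].
axial_diff <- function(a, b) {
  d <- abs(axial(a) - axial(b))
  pmin(d, pi - d)
}
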