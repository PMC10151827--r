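# Stress-fiber segmentation, length statistics, orientation fields and the
# alignment-versus-distance statistic.

#' Mask segmented cell boundaries out of a fiber-plane projection
#'
#' Cortical actin at cell boundaries confounds fiber tracing in jammed
#' layers. The watershed ridge set of the basal label map, dilated to the
#' requested physical width, is set to zero intensity and flagged excluded;
#' the excluded area is subtracted from the searched area used by
#' total-length density. Applying the mask twice equals applying it once.
#'
#' @param proj fiber-plane [projection()].
#' @param lmap basal-plane `CellLabelMap` sharing the projection's geometry.
#' @param width_um total width of the masked band (micrometres).
#' @return The masked `Projection` (with an `excluded` logical matrix).
#' @export
mask_cell_boundaries <- function(proj, lmap, width_um = 1.5) {
  stopifnot(inherits(proj, "Projection"), inherits(lmap, "CellLabelMap"))
  if (!all(dim(proj$image) == dim(lmap$labels)))
    stop("projection and label map shapes differ")
  excluded <- proj$excluded
  if (is.null(excluded)) excluded <- matrix(FALSE, nrow(proj$image),
                                            ncol(proj$image))
  if (max(lmap$labels) > 0L) {
    ridge <- lmap$labels == 0L
    if (any(ridge)) {
      size <- 2L * floor(width_um / proj$pixel_size_um / 2) + 1L
      if (size > 1L) {
        ridge <- eb_mat(EBImage::dilate(
          ridge * 1, EBImage::makeBrush(size, "box"))) > 0
      }
      excluded <- excluded | ridge
    }
  }
  img <- proj$image
  img[excluded] <- 0
  projection(img, proj$plane_name, proj$pixel_size_um, slab = proj$slab,
             excluded = excluded)
}

#' Fiber tracer parameters
#'
#' @param n_orientations number of oriented ridge-filter directions.
#' @param line_length_um length of the oriented averaging line.
#' @param width_um expected fiber width (FWHM, micrometres); sets the
#'   skeleton endpoint correction (skeleton ends sit about half a stroke
#'   width inside the true fiber end) and the suppression radius.
#' @param min_length_um fragments shorter than this are discarded.
#' @param threshold binary threshold on the ridge-enhanced image, or
#'   `"otsu"` for automatic selection.
#' @param max_turn_deg maximum bend accepted when pairing skeleton arms
#'   across a junction cluster into one continuing fiber.
#' @return A `TracerParams` object.
#' @export
tracer_params <- function(n_orientations = 12L, line_length_um = 1.5,
                          width_um = 0.5, min_length_um = 1,
                          threshold = "otsu", max_turn_deg = 40) {
  structure(list(n_orientations = as.integer(n_orientations),
                 line_length_um = line_length_um, width_um = width_um,
                 min_length_um = min_length_um, threshold = threshold,
                 max_turn_deg = max_turn_deg),
            class = "TracerParams")
}

# Oriented-line ridge enhancement: maximum over rotated line-mean filters.
ridge_enhance <- function(img, n_orient, len_px) {
  len_px <- max(5L, 2L * (len_px %/% 2L) + 1L)
  half <- (len_px - 1) / 2
  resp <- matrix(-Inf, nrow(img), ncol(img))
  for (a in seq_len(n_orient)) {
    th <- (a - 1) * pi / n_orient
    t <- seq(-half, half)
    xs <- round(t * cos(th)); ys <- round(t * sin(th))
    pts <- unique(cbind(ys, xs))
    kr <- max(abs(pts[, 1])); kc <- max(abs(pts[, 2]))
    k <- matrix(0, 2 * kr + 1, 2 * kc + 1)
    k[cbind(pts[, 1] + kr + 1, pts[, 2] + kc + 1)] <- 1
    k <- k / sum(k)
    resp <- pmax(resp, eb_mat(EBImage::filter2(img, k,
                                               boundary = "replicate")))
  }
  # light smoothing regularizes the band edges left by the discretized
  # oriented kernels, which keeps the skeleton free of staircase spurs
  sep_conv(resp, gauss_kernel(1))
}

# Order the pixels of a (mostly) simple 8-connected arc by greedy walking
# from an endpoint; returns the permutation of indices.
.order_arc <- function(r, c) {
  n <- length(r)
  if (n <= 2L) return(seq_len(n))
  pts <- cbind(r, c)
  d2 <- as.matrix(stats::dist(pts))^2
  adj <- d2 <= 2 + 1e-9 & d2 > 0
  deg <- rowSums(adj)
  start <- if (any(deg <= 1)) which(deg <= 1)[1L] else which.min(r + c)
  ord <- integer(0)
  visited <- logical(n)
  cur <- start
  repeat {
    visited[cur] <- TRUE
    ord <- c(ord, cur)
    nb <- which(adj[cur, ] & !visited)
    if (length(nb) == 0L) break
    cur <- nb[which.min(d2[cur, nb])]
  }
  ord
}

# Fragment extraction from a skeleton. The skeleton is split into arcs at
# junction pixels (>= 3 neighbours); short junction-to-junction arcs are
# crossing debris (the thinning of two crossing thick strokes leaves a
# small bar between two junction clusters) and are absorbed into junction
# clusters. Arm ends incident to the same cluster are then paired by
# angular continuation - two crossing fibers pair into two straight
# chains instead of four arms - and paired arcs are concatenated across
# the cluster.
extract_chains <- function(skel, max_turn_deg, debris_px = 12) {
  nr <- nrow(skel); nc <- ncol(skel)
  on <- skel > 0
  if (!any(on)) return(list())
  max_turn <- max_turn_deg * pi / 180
  # junction pixels by the Rutovitz crossing number: >= 3 distinct strands
  # enter the pixel (robust to the 2-px staircases thinning can leave,
  # where the plain neighbour count overshoots)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- on * 1L
  shift <- function(dr, dc) p[(1:nr) + 1L + dr, (1:nc) + 1L + dc]
  ring <- list(shift(-1L, 0L), shift(-1L, 1L), shift(0L, 1L), shift(1L, 1L),
               shift(1L, 0L), shift(1L, -1L), shift(0L, -1L), shift(-1L, -1L))
  cross <- matrix(0L, nr, nc)
  cnt <- matrix(0L, nr, nc)
  for (k in 1:8) {
    nxt <- ring[[if (k == 8L) 1L else k + 1L]]
    cross <- cross + (ring[[k]] == 0L & nxt == 1L)
    cnt <- cnt + ring[[k]]
  }
  # dense crossing centres (diamonds) can keep the crossing number at 2
  # while accumulating >= 5 neighbours; catch them by neighbour count
  junction <- on & (cross >= 3L | cnt >= 5L)
  arc_lab <- cpp_label(matrix(as.integer(on & !junction), nr, nc), 8L)
  n_arc <- max(arc_lab)
  if (n_arc == 0L) return(list())
  arc_pts <- vector("list", n_arc)
  idx <- which(arc_lab > 0L)
  by_arc <- split(idx, arc_lab[idx])
  for (a in seq_len(n_arc)) {
    ai <- by_arc[[as.character(a)]]
    r <- (ai - 1L) %% nr + 1L
    c <- (ai - 1L) %/% nr + 1L
    ord <- .order_arc(r, c)
    arc_pts[[a]] <- cbind(row = r[ord], col = c[ord])
  }
  touches_junction <- function(pt) {
    rs <- max(1L, pt[1L] - 1L):min(nr, pt[1L] + 1L)
    cs <- max(1L, pt[2L] - 1L):min(nc, pt[2L] + 1L)
    any(junction[rs, cs])
  }
  n_px <- vapply(arc_pts, nrow, integer(1))
  both_j <- vapply(arc_pts, function(m) {
    touches_junction(m[1L, ]) && touches_junction(m[nrow(m), ])
  }, logical(1))
  debris <- n_px <= debris_px & both_j
  # junction clusters absorb junction pixels and crossing debris
  cmask <- junction
  for (a in which(debris)) cmask[arc_pts[[a]]] <- TRUE
  clust <- cpp_label(matrix(as.integer(cmask), nr, nc), 8L)
  arms <- which(!debris)
  # collect arm ends attached to clusters, with travel direction into the
  # cluster estimated from the last few arc pixels
  ends <- list()
  for (a in arms) {
    m <- arc_pts[[a]]
    npx <- nrow(m)
    if (npx < 2L) next
    for (e in 1:2) {
      pt <- if (e == 1L) m[1L, ] else m[npx, ]
      rs <- max(1L, pt[1L] - 1L):min(nr, pt[1L] + 1L)
      cs <- max(1L, pt[2L] - 1L):min(nc, pt[2L] + 1L)
      cl <- setdiff(unique(as.vector(clust[rs, cs])), 0L)
      if (length(cl) == 0L) next
      k <- min(6L, npx - 1L)
      q <- if (e == 1L) m[1L + k, ] else m[npx - k, ]
      dir <- atan2(pt[1L] - q[1L], pt[2L] - q[2L])
      ends[[length(ends) + 1L]] <- list(arm = a, end = e, cluster = cl[1L],
                                        dir = dir)
    }
  }
  # pair arm ends within each cluster by angular continuation
  links <- list()
  if (length(ends)) {
    by_cl <- split(seq_along(ends), vapply(ends, `[[`, 0, "cluster"))
    for (cl_ends in by_cl) {
      ne <- length(cl_ends)
      if (ne < 2L) next
      cand <- NULL
      for (i in seq_len(ne - 1L)) {
        for (j in (i + 1L):ne) {
          ei <- ends[[cl_ends[i]]]; ej <- ends[[cl_ends[j]]]
          if (ei$arm == ej$arm) next
          mis <- abs(atan2(sin(ei$dir - ej$dir - pi),
                           cos(ei$dir - ej$dir - pi)))
          if (mis <= max_turn)
            cand <- rbind(cand, c(cl_ends[i], cl_ends[j], mis))
        }
      }
      if (is.null(cand)) next
      used <- logical(length(ends))
      for (k in order(cand[, 3L], cand[, 1L], cand[, 2L])) {
        i <- cand[k, 1L]; j <- cand[k, 2L]
        if (used[i] || used[j]) next
        used[i] <- used[j] <- TRUE
        links[[length(links) + 1L]] <- c(i, j)
      }
    }
  }
  # assemble chains of arcs joined across clusters
  end_key <- function(arm, e) (match(arm, arms) - 1L) * 2L + e
  link_of <- rep(NA_integer_, 2L * length(arms))
  link_ends <- integer(0)
  for (k in seq_along(links)) {
    for (s in 1:2) {
      e <- ends[[links[[k]][s]]]
      link_of[end_key(e$arm, e$end)] <- k
    }
  }
  other_end <- function(ek) if (ek %% 2L == 0L) ek - 1L else ek + 1L
  visited <- logical(length(arms))
  chains <- list()
  for (a0 in seq_along(arms)) {
    if (visited[a0]) next
    # walk to an extremity
    cur_ek <- (a0 - 1L) * 2L + 1L
    seen <- logical(2L * length(arms))
    repeat {
      lk <- link_of[cur_ek]
      if (is.na(lk) || seen[cur_ek]) break
      seen[cur_ek] <- TRUE
      pair <- links[[lk]]
      e1 <- ends[[pair[1L]]]; e2 <- ends[[pair[2L]]]
      k1 <- end_key(e1$arm, e1$end)
      nxt <- if (k1 == cur_ek) end_key(e2$arm, e2$end) else k1
      cur_ek <- other_end(nxt)
    }
    acur <- (cur_ek - 1L) %/% 2L + 1L
    enter <- cur_ek - (acur - 1L) * 2L
    rows <- NULL
    repeat {
      visited[acur] <- TRUE
      m <- arc_pts[[arms[acur]]]
      if (enter == 2L) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
      rows <- rbind(rows, m)
      exit_ek <- (acur - 1L) * 2L + (if (enter == 1L) 2L else 1L)
      lk <- link_of[exit_ek]
      if (is.na(lk)) break
      pair <- links[[lk]]
      e1 <- ends[[pair[1L]]]; e2 <- ends[[pair[2L]]]
      k1 <- end_key(e1$arm, e1$end)
      nxt <- if (k1 == exit_ek) end_key(e2$arm, e2$end) else k1
      anxt <- (nxt - 1L) %/% 2L + 1L
      if (visited[anxt]) break
      acur <- anxt
      enter <- nxt - (anxt - 1L) * 2L
    }
    chains[[length(chains) + 1L]] <- rows
  }
  # clusters with no attached arms are compact blobs left by thinning of
  # short wide strokes: emit their pixels as a chain ordered along the
  # principal axis so short fibers are not dropped
  if (max(clust) > 0L) {
    armed <- unique(vapply(ends, `[[`, 0, "cluster"))
    for (cl in setdiff(seq_len(max(clust)), armed)) {
      ci <- which(clust == cl)
      if (length(ci) < 2L) next
      r <- (ci - 1L) %% nr + 1L
      c <- (ci - 1L) %/% nr + 1L
      rc <- r - mean(r); cc0 <- c - mean(c)
      sv <- svd(cbind(cc0, rc), nu = 0, nv = 1)
      proj <- cc0 * sv$v[1L, 1L] + rc * sv$v[2L, 1L]
      ord <- order(proj)
      chains[[length(chains) + 1L]] <- cbind(row = r[ord], col = c[ord])
    }
  }
  chains
}

#' Trace fiber fragments in a fiber-plane projection
#'
#' Ridge-enhances the image with oriented line filters, thresholds,
#' skeletonizes, and extracts fragments by walking skeleton paths. Walks
#' continue straight through skeleton junctions (so two crossing fibers are
#' traced as two straight fragments, not four arms): after a fragment is
#' extracted its pixels are suppressed and tracing re-scans the remainder,
#' bridging the small gaps the suppression leaves in crossing fibers.
#' Fragment polylines are simplified and extended by half a stroke width at
#' each end; fragments shorter than the minimum length are discarded.
#'
#' @param proj fiber-plane [projection()] (masked for the jammed condition).
#' @param params a [tracer_params()].
#' @return List of `FiberFragment` objects: each has `points_um` (polyline,
#'   x/y columns in micrometres), `length_um`, `mean_intensity`, and
#'   `end_tangents` (outward axial directions at the two ends, radians).
#' @export
trace_fragments <- function(proj, params = tracer_params()) {
  stopifnot(inherits(proj, "Projection"))
  px <- proj$pixel_size_um
  img <- proj$image
  if (all(img == img[1L])) return(list())
  resp <- ridge_enhance(img, params$n_orientations,
                        round(params$line_length_um / px))
  if (!is.null(proj$excluded)) resp[proj$excluded] <- 0
  thr <- if (identical(params$threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(clip01(resp)), range = c(0, 1))
  } else params$threshold
  bw <- matrix(as.integer(resp > thr), nrow(img), ncol(img))
  # clip a thin border: fibers leaving the field end cleanly instead of
  # growing thinning artifacts along the image edge
  bw[c(1:2, nrow(bw) - 1:0), ] <- 0L
  bw[, c(1:2, ncol(bw) - 1:0)] <- 0L
  if (sum(bw) == 0L) return(list())
  skel <- cpp_thin(bw)
  # adaptive tip extension: the end of a blurred stroke is where intensity
  # falls to half the stroke's plateau (blurred step edge), so march each
  # polyline tip along its outward tangent until the image drops below
  # half the fragment mean
  extend_tip <- function(p, tang, mean_int) {
    cut <- 0.5 * mean_int
    step <- 0.25 * px
    emax <- min(1, 3 * params$width_um)
    e <- 0
    while (e + step <= emax) {
      q <- p + (e + step) * tang
      v <- bilinear(img, q[2L] / px + 0.5, q[1L] / px + 0.5)
      if (v < cut) break
      e <- e + step
    }
    p + e * tang
  }
  # crossing debris scale: mean stroke width of the thresholded bands
  band_px <- sum(bw) / max(1L, sum(skel))
  chains <- extract_chains(skel, params$max_turn_deg,
                           debris_px = ceiling(1.5 * band_px))
  frags <- list()
  for (ch in chains) {
    if (nrow(ch) < 2L) next
    mean_int <- mean(img[ch])
    pts <- cbind(x = (ch[, "col"] - 0.5) * px, y = (ch[, "row"] - 0.5) * px)
    pts <- simplify_polyline(pts, tol = 0.9 * px)
    if (nrow(pts) < 2L) next
    # outward end tangents from the terminal polyline segments
    t1 <- pts[1L, ] - pts[2L, ]
    t2 <- pts[nrow(pts), ] - pts[nrow(pts) - 1L, ]
    t1 <- t1 / sqrt(sum(t1^2)); t2 <- t2 / sqrt(sum(t2^2))
    pts[1L, ] <- extend_tip(pts[1L, ], t1, mean_int)
    pts[nrow(pts), ] <- extend_tip(pts[nrow(pts), ], t2, mean_int)
    len <- polyline_length(pts)
    if (len < params$min_length_um) next
    frags[[length(frags) + 1L]] <- structure(
      list(points_um = pts, length_um = len, mean_intensity = mean_int,
           end_tangents = c(atan2(t1[2L], t1[1L]), atan2(t2[2L], t2[1L]))),
      class = "FiberFragment")
  }
  frags
}

#' Fragment-joining parameters
#'
#' Geometric constraints for reconnecting fiber fragments, plus an
#' intensity-continuity constraint: a candidate connection is accepted only
#' if the mean intensity sampled along the straight connector is at least
#' `intensity_ratio` times the dimmer fragment's mean intensity.
#'
#' @param max_gap_um maximum endpoint gap bridged (micrometres).
#' @param max_tangent_deg maximum mismatch between the two fragments' end
#'   tangents (degrees).
#' @param max_deviation_deg maximum deviation of the connector direction
#'   from either fragment tangent (degrees).
#' @param intensity_ratio minimum connector/fragment intensity ratio in
#'   (0, 1\].
#' @return A `JoinParams` object.
#' @export
join_params <- function(max_gap_um = 3, max_tangent_deg = 20,
                        max_deviation_deg = 20, intensity_ratio = 0.6) {
  if (max_gap_um <= 0) stop("max_gap_um must be positive")
  if (max_tangent_deg <= 0 || max_tangent_deg >= 90)
    stop("max_tangent_deg must be in (0, 90)")
  if (max_deviation_deg <= 0 || max_deviation_deg >= 90)
    stop("max_deviation_deg must be in (0, 90)")
  if (intensity_ratio <= 0 || intensity_ratio > 1)
    stop("intensity_ratio must be in (0, 1]")
  structure(list(max_gap_um = max_gap_um, max_tangent_deg = max_tangent_deg,
                 max_deviation_deg = max_deviation_deg,
                 intensity_ratio = intensity_ratio), class = "JoinParams")
}

#' Join fiber fragments into fibers
#'
#' Evaluates all fragment endpoint pairs within the gap threshold, requiring
#' near-anti-parallel end tangents, a connector direction consistent with
#' both tangents, and intensity continuity along the connector. Candidates
#' are scored (smaller gap and smaller angle mismatch are better) and
#' accepted greedily in score order with each endpoint used at most once;
#' accepted chains are concatenated into single fibers.
#'
#' @param frags list of `FiberFragment` from [trace_fragments()].
#' @param proj the intensity [projection()] connectors are sampled on.
#' @param params a [join_params()].
#' @param searched_area_um2 area searched by the tracer; defaults to the
#'   projection's non-excluded area.
#' @return A `FiberSet`: list with `fibers` (list of polylines with
#'   lengths), `n`, `searched_area_um2`, `mean_length_um`,
#'   `total_length_density_per_um`.
#' @export
join_fragments <- function(frags, proj, params = join_params(),
                           searched_area_um2 = NULL) {
  stopifnot(inherits(proj, "Projection"))
  px <- proj$pixel_size_um
  if (is.null(searched_area_um2)) {
    n_px <- length(proj$image)
    n_ex <- if (is.null(proj$excluded)) 0L else sum(proj$excluded)
    searched_area_um2 <- (n_px - n_ex) * px^2
  }
  nf <- length(frags)
  if (nf == 0L)
    return(fiber_set(list(), searched_area_um2))
  # endpoint table: fragment, end (1 = first point, 2 = last), position,
  # outward tangent
  ep <- do.call(rbind, lapply(seq_len(nf), function(i) {
    f <- frags[[i]]
    p1 <- f$points_um[1L, ]; p2 <- f$points_um[nrow(f$points_um), ]
    rbind(c(i, 1, p1[1L], p1[2L], f$end_tangents[1L]),
          c(i, 2, p2[1L], p2[2L], f$end_tangents[2L]))
  }))
  colnames(ep) <- c("frag", "end", "x", "y", "tang")
  max_t <- params$max_tangent_deg * pi / 180
  max_d <- params$max_deviation_deg * pi / 180
  cands <- list()
  ne <- nrow(ep)
  for (i in seq_len(ne - 1L)) {
    for (j in (i + 1L):ne) {
      if (ep[i, "frag"] == ep[j, "frag"]) next
      dx <- ep[j, "x"] - ep[i, "x"]; dy <- ep[j, "y"] - ep[i, "y"]
      gap <- sqrt(dx^2 + dy^2)
      if (gap > params$max_gap_um) next
      ti <- ep[i, "tang"]; tj <- ep[j, "tang"]
      # outward tangents of joinable ends point towards each other
      mis <- abs(atan2(sin(ti - (tj + pi)), cos(ti - (tj + pi))))
      if (mis > max_t) next
      if (gap > 1e-9) {
        cang <- atan2(dy, dx)
        dev_i <- abs(atan2(sin(cang - ti), cos(cang - ti)))
        dev_j <- abs(atan2(sin(cang + pi - tj), cos(cang + pi - tj)))
        if (max(dev_i, dev_j) > max_d) next
      }
      # intensity continuity along the straight connector
      fi <- frags[[ep[i, "frag"]]]; fj <- frags[[ep[j, "frag"]]]
      if (gap > px / 2) {
        ns <- max(3L, ceiling(gap / (px / 2)))
        t <- seq(0, 1, length.out = ns)
        sx <- ep[i, "x"] + t * dx; sy <- ep[i, "y"] + t * dy
        conn_int <- mean(bilinear(proj$image, sy / px + 0.5, sx / px + 0.5))
        if (conn_int < params$intensity_ratio *
            min(fi$mean_intensity, fj$mean_intensity)) next
      }
      score <- gap / params$max_gap_um + mis / max_t
      cands[[length(cands) + 1L]] <- c(i, j, score, gap)
    }
  }
  used <- logical(ne)
  links <- list()
  if (length(cands)) {
    cm <- do.call(rbind, cands)
    ord <- order(cm[, 3L], cm[, 1L], cm[, 2L])   # deterministic tie-break
    for (k in ord) {
      i <- cm[k, 1L]; j <- cm[k, 2L]
      if (used[i] || used[j]) next
      used[i] <- used[j] <- TRUE
      links[[length(links) + 1L]] <- c(i, j, cm[k, 4L])
    }
  }
  # assemble chains of fragments connected at endpoints
  link_of <- rep(NA_integer_, ne)
  for (k in seq_along(links)) {
    link_of[links[[k]][1L]] <- k
    link_of[links[[k]][2L]] <- k
  }
  ep_id <- function(frag, end) (frag - 1L) * 2L + end
  other_ep <- function(e) if (e %% 2L == 0L) e - 1L else e + 1L
  visited <- logical(nf)
  fibers <- list()
  for (f0 in seq_len(nf)) {
    if (visited[f0]) next
    # walk to one extremity of the chain
    cur_ep <- ep_id(f0, 1L)
    seen_eps <- logical(ne)
    repeat {
      le <- link_of[cur_ep]
      if (is.na(le) || seen_eps[cur_ep]) break
      seen_eps[cur_ep] <- TRUE
      lk <- links[[le]]
      nxt <- if (lk[1L] == cur_ep) lk[2L] else lk[1L]
      cur_ep <- other_ep(nxt)
    }
    # now cur_ep is a free end (or loop fallback); walk forward collecting
    chain <- list(); gaps <- 0
    fcur <- as.integer(ceiling(cur_ep / 2))
    enter_end <- cur_ep - (fcur - 1L) * 2L
    repeat {
      visited[fcur] <- TRUE
      pts <- frags[[fcur]]$points_um
      if (enter_end == 2L) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
      chain[[length(chain) + 1L]] <- pts
      exit_ep <- ep_id(fcur, if (enter_end == 1L) 2L else 1L)
      le <- link_of[exit_ep]
      if (is.na(le)) break
      lk <- links[[le]]
      nxt <- if (lk[1L] == exit_ep) lk[2L] else lk[1L]
      fnxt <- as.integer(ceiling(nxt / 2))
      if (visited[fnxt]) break
      gaps <- gaps + lk[3L]
      fcur <- fnxt
      enter_end <- nxt - (fnxt - 1L) * 2L
    }
    poly <- do.call(rbind, chain)
    lens <- vapply(chain, polyline_length, numeric(1))
    fibers[[length(fibers) + 1L]] <- list(points_um = poly,
                                          length_um = sum(lens) + gaps)
  }
  fiber_set(fibers, searched_area_um2)
}

#' Construct a FiberSet and its length metrics
#'
#' @param fibers list of fibers (each with `points_um` and `length_um`).
#' @param searched_area_um2 searched area (micrometres squared, > 0).
#' @return A `FiberSet`.
#' @export
fiber_set <- function(fibers, searched_area_um2) {
  stopifnot_scalar(searched_area_um2, "searched_area_um2")
  lens <- vapply(fibers, function(f) f$length_um, numeric(1))
  structure(list(fibers = fibers, n = length(fibers),
                 searched_area_um2 = searched_area_um2,
                 mean_length_um = if (length(lens)) mean(lens) else NA_real_,
                 total_length_density_per_um =
                   sum(lens) / searched_area_um2),
            class = "FiberSet")
}

#' @export
print.FiberSet <- function(x, ...) {
  cat(sprintf(
    "FiberSet: %d fibers, mean length %.2f um, density %.4f um^-1 over %.0f um2\n",
    x$n, x$mean_length_um, x$total_length_density_per_um,
    x$searched_area_um2))
  invisible(x)
}

#' Mean fiber length and total-length density
#'
#' Mean length is the unweighted mean over fibers (missing for an empty
#' set); total-length density is the summed length divided by the searched
#' area (units 1/um), 0 for an empty set.
#'
#' @param fs a `FiberSet`.
#' @return Named list: `mean_length_um`, `total_length_density_per_um`.
#' @export
length_metrics <- function(fs) {
  stopifnot(inherits(fs, "FiberSet"))
  if (fs$searched_area_um2 <= 0) stop("searched area must be positive")
  list(mean_length_um = fs$mean_length_um,
       total_length_density_per_um = fs$total_length_density_per_um)
}
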