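#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pixel neighbourhood offsets. conn = 4 or 8.
static const int DR8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DC8[8] = {0, 0, -1, 1, -1, 1, -1, 1};

// ---------------------------------------------------------------------------
// Grayscale reconstruction by dilation of `marker` under `mask`
// (marker <= mask everywhere). Hybrid algorithm: raster + anti-raster sweep,
// then FIFO queue propagation. Used for opening/closing by reconstruction
// and for h-extrema suppression.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilate(NumericMatrix marker, NumericMatrix mask,
                                     int conn = 8) {
  int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask must have identical dimensions");
  int nnb = (conn == 4) ? 4 : 8;
  NumericMatrix J(clone(marker));

  // raster scan (N, W and upper diagonals are "previous" neighbours)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = J(r, c);
      if (r > 0 && J(r - 1, c) > v) v = J(r - 1, c);
      if (c > 0 && J(r, c - 1) > v) v = J(r, c - 1);
      if (nnb == 8) {
        if (r > 0 && c > 0 && J(r - 1, c - 1) > v) v = J(r - 1, c - 1);
        if (r < nr - 1 && c > 0 && J(r + 1, c - 1) > v) v = J(r + 1, c - 1);
      }
      J(r, c) = std::min(v, mask(r, c));
    }
  }
  // anti-raster scan + queue seeding
  std::queue<int> fifo;
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      double v = J(r, c);
      if (r < nr - 1 && J(r + 1, c) > v) v = J(r + 1, c);
      if (c < nc - 1 && J(r, c + 1) > v) v = J(r, c + 1);
      if (nnb == 8) {
        if (r < nr - 1 && c < nc - 1 && J(r + 1, c + 1) > v) v = J(r + 1, c + 1);
        if (r > 0 && c < nc - 1 && J(r - 1, c + 1) > v) v = J(r - 1, c + 1);
      }
      J(r, c) = std::min(v, mask(r, c));
      // queue pixels that could still propagate
      for (int k = 0; k < nnb; ++k) {
        int rr = r + DR8[k], cc = c + DC8[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (J(rr, cc) < J(r, c) && J(rr, cc) < mask(rr, cc)) {
          fifo.push(r + c * nr);
          break;
        }
      }
    }
  }
  while (!fifo.empty()) {
    int p = fifo.front(); fifo.pop();
    int r = p % nr, c = p / nr;
    for (int k = 0; k < nnb; ++k) {
      int rr = r + DR8[k], cc = c + DC8[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (J(rr, cc) < J(r, c) && mask(rr, cc) != J(rr, cc)) {
        double v = std::min(J(r, c), mask(rr, cc));
        if (v > J(rr, cc)) {
          J(rr, cc) = v;
          fifo.push(rr + cc * nr);
        }
      }
    }
  }
  return J;
}

// ---------------------------------------------------------------------------
// Label connected plateaus that are regional minima (no neighbour below the
// plateau value). Returns integer matrix: 0 = not a minimum, >0 = minimum id.
// [[Rcpp::export]]
IntegerMatrix cpp_regional_minima(NumericMatrix img, int conn = 8) {
  int nr = img.nrow(), nc = img.ncol();
  int nnb = (conn == 4) ? 4 : 8;
  IntegerMatrix lab(nr, nc);            // 0 unvisited
  std::vector<int> state(nr * nc, 0);   // 0 unvisited, 1 visited
  int next = 0;
  std::vector<int> plateau;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      int p0 = r0 + c0 * nr;
      if (state[p0]) continue;
      // flood the plateau of equal value containing (r0, c0)
      double v = img(r0, c0);
      bool is_min = true;
      plateau.clear();
      std::queue<int> q;
      q.push(p0);
      state[p0] = 1;
      while (!q.empty()) {
        int p = q.front(); q.pop();
        plateau.push_back(p);
        int r = p % nr, c = p / nr;
        for (int k = 0; k < nnb; ++k) {
          int rr = r + DR8[k], cc = c + DC8[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          double w = img(rr, cc);
          if (w < v) { is_min = false; continue; }
          if (w == v && !state[rr + cc * nr]) {
            state[rr + cc * nr] = 1;
            q.push(rr + cc * nr);
          }
        }
      }
      if (is_min) {
        ++next;
        for (size_t i = 0; i < plateau.size(); ++i) {
          lab(plateau[i] % nr, plateau[i] / nr) = next;
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Marker-controlled watershed by Meyer flooding with watershed lines.
// `surface` is the topographic relief (catchment basins grow uphill from the
// markers); `markers` holds positive seed labels, 0 elsewhere. Pixels
// reachable from two different basins at the same flood level become ridge
// pixels and keep label 0. Basins grow with `conn` connectivity (4 keeps
// regions 4-connected, leaving 8-connected ridges).
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix surface, IntegerMatrix markers,
                            int conn = 4) {
  int nr = surface.nrow(), nc = surface.ncol();
  if (markers.nrow() != nr || markers.ncol() != nc)
    stop("surface and markers must have identical dimensions");
  int nnb = (conn == 4) ? 4 : 8;
  IntegerMatrix lab(clone(markers));
  // priority queue ordered by (height, insertion order) for determinism
  typedef std::pair<double, long long> Key; // height, order-encoded pixel
  std::priority_queue<std::pair<Key, int>,
                      std::vector<std::pair<Key, int> >,
                      std::greater<std::pair<Key, int> > > pq;
  long long order = 0;
  std::vector<char> queued(nr * nc, 0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0) {
        for (int k = 0; k < nnb; ++k) {
          int rr = r + DR8[k], cc = c + DC8[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          int p = rr + cc * nr;
          if (lab(rr, cc) == 0 && !queued[p]) {
            queued[p] = 1;
            pq.push(std::make_pair(Key(surface(rr, cc), order++), p));
          }
        }
      }
  while (!pq.empty()) {
    int p = pq.top().second; pq.pop();
    int r = p % nr, c = p / nr;
    if (lab(r, c) != 0) continue;
    // examine labelled neighbours
    int l = 0; bool ridge = false;
    for (int k = 0; k < nnb; ++k) {
      int rr = r + DR8[k], cc = c + DC8[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int ln = lab(rr, cc);
      if (ln > 0) {
        if (l == 0) l = ln;
        else if (ln != l) ridge = true;
      }
    }
    if (ridge || l == 0) {
      lab(r, c) = ridge ? -1 : 0;  // -1 = watershed line
      continue;
    }
    lab(r, c) = l;
    for (int k = 0; k < nnb; ++k) {
      int rr = r + DR8[k], cc = c + DC8[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int q = rr + cc * nr;
      if (lab(rr, cc) == 0 && !queued[q]) {
        queued[q] = 1;
        pq.push(std::make_pair(Key(surface(rr, cc), order++), q));
      }
    }
  }
  // watershed lines back to 0
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) < 0) lab(r, c) = 0;
  return lab;
}

// ---------------------------------------------------------------------------
// Zhang-Suen morphological thinning of a binary image to an 8-connected
// skeleton one pixel wide.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix bw) {
  int nr = bw.nrow(), nc = bw.ncol();
  IntegerMatrix img(clone(bw));
  std::vector<int> kill;
  bool changed = true;
  // neighbours in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW)
  const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 1; c < nc - 1; ++c) {
        for (int r = 1; r < nr - 1; ++r) {
          if (!img(r, c)) continue;
          int p[8];
          for (int k = 0; k < 8; ++k) p[k] = img(r + dr[k], c + dc[k]) ? 1 : 0;
          int b = p[0] + p[1] + p[2] + p[3] + p[4] + p[5] + p[6] + p[7];
          if (b < 2 || b > 6) continue;
          int a = 0;
          for (int k = 0; k < 8; ++k) if (!p[k] && p[(k + 1) % 8]) ++a;
          if (a != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          kill.push_back(r + c * nr);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t i = 0; i < kill.size(); ++i)
          img(kill[i] % nr, kill[i] / nr) = 0;
      }
    }
  }
  return img;
}

// ---------------------------------------------------------------------------
// Connected-component labelling of a binary image.
// [[Rcpp::export]]
IntegerMatrix cpp_label(IntegerMatrix bw, int conn = 8) {
  int nr = bw.nrow(), nc = bw.ncol();
  int nnb = (conn == 4) ? 4 : 8;
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<int> q;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!bw(r0, c0) || lab(r0, c0)) continue;
      lab(r0, c0) = ++next;
      q.push(r0 + c0 * nr);
      while (!q.empty()) {
        int p = q.front(); q.pop();
        int r = p % nr, c = p / nr;
        for (int k = 0; k < nnb; ++k) {
          int rr = r + DR8[k], cc = c + DC8[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (bw(rr, cc) && !lab(rr, cc)) {
            lab(rr, cc) = next;
            q.push(rr + cc * nr);
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Nearest-seed (Voronoi) assignment of pixel centres to seed points in a
// possibly anisotropic metric: distances are measured after dividing x by
// `xscale`. Coordinates are in pixel units; seeds given as (x, y) pairs.
// Returns 1-based seed index per pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_nearest_seed(int nr, int nc, NumericVector sx,
                               NumericVector sy, double xscale) {
  int ns = sx.size();
  IntegerMatrix lab(nr, nc);
  for (int c = 0; c < nc; ++c) {
    double px = (c + 0.5) / xscale;
    for (int r = 0; r < nr; ++r) {
      double py = r + 0.5;
      double best = R_PosInf; int bi = 0;
      for (int i = 0; i < ns; ++i) {
        double dx = px - sx[i] / xscale, dy = py - sy[i];
        double d = dx * dx + dy * dy;
        if (d < best) { best = d; bi = i + 1; }
      }
      lab(r, c) = bi;
    }
  }
  return lab;
}
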