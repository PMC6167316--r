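#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Geodesic (within-mask) distance transform by chamfer propagation.
//
// Distances are measured in pixel units from the set of source pixels,
// with paths constrained to stay inside the mask.  A 5x5 chamfer
// neighbourhood is used (weights 1, sqrt(2), sqrt(5)); knight moves are
// only admissible when at least one intermediate pixel is inside the
// mask, and diagonal moves require an adjacent orthogonal pixel inside
// the mask, so paths cannot tunnel through one-pixel walls.  Forward and
// backward raster passes are repeated until convergence, which handles
// concave masks.  Pixels outside the mask get NA.
// [[Rcpp::export]]
NumericMatrix chamfer_geodesic(LogicalMatrix mask, LogicalMatrix sources) {
  const int nr = mask.nrow(), nc = mask.ncol();
  if (sources.nrow() != nr || sources.ncol() != nc)
    stop("mask and sources must have identical dimensions");

  const double W1 = 1.0, W2 = std::sqrt(2.0), W3 = std::sqrt(5.0);
  NumericMatrix d(nr, nc);
  std::vector<char> msk((size_t) nr * nc);
  double *dd = REAL(d);

  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      size_t i = (size_t) r + (size_t) c * nr;
      msk[i] = mask(r, c) ? 1 : 0;
      if (!msk[i]) { dd[i] = NA_REAL; continue; }
      dd[i] = sources(r, c) ? 0.0 : R_PosInf;
    }

  auto in = [&](int r, int c) {
    return r >= 0 && r < nr && c >= 0 && c < nc &&
      msk[(size_t) r + (size_t) c * nr];
  };
  auto D = [&](int r, int c) -> double & {
    return dd[(size_t) r + (size_t) c * nr];
  };

  // Offsets relative to (r, c); im1/im2 are intermediate pixels a legal
  // path must be able to pass through (-1 row/col meaning "no check").
  struct Move { int dr, dc; double w; int ir1, ic1, ir2, ic2; };
  const Move fwd[] = {
    { 0, -1, W1, -9, -9, -9, -9},
    {-1,  0, W1, -9, -9, -9, -9},
    {-1, -1, W2,  0, -1, -1,  0},
    {-1,  1, W2,  0,  1, -1,  0},
    {-1, -2, W3,  0, -1, -1, -1},
    {-2, -1, W3, -1,  0, -1, -1},
    {-2,  1, W3, -1,  0, -1,  1},
    {-1,  2, W3,  0,  1, -1,  1}
  };
  const int nmove = 8;

  bool changed = true;
  int iter = 0;
  while (changed && iter < 256) {
    changed = false;
    ++iter;
    // forward pass
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < nc; ++c) {
        if (!in(r, c)) continue;
        double best = D(r, c);
        for (int k = 0; k < nmove; ++k) {
          const Move &m = fwd[k];
          int rr = r + m.dr, cc = c + m.dc;
          if (!in(rr, cc)) continue;
          if (m.ir1 != -9 &&
              !in(r + m.ir1, c + m.ic1) && !in(r + m.ir2, c + m.ic2))
            continue;
          double cand = D(rr, cc) + m.w;
          if (cand < best) best = cand;
        }
        if (best < D(r, c)) { D(r, c) = best; changed = true; }
      }
    // backward pass (mirrored offsets)
    for (int r = nr - 1; r >= 0; --r)
      for (int c = nc - 1; c >= 0; --c) {
        if (!in(r, c)) continue;
        double best = D(r, c);
        for (int k = 0; k < nmove; ++k) {
          const Move &m = fwd[k];
          int rr = r - m.dr, cc = c - m.dc;
          if (!in(rr, cc)) continue;
          if (m.ir1 != -9 &&
              !in(r - m.ir1, c - m.ic1) && !in(r - m.ir2, c - m.ic2))
            continue;
          double cand = D(rr, cc) + m.w;
          if (cand < best) best = cand;
        }
        if (best < D(r, c)) { D(r, c) = best; changed = true; }
      }
  }
  return d;
}

// Connected-component labelling of a binary mask (4- or 8-connectivity),
// flood fill with an explicit stack.  Labels are assigned in raster order
// of each component's first pixel, starting at 1; background is 0.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[] = {-1, 0, 0, 1};
  const int dc4[] = {0, -1, 1, 0};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = connectivity;

  int next = 0;
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc2 = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int rr = cr + dr[k], ccn = cc2 + dc[k];
          if (rr < 0 || rr >= nr || ccn < 0 || ccn >= nc) continue;
          if (mask(rr, ccn) && lab(rr, ccn) == 0) {
            lab(rr, ccn) = next;
            stack.push_back(rr + ccn * nr);
          }
        }
      }
    }
  return lab;
}
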