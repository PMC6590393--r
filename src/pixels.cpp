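#include <Rcpp.h>
#include <deque>
#include <unordered_map>
using namespace Rcpp;

// 8-connected component labelling of a binary raster.
// Returns an integer matrix with 0 for background and 1..n for components.
// [[Rcpp::export]]
IntegerMatrix cf_label_components(const IntegerMatrix& img) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::deque<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (img(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.clear();
      q.push_back(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop_front();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ii = p.first + di, jj = p.second + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (img(ii, jj) != 0 && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              q.push_back(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Moore-neighbour boundary trace of a single 8-connected foreground
// component. Starts at the topmost pixel of the leftmost occupied column and
// walks clockwise; returns ordered (row, col) 1-based coordinates of the
// outer boundary, first pixel not repeated at the end.
// [[Rcpp::export]]
IntegerMatrix cf_trace_boundary(const IntegerMatrix& img) {
  const int nr = img.nrow(), nc = img.ncol();
  int si = -1, sj = -1;
  for (int j = 0; j < nc && si < 0; ++j)
    for (int i = 0; i < nr; ++i)
      if (img(i, j) != 0) { si = i; sj = j; break; }
  if (si < 0) stop("blank image");
  // clockwise Moore neighbourhood, starting west
  const int di[8] = {  0, -1, -1, -1,  0,  1,  1,  1 };
  const int dj[8] = { -1, -1,  0,  1,  1,  1,  0, -1 };
  std::vector<int> ri, rj;
  int ci = si, cj = sj;
  int backtrack = 0; // came from the west (background by construction)
  ri.push_back(ci); rj.push_back(cj);
  for (;;) {
    int k = (backtrack + 1) % 8, found = -1;
    for (int t = 0; t < 8; ++t, k = (k + 1) % 8) {
      int ii = ci + di[k], jj = cj + dj[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc || img(ii, jj) == 0) continue;
      found = k;
      break;
    }
    if (found < 0) break; // isolated pixel
    int pi = ci, pj = cj;
    ci += di[found]; cj += dj[found];
    if (ci == si && cj == sj) break;
    ri.push_back(ci); rj.push_back(cj);
    // new backtrack: direction from current pixel to the neighbour we
    // examined just before the foreground hit
    int prevk = (found + 7) % 8;
    int bi = pi + di[prevk] - ci, bj = pj + dj[prevk] - cj;
    backtrack = 0;
    for (int t = 0; t < 8; ++t)
      if (di[t] == bi && dj[t] == bj) { backtrack = t; break; }
    if ((int)ri.size() > 4 * (nr * nc)) stop("boundary trace did not close");
  }
  IntegerMatrix out(ri.size(), 2);
  for (size_t t = 0; t < ri.size(); ++t) {
    out(t, 0) = ri[t] + 1;
    out(t, 1) = rj[t] + 1;
  }
  return out;
}

// Per-box foreground masses for one (box size, grid offset) combination.
// xs, ys are 0-based pixel coordinates relative to the scan origin; the grid
// is anchored at -(ox, oy) so boxes are [k*size - ox, (k+1)*size - ox).
// Returns the multiset of masses of nonempty boxes (unordered). Dense
// accumulation over the box lattice of the bounding region.
// [[Rcpp::export]]
IntegerVector cf_box_masses(const IntegerVector& xs, const IntegerVector& ys,
                            int size, int ox, int oy) {
  const int n = xs.size();
  int xmax = 0, ymax = 0;
  for (int t = 0; t < n; ++t) {
    if (xs[t] > xmax) xmax = xs[t];
    if (ys[t] > ymax) ymax = ys[t];
  }
  const int nbx = (xmax + ox) / size + 1;
  const int nby = (ymax + oy) / size + 1;
  std::vector<int> acc((size_t)nbx * nby, 0);
  for (int t = 0; t < n; ++t)
    acc[(size_t)((xs[t] + ox) / size) * nby + (ys[t] + oy) / size] += 1;
  int nonempty = 0;
  for (size_t i = 0; i < acc.size(); ++i) if (acc[i]) ++nonempty;
  IntegerVector out(nonempty);
  int t = 0;
  for (size_t i = 0; i < acc.size(); ++i) if (acc[i]) out[t++] = acc[i];
  return out;
}

// Local window counts around sampled pixels: total foreground in the window
// (LFD) and foreground 8-connected to the window centre within the window
// (LCFD). radii are half-widths; window side = 2*r + 1, clipped at edges.
// px, py are 1-based (row, col). Returns two n x length(radii) matrices.
// [[Rcpp::export]]
List cf_local_fd_counts(const IntegerMatrix& img, const IntegerVector& px,
                        const IntegerVector& py, const IntegerVector& radii) {
  const int nr = img.nrow(), nc = img.ncol();
  const int n = px.size(), m = radii.size();
  IntegerMatrix lfd(n, m), lcfd(n, m);
  int rmax = 0;
  for (int w = 0; w < m; ++w) if (radii[w] > rmax) rmax = radii[w];
  const int side = 2 * rmax + 1;
  std::vector<char> vis(side * side);
  std::deque<int> q;
  for (int s = 0; s < n; ++s) {
    const int ci = px[s] - 1, cj = py[s] - 1;
    for (int w = 0; w < m; ++w) {
      const int r = radii[w];
      const int i0 = std::max(0, ci - r), i1 = std::min(nr - 1, ci + r);
      const int j0 = std::max(0, cj - r), j1 = std::min(nc - 1, cj + r);
      int tot = 0;
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          if (img(i, j) != 0) ++tot;
      lfd(s, w) = tot;
      // flood fill from centre restricted to this window
      const int wi = i1 - i0 + 1, wj = j1 - j0 + 1;
      std::fill(vis.begin(), vis.begin() + wi * wj, 0);
      int conn = 0;
      if (img(ci, cj) != 0) {
        q.clear();
        q.push_back((ci - i0) + (cj - j0) * wi);
        vis[(ci - i0) + (cj - j0) * wi] = 1;
        conn = 1;
        while (!q.empty()) {
          int idx = q.front(); q.pop_front();
          int li = idx % wi, lj = idx / wi;
          for (int dj = -1; dj <= 1; ++dj) {
            for (int di = -1; di <= 1; ++di) {
              int ii = li + di, jj = lj + dj;
              if (ii < 0 || ii >= wi || jj < 0 || jj >= wj) continue;
              int id2 = ii + jj * wi;
              if (vis[id2]) continue;
              if (img(i0 + ii, j0 + jj) != 0) {
                vis[id2] = 1;
                ++conn;
                q.push_back(id2);
              }
            }
          }
        }
      }
      lcfd(s, w) = conn;
    }
  }
  return List::create(Named("lfd") = lfd, Named("lcfd") = lcfd);
}
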