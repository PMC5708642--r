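#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Pixel neighbourhood offsets. R matrices are column-major; all scan orders
// below are column-major rasters, which fixes every tie-break deterministically.
static const int DR8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DC8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
static const int DR4[4] = {-1, 1, 0, 0};
static const int DC4[4] = {0, 0, -1, 1};

static inline void neighbours(int conn, const int*& dr, const int*& dc, int& nn) {
  if (conn == 4) { dr = DR4; dc = DC4; nn = 4; } else { dr = DR8; dc = DC8; nn = 8; }
}

// Greyscale morphological reconstruction by dilation of `marker` under `mask`
// (marker <= mask elementwise), hybrid raster/queue algorithm.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilate(NumericMatrix marker, NumericMatrix mask, int conn = 8) {
  int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask dimensions differ");
  NumericMatrix J(clone(marker));
  const int *dr, *dc; int nn;
  neighbours(conn, dr, dc, nn);

  // forward raster scan (column-major): propagate from already-visited neighbours
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = J(r, c);
      for (int k = 0; k < nn; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        // visited in column-major order iff cc < c, or cc == c and rr < r
        if (cc > c || (cc == c && rr >= r)) continue;
        if (J(rr, cc) > v) v = J(rr, cc);
      }
      if (v > mask(r, c)) v = mask(r, c);
      J(r, c) = v;
    }
  }

  // backward scan + seed the FIFO queue
  std::queue<int> q;
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      double v = J(r, c);
      for (int k = 0; k < nn; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (cc < c || (cc == c && rr <= r)) continue;
        if (J(rr, cc) > v) v = J(rr, cc);
      }
      if (v > mask(r, c)) v = mask(r, c);
      J(r, c) = v;
      for (int k = 0; k < nn; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (cc < c || (cc == c && rr <= r)) continue;
        if (J(rr, cc) < J(r, c) && J(rr, cc) < mask(rr, cc)) {
          q.push(c * nr + r);
          break;
        }
      }
    }
  }

  while (!q.empty()) {
    int p = q.front(); q.pop();
    int r = p % nr, c = p / nr;
    double vp = J(r, c);
    for (int k = 0; k < nn; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (J(rr, cc) < vp && J(rr, cc) < mask(rr, cc)) {
        double nv = vp < mask(rr, cc) ? vp : mask(rr, cc);
        if (nv > J(rr, cc)) {
          J(rr, cc) = nv;
          q.push(cc * nr + rr);
        }
      }
    }
  }
  return J;
}

// Connected-component labelling of a logical matrix; ids assigned in
// column-major discovery order starting at 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix x, int conn = 8) {
  int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);
  const int *dr, *dc; int nn;
  neighbours(conn, dr, dc, nn);
  int next = 0;
  std::queue<int> q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!x(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push(c * nr + r);
      while (!q.empty()) {
        int p = q.front(); q.pop();
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < nn; ++k) {
          int rr = pr + dr[k], cc = pc + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (x(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(cc * nr + rr);
          }
        }
      }
    }
  }
  return lab;
}

struct PFNode {
  double prio;
  std::uint64_t order;
  int idx;
};
struct PFCompare {
  bool operator()(const PFNode& a, const PFNode& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;
    return a.order > b.order; // FIFO on equal priority
  }
};

// Marker-controlled watershed by priority flooding: every mask pixel is
// assigned the label of the seed whose flood reaches it first on the given
// landscape. No dam/watershed-line pixels are produced. Mask pixels not
// geodesically reachable from any seed (seedless mask islands) are assigned
// afterwards by a breadth-first expansion of the labelled set across the
// whole frame.
// [[Rcpp::export]]
IntegerMatrix cpp_marker_watershed(NumericMatrix landscape, IntegerMatrix seeds,
                                   LogicalMatrix mask, int conn = 8) {
  int nr = landscape.nrow(), nc = landscape.ncol();
  if (seeds.nrow() != nr || seeds.ncol() != nc || mask.nrow() != nr || mask.ncol() != nc)
    stop("landscape, seeds and mask dimensions differ");
  IntegerMatrix lab(nr, nc);
  const int *dr, *dc; int nn;
  neighbours(conn, dr, dc, nn);
  std::priority_queue<PFNode, std::vector<PFNode>, PFCompare> pq;
  std::uint64_t counter = 0;

  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0 && mask(r, c)) {
        lab(r, c) = seeds(r, c);
        pq.push({landscape(r, c), counter++, c * nr + r});
      }

  while (!pq.empty()) {
    PFNode nd = pq.top(); pq.pop();
    int r = nd.idx % nr, c = nd.idx / nr;
    int lp = lab(r, c);
    for (int k = 0; k < nn; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (!mask(rr, cc) || lab(rr, cc) != 0) continue;
      lab(rr, cc) = lp;
      double p = landscape(rr, cc);
      if (p < nd.prio) p = nd.prio; // flood level never recedes
      pq.push({p, counter++, cc * nr + rr});
    }
  }

  // second pass for seedless mask islands: geodesic BFS over the full frame
  bool leftover = false;
  for (int i = 0; i < nr * nc && !leftover; ++i)
    if (mask[i] && lab[i] == 0) leftover = true;
  if (leftover) {
    std::vector<int> carrier(nr * nc, 0);
    std::queue<int> q;
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r)
        if (lab(r, c) != 0) {
          carrier[c * nr + r] = lab(r, c);
          q.push(c * nr + r);
        }
    while (!q.empty()) {
      int p = q.front(); q.pop();
      int r = p % nr, c = p / nr;
      for (int k = 0; k < nn; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int pi = cc * nr + rr;
        if (carrier[pi] != 0) continue;
        carrier[pi] = carrier[p];
        q.push(pi);
        if (mask(rr, cc)) lab(rr, cc) = carrier[pi];
      }
    }
  }
  return lab;
}
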