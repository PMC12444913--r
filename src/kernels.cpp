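#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 8-neighbourhood offsets
static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Prominence-based maxima detection.
//
// A pixel is a reported maximum iff no strictly higher pixel can be reached
// from it along a path whose values stay >= value - prominence. Maxima of
// equal value that lie within each other's tolerance region merge into one
// reported point, placed at the centroid of the equal-value (plateau) pixels
// and snapped to the nearest plateau pixel. Maxima whose plateau touches the
// image border are suppressed (so a constant image yields no maxima).
//
// Candidates (pixels with no strictly higher 8-neighbour) are processed in
// decreasing value order; each accepted flood region is marked "owned" so
// lower candidates inside it are skipped, and touching an owned region from
// below implies a strictly higher reachable pixel (equal-valued connected
// candidates would already be owned), hence rejection.
// [[Rcpp::export]]
List cpp_find_maxima(NumericMatrix x, double prominence) {
  const int nr = x.nrow(), nc = x.ncol(), n = nr * nc;
  std::vector<int> cand;
  cand.reserve(n / 4);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = x(i, j);
      bool ok = true;
      for (int k = 0; k < 8 && ok; ++k) {
        int ii = i + DR[k], jj = j + DC[k];
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc && x(ii, jj) > v) ok = false;
      }
      if (ok) cand.push_back(i + j * nr);
    }
  }
  // sort by value descending; ties row-major (row, then col)
  std::stable_sort(cand.begin(), cand.end(), [&](int a, int b) {
    double va = x[a], vb = x[b];
    if (va != vb) return va > vb;
    int ra = a % nr, ca = a / nr, rb = b % nr, cb = b / nr;
    if (ra != rb) return ra < rb;
    return ca < cb;
  });

  std::vector<char> owned(n, 0), dead(n, 0);
  std::vector<int> vis(n, -1);
  std::vector<int> stack, flooded, plateau;
  std::vector<int> out_r, out_c;

  for (size_t ci = 0; ci < cand.size(); ++ci) {
    int c0 = cand[ci];
    if (owned[c0] || dead[c0]) continue;
    double v = x[c0];
    int stamp = (int)ci;
    stack.clear(); flooded.clear(); plateau.clear();
    stack.push_back(c0); vis[c0] = stamp;
    bool reject = false, border = false;
    while (!stack.empty() && !reject) {
      int p = stack.back(); stack.pop_back();
      flooded.push_back(p);
      int i = p % nr, j = p / nr;
      if (x[p] == v) {
        plateau.push_back(p);
        if (i == 0 || i == nr - 1 || j == 0 || j == nc - 1) border = true;
      }
      for (int k = 0; k < 8; ++k) {
        int ii = i + DR[k], jj = j + DC[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        int q = ii + jj * nr;
        if (vis[q] == stamp) continue;
        double vq = x[q];
        if (vq > v) { reject = true; break; }
        if (vq >= v - prominence) {
          if (owned[q]) { reject = true; break; }
          vis[q] = stamp;
          stack.push_back(q);
        }
      }
    }
    if (reject) {
      // equal-valued candidates inside this flood share the same reach set
      // and would be rejected identically; skip them later
      for (size_t t = 0; t < plateau.size(); ++t) dead[plateau[t]] = 1;
      continue;
    }
    for (size_t t = 0; t < flooded.size(); ++t) owned[flooded[t]] = 1;
    if (border) continue;
    // centroid of plateau, snapped to nearest plateau pixel (tie: row-major)
    double mr = 0, mc = 0;
    for (size_t t = 0; t < plateau.size(); ++t) {
      mr += plateau[t] % nr;
      mc += plateau[t] / nr;
    }
    mr /= plateau.size(); mc /= plateau.size();
    double best = -1; int bi = -1, bj = -1;
    for (size_t t = 0; t < plateau.size(); ++t) {
      int i = plateau[t] % nr, j = plateau[t] / nr;
      double d = (i - mr) * (i - mr) + (j - mc) * (j - mc);
      if (bi < 0 || d < best - 1e-12 ||
          (std::abs(d - best) <= 1e-12 && (i < bi || (i == bi && j < bj)))) {
        best = d; bi = i; bj = j;
      }
    }
    out_r.push_back(bi + 1);
    out_c.push_back(bj + 1);
  }

  IntegerMatrix pts(out_r.size(), 2);
  for (size_t t = 0; t < out_r.size(); ++t) { pts(t, 0) = out_r[t]; pts(t, 1) = out_c[t]; }
  return List::create(_["points"] = pts);
}

struct QNode {
  double val; long long seq; int idx; int lab;
};
struct QCmp {
  bool operator()(const QNode &a, const QNode &b) const {
    if (a.val != b.val) return a.val < b.val;  // max-heap on value
    return a.seq > b.seq;                      // FIFO on ties
  }
};

// Flood descent from seed pixels: every pixel is assigned the label of the
// seed whose flood (always expanding from the currently highest frontier
// pixel) reaches it first. Partitions the full image when >= 1 seed exists.
// [[Rcpp::export]]
IntegerMatrix cpp_flood_segments(NumericMatrix x, IntegerMatrix seeds) {
  const int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<QNode, std::vector<QNode>, QCmp> pq;
  long long seq = 0;
  for (int s = 0; s < seeds.nrow(); ++s) {
    int i = seeds(s, 0) - 1, j = seeds(s, 1) - 1;
    lab(i, j) = s + 1;
    pq.push(QNode{x(i, j), seq++, i + j * nr, s + 1});
  }
  while (!pq.empty()) {
    QNode nd = pq.top(); pq.pop();
    int i = nd.idx % nr, j = nd.idx / nr;
    for (int k = 0; k < 8; ++k) {
      int ii = i + DR[k], jj = j + DC[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (lab(ii, jj) == 0) {
        lab(ii, jj) = nd.lab;
        pq.push(QNode{x(ii, jj), seq++, ii + jj * nr, nd.lab});
      }
    }
  }
  return lab;
}

// 8-connected components of `mask`; when `key` is supplied, two foreground
// pixels connect only if their key values are equal (used to keep maxima
// segments from merging across watershed boundaries).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, Nullable<IntegerMatrix> key = R_NilValue) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  bool has_key = key.isNotNull();
  IntegerMatrix k_;
  if (has_key) k_ = IntegerMatrix(key);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int t = 0; t < 8; ++t) {
          int ii = pi + DR[t], jj = pj + DC[t];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (!mask(ii, jj) || lab(ii, jj) != 0) continue;
          if (has_key && k_(ii, jj) != k_(pi, pj)) continue;
          lab(ii, jj) = next;
          stack.push_back(ii + jj * nr);
        }
      }
    }
  }
  return lab;
}

// Grayscale erosion (op = 0) or dilation (op = 1) with a structuring
// function given as offset lists (dr, dc) and heights h. Out-of-bounds
// offsets are ignored (restriction to the image domain keeps the
// erosion/dilation pair an adjunction, so dilate(erode(x)) is an opening).
// [[Rcpp::export]]
NumericMatrix cpp_gray_morph(NumericMatrix x, IntegerVector dr, IntegerVector dc,
                             NumericVector h, int op) {
  const int nr = x.nrow(), nc = x.ncol(), m = dr.size();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), op == 0 ? R_PosInf : R_NegInf);
  for (int t = 0; t < m; ++t) {
    int di = dr[t], dj = dc[t];
    if (op == 1) { di = -di; dj = -dj; }
    double ht = h[t];
    int i0 = std::max(0, -di), i1 = std::min(nr, nr - di);
    int j0 = std::max(0, -dj), j1 = std::min(nc, nc - dj);
    for (int j = j0; j < j1; ++j) {
      for (int i = i0; i < i1; ++i) {
        double v = x(i + di, j + dj);
        if (op == 0) {
          v -= ht;
          if (v < out(i, j)) out(i, j) = v;
        } else {
          v += ht;
          if (v > out(i, j)) out(i, j) = v;
        }
      }
    }
  }
  return out;
}
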