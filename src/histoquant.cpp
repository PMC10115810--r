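#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Offsets for 4- and 8-connectivity.
static const int DR8[8] = {-1,-1,-1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1,-1, 1,-1, 0, 1};
static const int DR4[4] = {-1, 1, 0, 0};
static const int DC4[4] = { 0, 0,-1, 1};

// Grayscale erosion with a non-flat structuring element given as offset
// lists (dr, dc) and heights h: out(p) = min over k of img(p + off_k) - h_k.
// Offsets falling outside the image are ignored (treated as +inf).
// [[Rcpp::export]]
NumericMatrix cpp_gray_erode(NumericMatrix img, IntegerVector dr,
                             IntegerVector dc, NumericVector h) {
  int nr = img.nrow(), nc = img.ncol(), K = dr.size();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double m = std::numeric_limits<double>::infinity();
      for (int k = 0; k < K; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        double v = img(rr, cc) - h[k];
        if (v < m) m = v;
      }
      out(r, c) = m;
    }
  }
  return out;
}

// Grayscale dilation, dual of cpp_gray_erode: max of img(p - off_k) + h_k.
// [[Rcpp::export]]
NumericMatrix cpp_gray_dilate(NumericMatrix img, IntegerVector dr,
                              IntegerVector dc, NumericVector h) {
  int nr = img.nrow(), nc = img.ncol(), K = dr.size();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double m = -std::numeric_limits<double>::infinity();
      for (int k = 0; k < K; ++k) {
        int rr = r - dr[k], cc = c - dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        double v = img(rr, cc) + h[k];
        if (v > m) m = v;
      }
      out(r, c) = m;
    }
  }
  return out;
}

// Connected-component labeling of a logical mask (BFS), connectivity 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int *dR = connectivity == 8 ? DR8 : DR4;
  const int *dC = connectivity == 8 ? DC8 : DC4;
  int nn = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < nn; ++k) {
          int rr = pr + dR[k], cc = pc + dC[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * nr);
          }
        }
      }
    }
  }
  return lab;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance of each foreground pixel to the nearest
// background pixel. Background pixels get 0. All-foreground input yields Inf.
// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix fg) {
  int nr = fg.nrow(), nc = fg.ncol();
  NumericMatrix d(nr, nc);
  // large finite sentinel: true infinity produces NaN in the parabola
  // intersection (Inf - Inf) and corrupts the lower envelope
  double INF = 1e30;
  std::vector<double> f(std::max(nr, nc)), out(std::max(nr, nc));
  // pass 1: columns
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = fg(r, c) ? INF : 0.0;
    dt1d(f, out, nr);
    for (int r = 0; r < nr; ++r) d(r, c) = out[r];
  }
  // pass 2: rows
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = d(r, c);
    dt1d(f, out, nc);
    for (int c = 0; c < nc; ++c) d(r, c) = out[c];
  }
  return d;
}

struct QItem {
  double prio;   // larger floods first
  long long ord; // FIFO tie-break for determinism
  int idx;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.prio != b.prio) return a.prio < b.prio;
    return a.ord > b.ord;
  }
};

// Marker-controlled watershed by priority flooding (Meyer). `prio` is the
// flooding priority (Euclidean distance: high floods first), `markers` holds
// positive seed labels, `mask` restricts flooding to foreground. Pixels where
// distinct labels meet become watershed lines (returned as -1).
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix prio, IntegerMatrix markers,
                            LogicalMatrix mask) {
  int nr = prio.nrow(), nc = prio.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> q;
  long long ord = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      lab(r, c) = markers(r, c);
  // seed the queue with unlabeled mask pixels adjacent to a marker
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      bool adj = false;
      for (int k = 0; k < 8 && !adj; ++k) {
        int rr = r + DR8[k], cc = c + DC8[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (lab(rr, cc) > 0) adj = true;
      }
      if (adj) q.push({prio(r, c), ord++, r + c * nr});
    }
  }
  while (!q.empty()) {
    QItem it = q.top(); q.pop();
    int r = it.idx % nr, c = it.idx / nr;
    if (lab(r, c) != 0) continue;
    int found = 0;
    bool conflict = false;
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR8[k], cc = c + DC8[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int l = lab(rr, cc);
      if (l > 0) {
        if (found == 0) found = l;
        else if (l != found) conflict = true;
      }
    }
    if (conflict) {
      lab(r, c) = -1; // watershed line
    } else if (found > 0) {
      lab(r, c) = found;
      for (int k = 0; k < 8; ++k) {
        int rr = r + DR8[k], cc = c + DC8[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (mask(rr, cc) && lab(rr, cc) == 0)
          q.push({prio(rr, cc), ord++, rr + cc * nr});
      }
    }
  }
  return lab;
}

// Regional maxima of `v` within `mask`, plateau-aware. Returns a label image
// where each regional-maximum plateau has a distinct positive label.
// [[Rcpp::export]]
IntegerMatrix cpp_regional_maxima(NumericMatrix v, LogicalMatrix mask) {
  int nr = v.nrow(), nc = v.ncol();
  IntegerMatrix lab(nr, nc);
  IntegerMatrix seen(nr, nc);
  std::vector<int> stack, plateau;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || seen(r, c)) continue;
      double val = v(r, c);
      bool is_max = true;
      stack.clear(); plateau.clear();
      stack.push_back(r + c * nr);
      seen(r, c) = 1;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        plateau.push_back(p);
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < 8; ++k) {
          int rr = pr + DR8[k], cc = pc + DC8[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          double nv = mask(rr, cc) ? v(rr, cc) : 0.0;
          if (nv > val) is_max = false;
          if (mask(rr, cc) && nv == val && !seen(rr, cc)) {
            seen(rr, cc) = 1;
            stack.push_back(rr + cc * nr);
          }
        }
      }
      if (is_max) {
        ++next;
        for (size_t i = 0; i < plateau.size(); ++i)
          lab[plateau[i]] = next;
      }
    }
  }
  return lab;
}

// Separable 1-D convolution along rows (dim = 1, i.e. vertical) or columns
// (dim = 2, horizontal) with reflect boundary handling.
// [[Rcpp::export]]
NumericMatrix cpp_conv1d(NumericMatrix img, NumericVector kern, int dim) {
  int nr = img.nrow(), nc = img.ncol(), K = kern.size();
  int half = (K - 1) / 2;
  NumericMatrix out(nr, nc);
  if (dim == 1) {
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        double s = 0;
        for (int k = 0; k < K; ++k) {
          int rr = r + k - half;
          if (rr < 0) rr = -rr - 1;
          if (rr >= nr) rr = 2 * nr - rr - 1;
          s += img(rr, c) * kern[k];
        }
        out(r, c) = s;
      }
    }
  } else {
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        double s = 0;
        for (int k = 0; k < K; ++k) {
          int cc = c + k - half;
          if (cc < 0) cc = -cc - 1;
          if (cc >= nc) cc = 2 * nc - cc - 1;
          s += img(r, cc) * kern[k];
        }
        out(r, c) = s;
      }
    }
  }
  return out;
}

// Block reduction by integer factor. op = 0 mean, 1 min, 2 max.
// Trailing partial blocks are reduced over the available pixels.
// [[Rcpp::export]]
NumericMatrix cpp_block_reduce(NumericMatrix img, int factor, int op) {
  int nr = img.nrow(), nc = img.ncol();
  int onr = (nr + factor - 1) / factor, onc = (nc + factor - 1) / factor;
  NumericMatrix out(onr, onc);
  for (int oc = 0; oc < onc; ++oc) {
    for (int orr = 0; orr < onr; ++orr) {
      int r0 = orr * factor, c0 = oc * factor;
      int r1 = std::min(r0 + factor, nr), c1 = std::min(c0 + factor, nc);
      double acc = (op == 1) ? std::numeric_limits<double>::infinity()
                 : (op == 2) ? -std::numeric_limits<double>::infinity() : 0.0;
      int n = 0;
      for (int c = c0; c < c1; ++c) {
        for (int r = r0; r < r1; ++r) {
          double v = img(r, c);
          if (op == 0) acc += v;
          else if (op == 1) acc = std::min(acc, v);
          else acc = std::max(acc, v);
          ++n;
        }
      }
      out(orr, oc) = (op == 0) ? acc / n : acc;
    }
  }
  return out;
}

// Bilinear resize to (onr, onc), aligning pixel centers of the two grids.
// [[Rcpp::export]]
NumericMatrix cpp_bilinear_resize(NumericMatrix img, int onr, int onc) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(onr, onc);
  double sr = (double)nr / onr, sc = (double)nc / onc;
  for (int oc = 0; oc < onc; ++oc) {
    double x = (oc + 0.5) * sc - 0.5;
    int c0 = (int)std::floor(x);
    double fx = x - c0;
    int c1 = c0 + 1;
    if (c0 < 0) { c0 = 0; c1 = 0; fx = 0; }
    if (c1 >= nc) { c1 = nc - 1; if (c0 >= nc) c0 = nc - 1; }
    for (int orr = 0; orr < onr; ++orr) {
      double y = (orr + 0.5) * sr - 0.5;
      int r0 = (int)std::floor(y);
      double fy = y - r0;
      int r1 = r0 + 1;
      if (r0 < 0) { r0 = 0; r1 = 0; fy = 0; }
      if (r1 >= nr) { r1 = nr - 1; if (r0 >= nr) r0 = nr - 1; }
      out(orr, oc) =
        (1 - fy) * ((1 - fx) * img(r0, c0) + fx * img(r0, c1)) +
        fy       * ((1 - fx) * img(r1, c0) + fx * img(r1, c1));
    }
  }
  return out;
}

// Burn filled disks (inner_px = 0) or annular rims (inner_px > 0) into a
// logical image. Centers in 0-based pixel coordinates (row, col), radii in px.
// [[Rcpp::export]]
LogicalMatrix cpp_draw_disks(int nr, int nc, NumericVector row_px,
                             NumericVector col_px, NumericVector rad_px,
                             NumericVector inner_px) {
  LogicalMatrix out(nr, nc);
  int N = row_px.size();
  for (int i = 0; i < N; ++i) {
    double cr = row_px[i], cc = col_px[i], R = rad_px[i], Ri = inner_px[i];
    int r0 = std::max(0, (int)std::floor(cr - R)), r1 = std::min(nr - 1, (int)std::ceil(cr + R));
    int c0 = std::max(0, (int)std::floor(cc - R)), c1 = std::min(nc - 1, (int)std::ceil(cc + R));
    double R2 = R * R, Ri2 = Ri * Ri;
    for (int c = c0; c <= c1; ++c) {
      for (int r = r0; r <= r1; ++r) {
        double d2 = (r - cr) * (r - cr) + (c - cc) * (c - cc);
        if (d2 <= R2 && d2 >= Ri2) out(r, c) = true;
      }
    }
  }
  return out;
}

// Per-label pixel count and centroid (0-based row/col sums) in one pass.
// Returns a matrix with columns: label, count, sum_row, sum_col.
// [[Rcpp::export]]
NumericMatrix cpp_label_stats(IntegerMatrix lab, int nlab) {
  std::vector<double> cnt(nlab + 1, 0), sr(nlab + 1, 0), sc(nlab + 1, 0);
  int nr = lab.nrow(), nc = lab.ncol();
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l > 0 && l <= nlab) { cnt[l]++; sr[l] += r; sc[l] += c; }
    }
  NumericMatrix out(nlab, 4);
  for (int l = 1; l <= nlab; ++l) {
    out(l - 1, 0) = l;
    out(l - 1, 1) = cnt[l];
    out(l - 1, 2) = sr[l];
    out(l - 1, 3) = sc[l];
  }
  return out;
}
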