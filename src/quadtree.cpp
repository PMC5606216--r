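// Quad-tree spatial index used twice per simulation tick: Barnes-Hut
// approximation of the many-body charge force, and neighbor queries for the
// post-tick collision-resolution pass. Bucketed leaves (up to 8 points) with
// a depth limit keep coincident points from subdividing forever.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct QuadTree {
  static const int BUCKET = 8;
  static const int MAXDEPTH = 32;

  const double *X, *Y;
  int n;

  std::vector<std::array<int, 4>> child; // -1 = none
  std::vector<std::vector<int>> pts;     // leaf buckets
  std::vector<char> leaf;
  std::vector<double> cx0, cy0, csz;     // cell bounds (squares)
  std::vector<int> cnt;                  // points in subtree
  std::vector<double> sx, sy;            // coordinate sums (for COM)

  int new_cell(double x0, double y0, double sz) {
    child.push_back({-1, -1, -1, -1});
    pts.emplace_back();
    leaf.push_back(1);
    cx0.push_back(x0); cy0.push_back(y0); csz.push_back(sz);
    cnt.push_back(0); sx.push_back(0.0); sy.push_back(0.0);
    return (int)child.size() - 1;
  }

  QuadTree(const double *x, const double *y, int n_) : X(x), Y(y), n(n_) {
    double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
    for (int i = 0; i < n; i++) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
    }
    if (n == 0) { xmin = ymin = 0; xmax = ymax = 1; }
    double sz = std::max(xmax - xmin, ymax - ymin);
    if (sz <= 0) sz = 1.0;
    sz *= 1.0 + 1e-9;
    new_cell(xmin, ymin, sz);
    for (int i = 0; i < n; i++) insert(0, i, 0);
  }

  void insert(int c, int i, int depth) {
    cnt[c] += 1; sx[c] += X[i]; sy[c] += Y[i];
    if (leaf[c]) {
      pts[c].push_back(i);
      if ((int)pts[c].size() > BUCKET && depth < MAXDEPTH) split(c, depth);
      return;
    }
    descend(c, i, depth);
  }

  void split(int c, int depth) {
    leaf[c] = 0;
    std::vector<int> moved;
    moved.swap(pts[c]);
    for (int i : moved) descend(c, i, depth);
  }

  void descend(int c, int i, int depth) {
    double half = csz[c] / 2.0;
    int qx = (X[i] >= cx0[c] + half) ? 1 : 0;
    int qy = (Y[i] >= cy0[c] + half) ? 1 : 0;
    int q = qy * 2 + qx;
    if (child[c][q] < 0) {
      child[c][q] = new_cell(cx0[c] + qx * half, cy0[c] + qy * half, half);
    }
    insert(child[c][q], i, depth + 1);
  }
};

// Accumulate the Barnes-Hut force on point i into (fx, fy).
void bh_accum(const QuadTree &t, int c, int i, double theta, double &fx, double &fy) {
  if (t.cnt[c] == 0) return;
  double xi = t.X[i], yi = t.Y[i];
  if (!t.leaf[c]) {
    double mx = t.sx[c] / t.cnt[c], my = t.sy[c] / t.cnt[c];
    double dx = xi - mx, dy = yi - my;
    double d2 = dx * dx + dy * dy;
    if (d2 > 0 && t.csz[c] * t.csz[c] < theta * theta * d2) {
      // opening criterion s/d < theta: treat the whole cell as one body at
      // its center of mass (the subtree may contain i itself only when the
      // criterion fails, because then d >= s/theta > 0 excludes i's cell)
      double inv = 1.0 / d2;
      fx += t.cnt[c] * dx * inv;
      fy += t.cnt[c] * dy * inv;
      return;
    }
    for (int q = 0; q < 4; q++)
      if (t.child[c][q] >= 0) bh_accum(t, t.child[c][q], i, theta, fx, fy);
    return;
  }
  for (int j : t.pts[c]) {
    if (j == i) continue;
    double dx = xi - t.X[j], dy = yi - t.Y[j];
    double d2 = dx * dx + dy * dy;
    if (d2 < 1e-18) continue; // coincident points exert no deterministic force
    double inv = 1.0 / d2;
    fx += dx * inv;
    fy += dy * inv;
  }
}

// Collect points within radius `rad` of (px, py).
void range_query(const QuadTree &t, int c, double px, double py, double rad,
                 std::vector<int> &out) {
  if (t.cnt[c] == 0) return;
  // reject cells farther than rad from the query point
  double x0 = t.cx0[c], y0 = t.cy0[c], s = t.csz[c];
  double dx = std::max({x0 - px, 0.0, px - (x0 + s)});
  double dy = std::max({y0 - py, 0.0, py - (y0 + s)});
  if (dx * dx + dy * dy > rad * rad) return;
  if (t.leaf[c]) {
    for (int j : t.pts[c]) {
      double ddx = t.X[j] - px, ddy = t.Y[j] - py;
      if (ddx * ddx + ddy * ddy <= rad * rad) out.push_back(j);
    }
    return;
  }
  for (int q = 0; q < 4; q++)
    if (t.child[c][q] >= 0) range_query(t, t.child[c][q], px, py, rad, out);
}

void overlap_pairs_impl(const double *x, const double *y, const double *r,
                        int n, double padding,
                        std::vector<int> &pi, std::vector<int> &pj) {
  QuadTree t(x, y, n);
  double rmax = 0.0;
  for (int i = 0; i < n; i++) rmax = std::max(rmax, r[i]);
  std::vector<int> hits;
  for (int i = 0; i < n; i++) {
    hits.clear();
    range_query(t, 0, x[i], y[i], r[i] + rmax + padding, hits);
    for (int j : hits) {
      if (j <= i) continue;
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double lim = r[i] + r[j] + padding;
      if (dx * dx + dy * dy < lim * lim) { pi.push_back(i); pj.push_back(j); }
    }
  }
  // deterministic processing order
  std::vector<int> ord(pi.size());
  for (size_t k = 0; k < ord.size(); k++) ord[k] = (int)k;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (pi[a] != pi[b]) return pi[a] < pi[b];
    return pj[a] < pj[b];
  });
  std::vector<int> qi(pi.size()), qj(pj.size());
  for (size_t k = 0; k < ord.size(); k++) { qi[k] = pi[ord[k]]; qj[k] = pj[ord[k]]; }
  pi.swap(qi); pj.swap(qj);
}

} // namespace

// [[Rcpp::export(name = ".bh_repulsion")]]
NumericMatrix bh_repulsion(NumericVector x, NumericVector y, double k, double theta) {
  int n = x.size();
  NumericMatrix F(n, 2);
  if (n < 2 || k == 0.0) return F;
  QuadTree t(REAL(x), REAL(y), n);
  for (int i = 0; i < n; i++) {
    double fx = 0.0, fy = 0.0;
    bh_accum(t, 0, i, theta, fx, fy);
    F(i, 0) = k * fx;
    F(i, 1) = k * fy;
  }
  return F;
}

// [[Rcpp::export(name = ".pairwise_repulsion")]]
NumericMatrix pairwise_repulsion(NumericVector x, NumericVector y, double k) {
  // exact all-pairs summation; reference path for theta = 0 and small n
  int n = x.size();
  NumericMatrix F(n, 2);
  for (int i = 0; i < n; i++) {
    double fx = 0.0, fy = 0.0;
    for (int j = 0; j < n; j++) {
      if (j == i) continue;
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < 1e-18) continue;
      fx += dx / d2;
      fy += dy / d2;
    }
    F(i, 0) = k * fx;
    F(i, 1) = k * fy;
  }
  return F;
}

// [[Rcpp::export(name = ".overlap_pairs")]]
IntegerMatrix overlap_pairs(NumericVector x, NumericVector y, NumericVector r,
                            double padding) {
  std::vector<int> pi, pj;
  overlap_pairs_impl(REAL(x), REAL(y), REAL(r), x.size(), padding, pi, pj);
  IntegerMatrix out(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); k++) {
    out(k, 0) = pi[k] + 1;
    out(k, 1) = pj[k] + 1;
  }
  return out;
}

// [[Rcpp::export(name = ".resolve_collisions_cpp")]]
List resolve_collisions_cpp(NumericVector x, NumericVector y, NumericVector r,
                            double padding, double repulsive,
                            LogicalVector pinned) {
  int n = x.size();
  NumericVector nx = clone(x), ny = clone(y);
  LogicalVector moved(n);
  if (repulsive <= 0.0 || n < 2) {
    return List::create(_["x"] = nx, _["y"] = ny, _["moved"] = moved);
  }
  std::vector<int> pi, pj;
  overlap_pairs_impl(REAL(x), REAL(y), REAL(r), n, padding, pi, pj);
  for (size_t k = 0; k < pi.size(); k++) {
    int i = pi[k], j = pj[k];
    if (pinned[i] && pinned[j]) continue;
    double dx = nx[i] - nx[j], dy = ny[i] - ny[j];
    double d = std::sqrt(dx * dx + dy * dy);
    double minsep = r[i] + r[j] + padding;
    if (d >= minsep - 1e-12) continue; // resolved by an earlier displacement
    double ux, uy;
    if (d < 1e-9) { ux = 1.0; uy = 0.0; } // coincident: deterministic +x axis
    else { ux = dx / d; uy = dy / d; }
    double overlap = minsep - d;
    double si, sj; // displacement shares along the center line
    if (pinned[i]) { si = 0.0; sj = repulsive * overlap; }
    else if (pinned[j]) { si = repulsive * overlap; sj = 0.0; }
    else { si = sj = repulsive * overlap / 2.0; }
    nx[i] += si * ux; ny[i] += si * uy;
    nx[j] -= sj * ux; ny[j] -= sj * uy;
    if (si > 0) moved[i] = TRUE;
    if (sj > 0) moved[j] = TRUE;
  }
  return List::create(_["x"] = nx, _["y"] = ny, _["moved"] = moved);
}
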