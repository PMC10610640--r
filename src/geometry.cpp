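// Computational-geometry kernels: 3D convex hull (incremental), 2D Delaunay
// (Bowyer-Watson), linear TIN interpolation with point location, and k-nearest
// neighbour mean distances on a uniform grid. Self-contained on purpose: the
// target runtime has no qhull/Delaunay/kNN R package available.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <set>
#include <utility>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 sub(const Vec3& a, const Vec3& b) {
  Vec3 r; r.x = a.x - b.x; r.y = a.y - b.y; r.z = a.z - b.z; return r;
}
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  Vec3 r;
  r.x = a.y * b.z - a.z * b.y;
  r.y = a.z * b.x - a.x * b.z;
  r.z = a.x * b.y - a.y * b.x;
  return r;
}
inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

struct HullFace {
  int a, b, c;
  bool alive;
};

// signed distance (not normalised) of p from plane of face (fa,fb,fc)
inline double plane_side(const std::vector<Vec3>& P, int fa, int fb, int fc,
                         const Vec3& p) {
  Vec3 n = cross(sub(P[fb], P[fa]), sub(P[fc], P[fa]));
  return dot(n, sub(p, P[fa]));
}

}  // namespace

// Incremental 3D convex hull. Returns hull volume, the triangular faces
// (1-based row indices into X, outward-oriented), and the hull vertex ids.
// [[Rcpp::export]]
List cpp_hull3d(NumericMatrix X) {
  const int n = X.nrow();
  if (X.ncol() != 3) stop("expected an N x 3 coordinate matrix");
  if (n < 4)
    stop("degenerate geometry: convex hull needs >= 4 points, got %d", n);

  std::vector<Vec3> P(n);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    P[i].x = X(i, 0); P[i].y = X(i, 1); P[i].z = X(i, 2);
    if (!R_finite(P[i].x) || !R_finite(P[i].y) || !R_finite(P[i].z))
      stop("non-finite coordinate at row %d", i + 1);
    double c[3] = {P[i].x, P[i].y, P[i].z};
    for (int d = 0; d < 3; ++d) {
      if (c[d] < lo[d]) lo[d] = c[d];
      if (c[d] > hi[d]) hi[d] = c[d];
    }
  }
  const double span = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2]});
  const double tol = 1e-10 * std::max(span, 1.0);

  // initial simplex: extreme in x, farthest point, farthest from line,
  // farthest from plane
  int i0 = 0;
  for (int i = 1; i < n; ++i)
    if (P[i].x < P[i0].x) i0 = i;
  int i1 = -1; double best = tol;
  for (int i = 0; i < n; ++i) {
    double d = norm(sub(P[i], P[i0]));
    if (d > best) { best = d; i1 = i; }
  }
  if (i1 < 0) stop("degenerate geometry: all %d points coincide", n);
  int i2 = -1; best = tol;
  Vec3 dir = sub(P[i1], P[i0]);
  for (int i = 0; i < n; ++i) {
    double d = norm(cross(dir, sub(P[i], P[i0]))) / norm(dir);
    if (d > best) { best = d; i2 = i; }
  }
  if (i2 < 0) stop("degenerate geometry: all %d points collinear", n);
  int i3 = -1; best = tol;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(plane_side(P, i0, i1, i2, P[i]));
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) stop("degenerate geometry: all %d points coplanar", n);

  Vec3 inner;  // interior reference point: simplex centroid
  inner.x = (P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4.0;
  inner.y = (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4.0;
  inner.z = (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4.0;

  std::vector<HullFace> faces;
  auto add_face = [&](int a, int b, int c) {
    // orient outward (inner point on negative side)
    if (plane_side(P, a, b, c, inner) > 0.0) std::swap(b, c);
    HullFace f; f.a = a; f.b = b; f.c = c; f.alive = true;
    faces.push_back(f);
  };
  add_face(i0, i1, i2);
  add_face(i0, i1, i3);
  add_face(i0, i2, i3);
  add_face(i1, i2, i3);

  std::vector<int> order;
  order.reserve(n);
  for (int i = 0; i < n; ++i)
    if (i != i0 && i != i1 && i != i2 && i != i3) order.push_back(i);

  std::vector<int> visible;
  for (size_t oi = 0; oi < order.size(); ++oi) {
    const int pi = order[oi];
    visible.clear();
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      Vec3 nrm = cross(sub(P[faces[f].b], P[faces[f].a]),
                       sub(P[faces[f].c], P[faces[f].a]));
      double nl = norm(nrm);
      if (nl <= 0) continue;
      double d = dot(nrm, sub(P[pi], P[faces[f].a])) / nl;
      if (d > tol) visible.push_back((int)f);
    }
    if (visible.empty()) continue;  // interior point
    // horizon = directed edges of visible faces whose reverse is absent
    std::set<std::pair<int, int> > edges;
    for (size_t v = 0; v < visible.size(); ++v) {
      const HullFace& f = faces[visible[v]];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int k = 0; k < 3; ++k)
        edges.insert(std::make_pair(e[k][0], e[k][1]));
    }
    for (size_t v = 0; v < visible.size(); ++v) faces[visible[v]].alive = false;
    for (std::set<std::pair<int, int> >::iterator it = edges.begin();
         it != edges.end(); ++it) {
      if (edges.count(std::make_pair(it->second, it->first))) continue;
      add_face(it->first, it->second, pi);
    }
  }

  double vol = 0.0;
  int nf = 0;
  for (size_t f = 0; f < faces.size(); ++f)
    if (faces[f].alive) ++nf;
  IntegerMatrix F(nf, 3);
  std::set<int> verts;
  int r = 0;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    const HullFace& fc = faces[f];
    Vec3 a = sub(P[fc.a], inner), b = sub(P[fc.b], inner),
         c = sub(P[fc.c], inner);
    vol += dot(a, cross(b, c)) / 6.0;
    F(r, 0) = fc.a + 1; F(r, 1) = fc.b + 1; F(r, 2) = fc.c + 1;
    verts.insert(fc.a + 1); verts.insert(fc.b + 1); verts.insert(fc.c + 1);
    ++r;
  }
  return List::create(_["volume"] = vol, _["faces"] = F,
                      _["vertices"] = IntegerVector(verts.begin(), verts.end()));
}

namespace {

struct DTri {
  int a, b, c;
  double cx, cy, r2;
  bool alive;
};

inline bool circumcircle(double ax, double ay, double bx, double by,
                         double cx_, double cy_, DTri& t) {
  double d = 2.0 * (ax * (by - cy_) + bx * (cy_ - ay) + cx_ * (ay - by));
  if (std::fabs(d) < 1e-300) return false;
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by,
         c2 = cx_ * cx_ + cy_ * cy_;
  t.cx = (a2 * (by - cy_) + b2 * (cy_ - ay) + c2 * (ay - by)) / d;
  t.cy = (a2 * (cx_ - bx) + b2 * (ax - cx_) + c2 * (bx - ax)) / d;
  double dx = ax - t.cx, dy = ay - t.cy;
  t.r2 = dx * dx + dy * dy;
  return true;
}

}  // namespace

// Bowyer-Watson Delaunay triangulation of 2D points (assumed deduplicated).
// Returns an M x 3 matrix of 1-based vertex indices.
// [[Rcpp::export]]
IntegerMatrix cpp_delaunay(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (y.size() != n) stop("x and y lengths differ");
  if (n < 3) stop("degenerate geometry: need >= 3 points for triangulation");

  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    if (!R_finite(x[i]) || !R_finite(y[i])) stop("non-finite coordinate");
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }
  double span = std::max({xmax - xmin, ymax - ymin, 1.0});
  double midx = 0.5 * (xmin + xmax), midy = 0.5 * (ymin + ymax);

  std::vector<double> px(n + 3), py(n + 3);
  for (int i = 0; i < n; ++i) { px[i] = x[i]; py[i] = y[i]; }
  // large enclosing super-triangle
  px[n] = midx - 20.0 * span; py[n] = midy - 10.0 * span;
  px[n + 1] = midx + 20.0 * span; py[n + 1] = midy - 10.0 * span;
  px[n + 2] = midx; py[n + 2] = midy + 20.0 * span;

  std::vector<DTri> tris;
  {
    DTri t; t.a = n; t.b = n + 1; t.c = n + 2; t.alive = true;
    if (!circumcircle(px[t.a], py[t.a], px[t.b], py[t.b], px[t.c], py[t.c], t))
      stop("internal error: degenerate super-triangle");
    tris.push_back(t);
  }
  const double eps = 1e-12 * span * span;

  std::vector<int> bad;
  std::map<std::pair<int, int>, int> edge_count;
  for (int i = 0; i < n; ++i) {
    bad.clear();
    edge_count.clear();
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      double dx = px[i] - tris[t].cx, dy = py[i] - tris[t].cy;
      if (dx * dx + dy * dy <= tris[t].r2 + eps) bad.push_back((int)t);
    }
    if (bad.empty()) continue;  // duplicate point: leave triangulation as is
    for (size_t b = 0; b < bad.size(); ++b) {
      const DTri& t = tris[bad[b]];
      int e[3][2] = {{t.a, t.b}, {t.b, t.c}, {t.c, t.a}};
      for (int k = 0; k < 3; ++k) {
        std::pair<int, int> key(std::min(e[k][0], e[k][1]),
                                std::max(e[k][0], e[k][1]));
        edge_count[key]++;
      }
      tris[bad[b]].alive = false;
    }
    for (std::map<std::pair<int, int>, int>::iterator it = edge_count.begin();
         it != edge_count.end(); ++it) {
      if (it->second != 1) continue;  // interior edge of the cavity
      DTri t; t.a = it->first.first; t.b = it->first.second; t.c = i;
      t.alive = circumcircle(px[t.a], py[t.a], px[t.b], py[t.b],
                             px[t.c], py[t.c], t);
      if (t.alive) tris.push_back(t);
    }
  }

  int m = 0;
  for (size_t t = 0; t < tris.size(); ++t)
    if (tris[t].alive && tris[t].a < n && tris[t].b < n && tris[t].c < n) ++m;
  if (m == 0) stop("degenerate geometry: all points collinear");
  IntegerMatrix out(m, 3);
  int r = 0;
  for (size_t t = 0; t < tris.size(); ++t) {
    if (!(tris[t].alive && tris[t].a < n && tris[t].b < n && tris[t].c < n))
      continue;
    out(r, 0) = tris[t].a + 1;
    out(r, 1) = tris[t].b + 1;
    out(r, 2) = tris[t].c + 1;
    ++r;
  }
  return out;
}

// Linear interpolation on a TIN. Queries outside the triangulation get NA.
// Returns per-query interpolated z and the (1-based) containing triangle row.
// [[Rcpp::export]]
List cpp_tin_interp(NumericVector x, NumericVector y, NumericVector z,
                    IntegerMatrix tri, NumericVector qx, NumericVector qy) {
  const int nt = tri.nrow();
  const int nq = qx.size();
  NumericVector zi(nq, NA_REAL);
  IntegerVector ti(nq, NA_INTEGER);
  if (nt == 0) return List::create(_["z"] = zi, _["tri"] = ti);

  // uniform grid over triangle bounding boxes
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < x.size(); ++i) {
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }
  const int G = std::max(1, std::min(128, (int)std::sqrt((double)nt)));
  const double gx = std::max(xmax - xmin, 1e-12) / G;
  const double gy = std::max(ymax - ymin, 1e-12) / G;
  std::vector<std::vector<int> > cells(G * G);
  for (int t = 0; t < nt; ++t) {
    int a = tri(t, 0) - 1, b = tri(t, 1) - 1, c = tri(t, 2) - 1;
    double tx0 = std::min({x[a], x[b], x[c]}), tx1 = std::max({x[a], x[b], x[c]});
    double ty0 = std::min({y[a], y[b], y[c]}), ty1 = std::max({y[a], y[b], y[c]});
    int cx0 = std::max(0, std::min(G - 1, (int)((tx0 - xmin) / gx)));
    int cx1 = std::max(0, std::min(G - 1, (int)((tx1 - xmin) / gx)));
    int cy0 = std::max(0, std::min(G - 1, (int)((ty0 - ymin) / gy)));
    int cy1 = std::max(0, std::min(G - 1, (int)((ty1 - ymin) / gy)));
    for (int ix = cx0; ix <= cx1; ++ix)
      for (int iy = cy0; iy <= cy1; ++iy)
        cells[ix * G + iy].push_back(t);
  }

  const double span = std::max({xmax - xmin, ymax - ymin, 1.0});
  const double btol = -1e-9 * span;
  for (int q = 0; q < nq; ++q) {
    if (!R_finite(qx[q]) || !R_finite(qy[q])) continue;
    int ix = std::max(0, std::min(G - 1, (int)((qx[q] - xmin) / gx)));
    int iy = std::max(0, std::min(G - 1, (int)((qy[q] - ymin) / gy)));
    const std::vector<int>& cand = cells[ix * G + iy];
    for (size_t k = 0; k < cand.size(); ++k) {
      int t = cand[k];
      int a = tri(t, 0) - 1, b = tri(t, 1) - 1, c = tri(t, 2) - 1;
      double d = (y[b] - y[c]) * (x[a] - x[c]) + (x[c] - x[b]) * (y[a] - y[c]);
      if (std::fabs(d) < 1e-300) continue;
      double l1 = ((y[b] - y[c]) * (qx[q] - x[c]) +
                   (x[c] - x[b]) * (qy[q] - y[c])) / d;
      double l2 = ((y[c] - y[a]) * (qx[q] - x[c]) +
                   (x[a] - x[c]) * (qy[q] - y[c])) / d;
      double l3 = 1.0 - l1 - l2;
      if (l1 >= btol && l2 >= btol && l3 >= btol) {
        zi[q] = l1 * z[a] + l2 * z[b] + l3 * z[c];
        ti[q] = t + 1;
        break;
      }
    }
  }
  return List::create(_["z"] = zi, _["tri"] = ti);
}

// Mean distance from every point to its k nearest neighbours (3D), using a
// uniform grid with expanding-shell search.
// [[Rcpp::export]]
NumericVector cpp_knn_meandist(NumericMatrix X, int k) {
  const int n = X.nrow();
  if (X.ncol() != 3) stop("expected an N x 3 coordinate matrix");
  if (k < 1) stop("k must be >= 1");
  if (n <= k) stop("need more points (%d) than neighbours k=%d", n, k);

  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      double v = X(i, d);
      if (!R_finite(v)) stop("non-finite coordinate at row %d", i + 1);
      lo[d] = std::min(lo[d], v);
      hi[d] = std::max(hi[d], v);
    }
  double span[3], s = 0.0;
  for (int d = 0; d < 3; ++d) {
    span[d] = std::max(hi[d] - lo[d], 1e-9);
    s = std::max(s, span[d]);
  }
  // aim for ~k points per occupied cell
  double target = std::cbrt(span[0] * span[1] * span[2] *
                            (double)(k + 1) / (double)n);
  target = std::max(target, 1e-9);
  int ng[3];
  double cs[3];
  for (int d = 0; d < 3; ++d) {
    ng[d] = std::max(1, std::min(96, (int)(span[d] / target)));
    cs[d] = span[d] / ng[d];
  }
  std::vector<std::vector<int> > cells(ng[0] * ng[1] * ng[2]);
  std::vector<int> ci(n), cj(n), ck(n);
  for (int i = 0; i < n; ++i) {
    ci[i] = std::min(ng[0] - 1, (int)((X(i, 0) - lo[0]) / cs[0]));
    cj[i] = std::min(ng[1] - 1, (int)((X(i, 1) - lo[1]) / cs[1]));
    ck[i] = std::min(ng[2] - 1, (int)((X(i, 2) - lo[2]) / cs[2]));
    cells[(ci[i] * ng[1] + cj[i]) * ng[2] + ck[i]].push_back(i);
  }
  const double mincell = std::min({cs[0], cs[1], cs[2]});
  const int max_shell = std::max({ng[0], ng[1], ng[2]});

  NumericVector out(n);
  std::vector<double> d2;
  for (int i = 0; i < n; ++i) {
    d2.clear();
    for (int shell = 0; shell <= max_shell; ++shell) {
      // gather cells at Chebyshev distance == shell
      for (int a = ci[i] - shell; a <= ci[i] + shell; ++a) {
        if (a < 0 || a >= ng[0]) continue;
        for (int b = cj[i] - shell; b <= cj[i] + shell; ++b) {
          if (b < 0 || b >= ng[1]) continue;
          for (int c = ck[i] - shell; c <= ck[i] + shell; ++c) {
            if (c < 0 || c >= ng[2]) continue;
            if (std::max({std::abs(a - ci[i]), std::abs(b - cj[i]),
                          std::abs(c - ck[i])}) != shell)
              continue;
            const std::vector<int>& cell = cells[(a * ng[1] + b) * ng[2] + c];
            for (size_t m = 0; m < cell.size(); ++m) {
              int j = cell[m];
              if (j == i) continue;
              double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1),
                     dz = X(i, 2) - X(j, 2);
              d2.push_back(dx * dx + dy * dy + dz * dz);
            }
          }
        }
      }
      if ((int)d2.size() >= k) {
        std::nth_element(d2.begin(), d2.begin() + (k - 1), d2.end());
        double kth = std::sqrt(d2[k - 1]);
        // any point in a farther shell is at least this far away
        double bound = (double)shell * mincell;
        if (kth <= bound || shell == max_shell) break;
      }
    }
    std::nth_element(d2.begin(), d2.begin() + (k - 1), d2.end());
    double acc = 0.0;
    for (int m = 0; m < k; ++m) acc += std::sqrt(d2[m]);
    out[i] = acc / k;
  }
  return out;
}
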