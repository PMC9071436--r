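// Knot toolkit: KMT chain reduction, Alexander determinant at t = -1,
// crossing counts for the minimally interfering closure.
//
// The determinant uses the classical underpass presentation: underpasses are
// numbered along the chain, generator k is the arc between underpasses k and
// k+1, and at t = -1 the matrix row for underpass k is
//   overpass arc == k or k+1 :  M[k][k] = -1, M[k][k+1] = +1
//   otherwise                :  M[k][k] = +1, M[k][k+1] = +1, M[k][ov] = -2
// (crossing signs drop out at t = -1). One row and one column are deleted and
// the determinant is evaluated in exact integer (128-bit Bareiss) arithmetic.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

namespace {

struct V3 { double x, y, z; };

inline V3 sub(const V3& a, const V3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline V3 crossv(const V3& a, const V3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dotv(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline double norm3(const V3& a) { return std::sqrt(dotv(a, a)); }

std::vector<V3> as_points(const NumericMatrix& m) {
  std::vector<V3> p(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) p[i] = {m(i, 0), m(i, 1), m(i, 2)};
  return p;
}

// --- segment/triangle intersection (for KMT) -------------------------------

// 2D helpers for the coplanar segment/triangle case
inline double orient2(double ax, double ay, double bx, double by,
                      double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

bool seg_seg_2d(double ax, double ay, double bx, double by,
                double cx, double cy, double dx, double dy, double tol) {
  double d1 = orient2(cx, cy, dx, dy, ax, ay);
  double d2 = orient2(cx, cy, dx, dy, bx, by);
  double d3 = orient2(ax, ay, bx, by, cx, cy);
  double d4 = orient2(ax, ay, bx, by, dx, dy);
  if (((d1 > tol && d2 < -tol) || (d1 < -tol && d2 > tol)) &&
      ((d3 > tol && d4 < -tol) || (d3 < -tol && d4 > tol))) return true;
  // near-collinear touches: conservative (count as intersection)
  auto onseg = [&](double px, double py, double qx, double qy,
                   double rx, double ry, double dd) {
    return std::fabs(dd) <= tol &&
      rx >= std::min(px, qx) - tol && rx <= std::max(px, qx) + tol &&
      ry >= std::min(py, qy) - tol && ry <= std::max(py, qy) + tol;
  };
  if (onseg(cx, cy, dx, dy, ax, ay, d1)) return true;
  if (onseg(cx, cy, dx, dy, bx, by, d2)) return true;
  if (onseg(ax, ay, bx, by, cx, cy, d3)) return true;
  if (onseg(ax, ay, bx, by, dx, dy, d4)) return true;
  return false;
}

bool point_in_tri_2d(double px, double py, double x0, double y0,
                     double x1, double y1, double x2, double y2, double tol) {
  double d1 = orient2(x0, y0, x1, y1, px, py);
  double d2 = orient2(x1, y1, x2, y2, px, py);
  double d3 = orient2(x2, y2, x0, y0, px, py);
  bool neg = (d1 < -tol) || (d2 < -tol) || (d3 < -tol);
  bool pos = (d1 > tol) || (d2 > tol) || (d3 > tol);
  return !(neg && pos);
}

// Does segment [a,b] intersect triangle (t0,t1,t2)?  Conservative on
// near-degenerate cases: returns true unless the move is clearly
// unobstructed, so KMT stays topology preserving.
bool seg_hits_triangle(const V3& a, const V3& b,
                       const V3& t0, const V3& t1, const V3& t2) {
  const double eps = 1e-12;
  V3 e1 = sub(t1, t0), e2 = sub(t2, t0);
  V3 dir = sub(b, a);
  V3 p = crossv(dir, e2);
  double det = dotv(e1, p);
  double scale = norm3(e1) * norm3(e2) * norm3(dir);
  if (std::fabs(det) < 1e-12 * (scale + eps)) {
    // segment parallel to the triangle plane
    V3 n = crossv(e1, e2);
    double nn = norm3(n);
    if (nn < eps) return false;  // degenerate (flat) triangle obstructs nothing
    double geo = std::max({norm3(e1), norm3(e2), 1e-300});
    double d0 = dotv(sub(a, t0), n) / nn;
    double d1 = dotv(sub(b, t0), n) / nn;
    if (std::fabs(d0) > 1e-9 * geo && std::fabs(d1) > 1e-9 * geo &&
        d0 * d1 > 0) return false;  // strictly off-plane on one side
    if (std::fabs(d0) > 1e-9 * geo || std::fabs(d1) > 1e-9 * geo) {
      // crosses the plane but det ~ 0 (grazing): be conservative
      return true;
    }
    // coplanar: project on the two dominant axes of the normal and test in 2D
    double anx = std::fabs(n.x), any = std::fabs(n.y), anz = std::fabs(n.z);
    int drop = (anx >= any && anx >= anz) ? 0 : (any >= anz ? 1 : 2);
    auto px = [&](const V3& v) { return drop == 0 ? v.y : v.x; };
    auto py = [&](const V3& v) { return drop == 2 ? v.y : v.z; };
    double tol = 1e-12 * geo * geo;
    if (point_in_tri_2d(px(a), py(a), px(t0), py(t0), px(t1), py(t1),
                        px(t2), py(t2), tol)) return true;
    if (point_in_tri_2d(px(b), py(b), px(t0), py(t0), px(t1), py(t1),
                        px(t2), py(t2), tol)) return true;
    if (seg_seg_2d(px(a), py(a), px(b), py(b), px(t0), py(t0), px(t1), py(t1), tol)) return true;
    if (seg_seg_2d(px(a), py(a), px(b), py(b), px(t1), py(t1), px(t2), py(t2), tol)) return true;
    if (seg_seg_2d(px(a), py(a), px(b), py(b), px(t2), py(t2), px(t0), py(t0), tol)) return true;
    return false;
  }
  double inv = 1.0 / det;
  V3 s = sub(a, t0);
  double u = dotv(s, p) * inv;
  if (u < -1e-12 || u > 1.0 + 1e-12) return false;
  V3 q = crossv(s, e1);
  double v = dotv(dir, q) * inv;
  if (v < -1e-12 || u + v > 1.0 + 1e-12) return false;
  double t = dotv(e2, q) * inv;
  return (t > -1e-12 && t < 1.0 + 1e-12);
}

// --- projection / crossing extraction ---------------------------------------

struct Crossing {
  double s_under;  // chain coordinate (segment index + fraction) of underpass
  double s_over;
};

// rotate points by a random rotation drawn from rng
std::vector<V3> rotate_points(const std::vector<V3>& pts, KRng& rng) {
  // uniform random quaternion
  double u1 = rng.unif(), u2 = rng.unif(), u3 = rng.unif();
  double a = std::sqrt(1.0 - u1), b = std::sqrt(u1);
  double qx = a * std::sin(2 * M_PI * u2), qy = a * std::cos(2 * M_PI * u2);
  double qz = b * std::sin(2 * M_PI * u3), qw = b * std::cos(2 * M_PI * u3);
  double R[3][3] = {
    {1 - 2 * (qy * qy + qz * qz), 2 * (qx * qy - qz * qw), 2 * (qx * qz + qy * qw)},
    {2 * (qx * qy + qz * qw), 1 - 2 * (qx * qx + qz * qz), 2 * (qy * qz - qx * qw)},
    {2 * (qx * qz - qy * qw), 2 * (qy * qz + qx * qw), 1 - 2 * (qx * qx + qy * qy)}
  };
  std::vector<V3> out(pts.size());
  for (size_t i = 0; i < pts.size(); ++i) {
    out[i].x = R[0][0] * pts[i].x + R[0][1] * pts[i].y + R[0][2] * pts[i].z;
    out[i].y = R[1][0] * pts[i].x + R[1][1] * pts[i].y + R[1][2] * pts[i].z;
    out[i].z = R[2][0] * pts[i].x + R[2][1] * pts[i].y + R[2][2] * pts[i].z;
  }
  return out;
}

// Extract crossings of the xy-projection of closed polygon pts.
// Returns false if the projection is non-generic and should be retried.
bool extract_crossings(const std::vector<V3>& pts, std::vector<Crossing>& out,
                       std::vector<std::pair<int,int> >* pairs = nullptr) {
  int m = static_cast<int>(pts.size());
  out.clear();
  if (pairs) pairs->clear();
  double scale = 0.0;
  for (int i = 0; i < m; ++i) {
    int j = (i + 1) % m;
    double dx = pts[j].x - pts[i].x, dy = pts[j].y - pts[i].y;
    scale = std::max(scale, std::fabs(dx) + std::fabs(dy));
  }
  if (scale <= 0) return false;
  const double tol = 1e-9;
  for (int i = 0; i < m; ++i) {
    int i2 = (i + 1) % m;
    double ax = pts[i].x, ay = pts[i].y, bx = pts[i2].x, by = pts[i2].y;
    for (int j = i + 1; j < m; ++j) {
      int j2 = (j + 1) % m;
      if (j == i || j2 == i || j == i2) continue;  // adjacent segments
      double cx = pts[j].x, cy = pts[j].y, dx = pts[j2].x, dy = pts[j2].y;
      double r1x = bx - ax, r1y = by - ay, r2x = dx - cx, r2y = dy - cy;
      double den = r1x * r2y - r1y * r2x;
      double qx = cx - ax, qy = cy - ay;
      double tn = qx * r2y - qy * r2x;   // t = tn/den along segment i
      double un = qx * r1y - qy * r1x;   // u = un/den along segment j
      if (std::fabs(den) < 1e-13 * scale * scale) {
        // (near-)parallel: generic iff they do not overlap; check distance
        double d2 = std::fabs(tn) / (std::hypot(r2x, r2y) + 1e-300);
        if (d2 < tol * scale) {
          // collinear-ish; see whether the spans overlap
          double lo = std::min(ax, bx) - tol, hi = std::max(ax, bx) + tol;
          if (std::max(cx, dx) >= lo && std::min(cx, dx) <= hi) return false;
        }
        continue;
      }
      double t = tn / den, u = un / den;
      if (t <= -tol || t >= 1 + tol || u <= -tol || u >= 1 + tol) continue;
      if (t < tol || t > 1 - tol || u < tol || u > 1 - tol) return false;  // vertex hit
      double za = pts[i].z + t * (pts[i2].z - pts[i].z);
      double zb = pts[j].z + u * (pts[j2].z - pts[j].z);
      if (std::fabs(za - zb) < 1e-10) return false;  // actual 3D contact/tangency
      Crossing c;
      if (za < zb) { c.s_under = i + t; c.s_over = j + u; }
      else         { c.s_under = j + u; c.s_over = i + t; }
      out.push_back(c);
      if (pairs) pairs->push_back(std::make_pair(i, j));
    }
  }
  return true;
}

// --- Alexander determinant ---------------------------------------------------

typedef __int128 int128;

// |det| of integer matrix (Bareiss, fraction free). n up to ~120.
double int_abs_det(std::vector<std::vector<long long> >& M) {
  int n = static_cast<int>(M.size());
  if (n == 0) return 1.0;
  std::vector<std::vector<int128> > A(n, std::vector<int128>(n));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) A[i][j] = M[i][j];
  int128 prev = 1;
  int sign = 1;
  for (int k = 0; k < n - 1; ++k) {
    if (A[k][k] == 0) {
      int piv = -1;
      for (int r = k + 1; r < n; ++r) if (A[r][k] != 0) { piv = r; break; }
      if (piv < 0) return 0.0;
      std::swap(A[k], A[piv]);
      sign = -sign;
    }
    for (int i = k + 1; i < n; ++i)
      for (int j = k + 1; j < n; ++j)
        A[i][j] = (A[i][j] * A[k][k] - A[i][k] * A[k][j]) / prev;
    prev = A[k][k];
  }
  int128 d = A[n - 1][n - 1];
  if (d < 0) d = -d;
  return static_cast<double>(d) * 1.0;  // caller range-checks
}

// determinant at -1 from the crossing list; -1 on failure
double alexander_from_crossings(std::vector<Crossing>& cr) {
  int n = static_cast<int>(cr.size());
  if (n <= 1) return 1.0;
  std::sort(cr.begin(), cr.end(),
            [](const Crossing& a, const Crossing& b) { return a.s_under < b.s_under; });
  std::vector<double> su(n);
  for (int i = 0; i < n; ++i) su[i] = cr[i].s_under;
  // generator index of a chain coordinate s: largest k with su[k] <= s (cyclic)
  auto gen_of = [&](double s) -> int {
    int k = static_cast<int>(std::upper_bound(su.begin(), su.end(), s) - su.begin()) - 1;
    if (k < 0) k = n - 1;
    return k;
  };
  // generator k = arc from underpass k to underpass k+1, so at underpass k
  // the incoming arc is k-1 and the outgoing arc is k
  std::vector<std::vector<long long> > M(n, std::vector<long long>(n, 0));
  for (int k = 0; k < n; ++k) {
    int ov = gen_of(cr[k].s_over);
    int kin = (k - 1 + n) % n;
    if (ov == kin || ov == k) {
      M[k][kin] += 1; M[k][k] += -1;
    } else {
      M[k][kin] += 1; M[k][k] += 1; M[k][ov] += -2;
    }
  }
  // delete last row and column
  std::vector<std::vector<long long> > Mm(n - 1, std::vector<long long>(n - 1));
  for (int i = 0; i < n - 1; ++i)
    for (int j = 0; j < n - 1; ++j) Mm[i][j] = M[i][j];
  return int_abs_det(Mm);
}

}  // namespace

// [[Rcpp::export]]
List cpp_kmt(NumericMatrix coords) {
  std::vector<V3> pts = as_points(coords);
  int n = static_cast<int>(pts.size());
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i + 1;  // 1-based original indices

  bool removed = true;
  while (removed && static_cast<int>(pts.size()) > 3) {
    removed = false;
    int m = static_cast<int>(pts.size());
    for (int i = 0; i < m && m > 3; ++i) {
      int ip = (i - 1 + m) % m, in = (i + 1) % m;
      const V3& P = pts[ip];
      const V3& V = pts[i];
      const V3& Q = pts[in];
      // degenerate triangle (collinear): removable
      V3 ar = crossv(sub(V, P), sub(Q, P));
      bool obstructed = false;
      if (norm3(ar) > 1e-12) {
        for (int s = 0; s < m; ++s) {
          int s2 = (s + 1) % m;
          if (s == ip || s == i || s == in) continue;  // triangle's own sides +
          if (s2 == ip || s2 == i) continue;           // segments into P / V
          V3 a = pts[s], b = pts[s2];
          // segments sharing exactly vertex Q (s == in handled) or P:
          if (s2 == in) continue;  // cannot happen (s==i covers), kept for clarity
          if (seg_hits_triangle(a, b, P, V, Q)) { obstructed = true; break; }
        }
        // segments incident to P or Q (one shared endpoint): shrink away from
        // the shared vertex and retest so a pierce through the interior counts
        if (!obstructed) {
          int incid[2] = {(ip - 1 + m) % m, in};  // seg ending at P, seg from Q
          for (int w = 0; w < 2 && !obstructed; ++w) {
            int s = incid[w], s2 = (s + 1) % m;
            if (s == i || s2 == i) continue;
            V3 a = pts[s], b = pts[s2];
            // shrink 0.1% from each end
            V3 d = sub(b, a);
            V3 aa = {a.x + 1e-3 * d.x, a.y + 1e-3 * d.y, a.z + 1e-3 * d.z};
            V3 bb = {b.x - 1e-3 * d.x, b.y - 1e-3 * d.y, b.z - 1e-3 * d.z};
            if (seg_hits_triangle(aa, bb, P, V, Q)) obstructed = true;
          }
        }
      }
      if (!obstructed) {
        pts.erase(pts.begin() + i);
        idx.erase(idx.begin() + i);
        --m; --i;
        removed = true;
      }
    }
  }
  NumericMatrix out(static_cast<int>(pts.size()), 3);
  IntegerVector oidx(static_cast<int>(pts.size()));
  for (size_t i = 0; i < pts.size(); ++i) {
    out(i, 0) = pts[i].x; out(i, 1) = pts[i].y; out(i, 2) = pts[i].z;
    oidx[i] = idx[i];
  }
  return List::create(_["coords"] = out, _["index"] = oidx);
}

// [[Rcpp::export]]
double cpp_alexander(NumericMatrix coords, int seed, int max_tries = 64) {
  std::vector<V3> pts = as_points(coords);
  if (pts.size() < 3) return 1.0;
  KRng rng(static_cast<uint64_t>(seed) * 2654435761ULL + 17ULL);
  for (int attempt = 0; attempt < max_tries; ++attempt) {
    std::vector<V3> rp = rotate_points(pts, rng);
    std::vector<Crossing> cr;
    if (!extract_crossings(rp, cr)) continue;
    double d = alexander_from_crossings(cr);
    if (d <= 0.0) continue;                       // degenerate matrix: retry
    // knot determinant is odd; an even value marks a degenerate projection
    if (d < 9e15 && (static_cast<long long>(d) % 2LL == 0LL)) continue;
    return d;
  }
  stop("alexander determinant: no generic projection found after max_tries");
}

// Count crossings in a seeded generic projection that involve any of the
// (1-based) polygon segments listed in `segs` (segment i joins vertex i to
// i+1, cyclically). Used to score closure candidates.
// [[Rcpp::export]]
double cpp_crossing_count(NumericMatrix coords, int seed, IntegerVector segs) {
  std::vector<V3> pts = as_points(coords);
  if (pts.size() < 3) return 0.0;
  std::vector<bool> marked(pts.size(), false);
  for (int k = 0; k < segs.size(); ++k) {
    int s = segs[k] - 1;
    if (s >= 0 && s < static_cast<int>(pts.size()))
      marked[s] = true;
  }
  KRng rng(static_cast<uint64_t>(seed) * 2654435761ULL + 40503ULL);
  for (int attempt = 0; attempt < 64; ++attempt) {
    std::vector<V3> rp = rotate_points(pts, rng);
    std::vector<Crossing> cr;
    std::vector<std::pair<int,int> > pairs;
    if (!extract_crossings(rp, cr, &pairs)) continue;
    int count = 0;
    for (size_t i = 0; i < pairs.size(); ++i)
      if (marked[pairs[i].first] || marked[pairs[i].second]) ++count;
    return count;
  }
  stop("crossing count: no generic projection found");
}
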