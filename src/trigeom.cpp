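// Triangle geometry: point-to-triangle distance maps and strict
// triangle-triangle penetration tests (Moller interval method). Touching or
// coplanar faces count as non-intersecting; only true penetration is
// reported, which matches the finite-element contact convention where
// conforming interfaces share a plane.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct V3 {
  double x, y, z;
};
inline V3 sub(const V3& a, const V3& b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
inline V3 cross(const V3& a, const V3& b) {
  return {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}
inline double dot(const V3& a, const V3& b) {
  return a.x*b.x + a.y*b.y + a.z*b.z;
}
inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }

// Closest point on triangle (Ericson, Real-Time Collision Detection).
double point_tri_dist2(const V3& p, const V3& a, const V3& b, const V3& c) {
  V3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { V3 d = sub(p, a); return dot(d, d); }
  V3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { V3 d = sub(p, b); return dot(d, d); }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    V3 q = {a.x + v*ab.x, a.y + v*ab.y, a.z + v*ab.z};
    V3 d = sub(p, q); return dot(d, d);
  }
  V3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { V3 d = sub(p, c); return dot(d, d); }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    V3 q = {a.x + w*ac.x, a.y + w*ac.y, a.z + w*ac.z};
    V3 d = sub(p, q); return dot(d, d);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    V3 q = {b.x + w*(c.x-b.x), b.y + w*(c.y-b.y), b.z + w*(c.z-b.z)};
    V3 d = sub(p, q); return dot(d, d);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  V3 q = {a.x + ab.x*v + ac.x*w, a.y + ab.y*v + ac.y*w, a.z + ab.z*v + ac.z*w};
  V3 d = sub(p, q);
  return dot(d, d);
}

// Project triangle onto the intersection line and return the parameter
// interval. Standard Moller helper.
bool compute_interval(double proj0, double proj1, double proj2, double d0,
                      double d1, double d2, double& t0, double& t1) {
  // the vertex with sign opposite to the other two is found by the caller's
  // permutation: here d0*d2 and d1*d2 have opposite signs w.r.t. vertex 2
  t0 = proj0 + (proj2 - proj0) * d0 / (d0 - d2);
  t1 = proj1 + (proj2 - proj1) * d1 / (d1 - d2);
  return true;
}

bool tri_tri_penetrates(const V3 t1[3], const V3 t2[3], double eps) {
  V3 e1 = sub(t1[1], t1[0]), e2 = sub(t1[2], t1[0]);
  V3 n1 = cross(e1, e2);
  double d1 = -dot(n1, t1[0]);
  double du0 = dot(n1, t2[0]) + d1;
  double du1 = dot(n1, t2[1]) + d1;
  double du2 = dot(n1, t2[2]) + d1;
  double s1 = norm(n1);
  double tol1 = eps * s1;
  if (std::fabs(du0) < tol1) du0 = 0;
  if (std::fabs(du1) < tol1) du1 = 0;
  if (std::fabs(du2) < tol1) du2 = 0;
  if (du0 >= 0 && du1 >= 0 && du2 >= 0) return false;
  if (du0 <= 0 && du1 <= 0 && du2 <= 0) return false;

  V3 f1 = sub(t2[1], t2[0]), f2 = sub(t2[2], t2[0]);
  V3 n2 = cross(f1, f2);
  double d2 = -dot(n2, t2[0]);
  double dv0 = dot(n2, t1[0]) + d2;
  double dv1 = dot(n2, t1[1]) + d2;
  double dv2 = dot(n2, t1[2]) + d2;
  double s2 = norm(n2);
  double tol2 = eps * s2;
  if (std::fabs(dv0) < tol2) dv0 = 0;
  if (std::fabs(dv1) < tol2) dv1 = 0;
  if (std::fabs(dv2) < tol2) dv2 = 0;
  if (dv0 >= 0 && dv1 >= 0 && dv2 >= 0) return false;
  if (dv0 <= 0 && dv1 <= 0 && dv2 <= 0) return false;

  // intersection line direction
  V3 D = cross(n1, n2);
  // largest component of D for projection
  double ax = std::fabs(D.x), ay = std::fabs(D.y), az = std::fabs(D.z);
  int axis = ax >= ay ? (ax >= az ? 0 : 2) : (ay >= az ? 1 : 2);
  auto proj = [axis](const V3& v) {
    return axis == 0 ? v.x : (axis == 1 ? v.y : v.z);
  };

  // permute so the lone-signed vertex is last
  auto interval = [&](const V3 tv[3], double dd0, double dd1, double dd2,
                      double& a, double& b) -> bool {
    double p0 = proj(tv[0]), p1 = proj(tv[1]), p2 = proj(tv[2]);
    if (dd0 * dd1 > 0)       // 2 is alone
      compute_interval(p0, p1, p2, dd0, dd1, dd2, a, b);
    else if (dd0 * dd2 > 0)  // 1 is alone
      compute_interval(p0, p2, p1, dd0, dd2, dd1, a, b);
    else if (dd1 * dd2 > 0)  // 0 is alone
      compute_interval(p1, p2, p0, dd1, dd2, dd0, a, b);
    else if (dd1 != 0)       // dd0 == 0 (and maybe dd2): 1 vs rest
      compute_interval(p0, p2, p1, dd0, dd2, dd1, a, b);
    else if (dd2 != 0)
      compute_interval(p0, p1, p2, dd0, dd1, dd2, a, b);
    else
      return false;          // degenerate/coplanar
    if (a > b) std::swap(a, b);
    return true;
  };

  double a0, a1, b0, b1;
  if (!interval(t1, dv0, dv1, dv2, a0, a1)) return false;
  if (!interval(t2, du0, du1, du2, b0, b1)) return false;

  double lo = std::max(a0, b0), hi = std::min(a1, b1);
  double scale = std::max(std::max(std::fabs(a0), std::fabs(a1)),
                          std::max(std::fabs(b0), std::fabs(b1)));
  return hi - lo > eps * (1.0 + scale);  // strict overlap = penetration
}

} // namespace

// Minimum distance from each point to a triangulated reference surface.
// [[Rcpp::export]]
NumericVector cpp_point_triangle_distances(NumericMatrix P, NumericMatrix V,
                                           IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  std::vector<V3> verts(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) verts[i] = {V(i,0), V(i,1), V(i,2)};
  // triangle bounding boxes for pruning
  std::vector<double> blo(3 * nf), bhi(3 * nf);
  for (int t = 0; t < nf; ++t) {
    const V3& a = verts[F(t,0)-1];
    const V3& b = verts[F(t,1)-1];
    const V3& c = verts[F(t,2)-1];
    blo[3*t]   = std::min(a.x, std::min(b.x, c.x));
    blo[3*t+1] = std::min(a.y, std::min(b.y, c.y));
    blo[3*t+2] = std::min(a.z, std::min(b.z, c.z));
    bhi[3*t]   = std::max(a.x, std::max(b.x, c.x));
    bhi[3*t+1] = std::max(a.y, std::max(b.y, c.y));
    bhi[3*t+2] = std::max(a.z, std::max(b.z, c.z));
  }
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    V3 q = {P(p,0), P(p,1), P(p,2)};
    double best = R_PosInf;
    for (int t = 0; t < nf; ++t) {
      // squared distance to bbox as lower bound
      double lb = 0.0;
      double dx = std::max(std::max(blo[3*t] - q.x, q.x - bhi[3*t]), 0.0);
      double dy = std::max(std::max(blo[3*t+1] - q.y, q.y - bhi[3*t+1]), 0.0);
      double dz = std::max(std::max(blo[3*t+2] - q.z, q.z - bhi[3*t+2]), 0.0);
      lb = dx*dx + dy*dy + dz*dz;
      if (lb >= best) continue;
      double d2 = point_tri_dist2(q, verts[F(t,0)-1], verts[F(t,1)-1],
                                  verts[F(t,2)-1]);
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}

// Count penetrating triangle pairs between two triangle soups. N1/N2 carry
// the global node ids of each triangle's vertices; pairs sharing a node id
// are skipped (conforming interfaces). Returns the count and the (1-based)
// indices of intersecting pairs in deterministic order.
// [[Rcpp::export]]
List cpp_triangle_intersections(NumericMatrix V1, IntegerMatrix F1,
                                IntegerMatrix N1, NumericMatrix V2,
                                IntegerMatrix F2, IntegerMatrix N2,
                                double eps) {
  int nf1 = F1.nrow(), nf2 = F2.nrow();
  std::vector<V3> a(V1.nrow()), b(V2.nrow());
  for (int i = 0; i < V1.nrow(); ++i) a[i] = {V1(i,0), V1(i,1), V1(i,2)};
  for (int i = 0; i < V2.nrow(); ++i) b[i] = {V2(i,0), V2(i,1), V2(i,2)};

  std::vector<double> lo2(3 * nf2), hi2(3 * nf2);
  for (int t = 0; t < nf2; ++t) {
    const V3& p = b[F2(t,0)-1];
    const V3& q = b[F2(t,1)-1];
    const V3& r = b[F2(t,2)-1];
    lo2[3*t]   = std::min(p.x, std::min(q.x, r.x));
    lo2[3*t+1] = std::min(p.y, std::min(q.y, r.y));
    lo2[3*t+2] = std::min(p.z, std::min(q.z, r.z));
    hi2[3*t]   = std::max(p.x, std::max(q.x, r.x));
    hi2[3*t+1] = std::max(p.y, std::max(q.y, r.y));
    hi2[3*t+2] = std::max(p.z, std::max(q.z, r.z));
  }

  std::vector<int> pi, pj;
  bool use_ids = N1.nrow() == nf1 && N2.nrow() == nf2;
  for (int s = 0; s < nf1; ++s) {
    V3 t1[3] = {a[F1(s,0)-1], a[F1(s,1)-1], a[F1(s,2)-1]};
    double lx = std::min(t1[0].x, std::min(t1[1].x, t1[2].x));
    double ly = std::min(t1[0].y, std::min(t1[1].y, t1[2].y));
    double lz = std::min(t1[0].z, std::min(t1[1].z, t1[2].z));
    double hx = std::max(t1[0].x, std::max(t1[1].x, t1[2].x));
    double hy = std::max(t1[0].y, std::max(t1[1].y, t1[2].y));
    double hz = std::max(t1[0].z, std::max(t1[1].z, t1[2].z));
    for (int t = 0; t < nf2; ++t) {
      if (lo2[3*t] > hx + eps || hi2[3*t] < lx - eps ||
          lo2[3*t+1] > hy + eps || hi2[3*t+1] < ly - eps ||
          lo2[3*t+2] > hz + eps || hi2[3*t+2] < lz - eps)
        continue;
      if (use_ids) {
        bool shared = false;
        for (int u = 0; u < 3 && !shared; ++u)
          for (int w = 0; w < 3; ++w)
            if (N1(s, u) == N2(t, w)) { shared = true; break; }
        if (shared) continue;
      }
      V3 t2[3] = {b[F2(t,0)-1], b[F2(t,1)-1], b[F2(t,2)-1]};
      if (tri_tri_penetrates(t1, t2, eps)) {
        pi.push_back(s + 1);
        pj.push_back(t + 1);
      }
    }
  }
  return List::create(_["count"] = (int)pi.size(),
                      _["i"] = IntegerVector(pi.begin(), pi.end()),
                      _["j"] = IntegerVector(pj.begin(), pj.end()));
}
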