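// Minimum-distance kernels between a solid axis-aligned ellipsoid (body frame,
// centred at the origin) and points / segments / triangle meshes.  All
// distances are Euclidean distances to the ellipsoid SURFACE, clamped to 0 for
// overlapping or contained configurations; callers transform shapes into the
// ellipsoid body frame first (rigid transforms leave distances unchanged).
#include <Rcpp.h>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

static inline double dot3(const double* u, const double* v) {
  return u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
}
static inline double norm3(const double* u) { return std::sqrt(dot3(u, u)); }
static inline void sub3(const double* u, const double* v, double* out) {
  out[0] = u[0] - v[0]; out[1] = u[1] - v[1]; out[2] = u[2] - v[2];
}
static inline void cross3(const double* u, const double* v, double* out) {
  out[0] = u[1] * v[2] - u[2] * v[1];
  out[1] = u[2] * v[0] - u[0] * v[2];
  out[2] = u[0] * v[1] - u[1] * v[0];
}

// Distance from point p to the solid ellipsoid with semi-axes a.
// Exterior points: the closest surface point satisfies
//   x_i = a_i^2 p_i / (t + a_i^2)  with t > 0 the unique root of
//   F(t) = sum (a_i p_i / (t + a_i^2))^2 - 1.
// F is convex and decreasing on t > 0, so Newton from t = 0 converges
// monotonically.  Interior points report distance 0 (inside flag set).
double pt_ellipsoid(const double* p, const double* a, double* cp, bool* inside) {
  double s = (p[0] / a[0]) * (p[0] / a[0]) + (p[1] / a[1]) * (p[1] / a[1]) +
             (p[2] / a[2]) * (p[2] / a[2]);
  if (s <= 1.0) {
    *inside = true;
    cp[0] = p[0]; cp[1] = p[1]; cp[2] = p[2];
    return 0.0;
  }
  *inside = false;
  double ap2[3];
  for (int i = 0; i < 3; ++i) ap2[i] = (a[i] * p[i]) * (a[i] * p[i]);
  double t = 0.0;
  for (int it = 0; it < 100; ++it) {
    double F = -1.0, dF = 0.0;
    for (int i = 0; i < 3; ++i) {
      double d = t + a[i] * a[i];
      double r = ap2[i] / (d * d);
      F += r;
      dF -= 2.0 * r / d;
    }
    if (F < 1e-15) break;
    double step = -F / dF;
    t += step;
    if (step < 1e-16 * (1.0 + t)) break;
  }
  double diff[3];
  for (int i = 0; i < 3; ++i) {
    cp[i] = a[i] * a[i] * p[i] / (t + a[i] * a[i]);
    diff[i] = p[i] - cp[i];
  }
  return norm3(diff);
}

// Closest point on triangle (A,B,C) to point p (Ericson, Real-Time Collision
// Detection).  Returns false for degenerate (near-zero-area) triangles.
static bool closest_pt_triangle(const double* p, const double* A,
                                const double* B, const double* C,
                                double* out) {
  double ab[3], ac[3], ap[3];
  sub3(B, A, ab); sub3(C, A, ac); sub3(p, A, ap);
  double n[3];
  cross3(ab, ac, n);
  double scale = norm3(ab) + norm3(ac);
  if (norm3(n) < 1e-14 * scale * scale) return false;

  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { out[0] = A[0]; out[1] = A[1]; out[2] = A[2]; return true; }
  double bp[3]; sub3(p, B, bp);
  double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { out[0] = B[0]; out[1] = B[1]; out[2] = B[2]; return true; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = A[i] + v * ab[i];
    return true;
  }
  double cp_[3]; sub3(p, C, cp_);
  double d5 = dot3(ab, cp_), d6 = dot3(ac, cp_);
  if (d6 >= 0.0 && d5 <= d6) { out[0] = C[0]; out[1] = C[1]; out[2] = C[2]; return true; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = A[i] + w * ac[i];
    return true;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = B[i] + w * (C[i] - B[i]);
    return true;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = A[i] + ab[i] * v + ac[i] * w;
  return true;
}

// Segment [p0, p1] vs solid ellipsoid: golden-section minimisation of the
// (convex) point distance along the segment; short-circuits on penetration.
// Fills seg_pt (closest point on segment) and ell_pt (closest surface point).
double seg_ellipsoid(const double* p0, const double* p1, const double* a,
                     double* seg_pt, double* ell_pt) {
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  double dseg[3]; sub3(p1, p0, dseg);
  double q[3], cp[3];
  bool inside;

  double lo = 0.0, hi = 1.0;
  double s1 = hi - gr * (hi - lo), s2 = lo + gr * (hi - lo);
  double f1, f2;
  for (int i = 0; i < 3; ++i) q[i] = p0[i] + s1 * dseg[i];
  f1 = pt_ellipsoid(q, a, cp, &inside);
  if (inside) { for (int i = 0; i < 3; ++i) { seg_pt[i] = q[i]; ell_pt[i] = q[i]; } return 0.0; }
  for (int i = 0; i < 3; ++i) q[i] = p0[i] + s2 * dseg[i];
  f2 = pt_ellipsoid(q, a, cp, &inside);
  if (inside) { for (int i = 0; i < 3; ++i) { seg_pt[i] = q[i]; ell_pt[i] = q[i]; } return 0.0; }

  for (int it = 0; it < 200 && (hi - lo) > 1e-13; ++it) {
    if (f1 <= f2) {
      hi = s2; s2 = s1; f2 = f1;
      s1 = hi - gr * (hi - lo);
      for (int i = 0; i < 3; ++i) q[i] = p0[i] + s1 * dseg[i];
      f1 = pt_ellipsoid(q, a, cp, &inside);
    } else {
      lo = s1; s1 = s2; f1 = f2;
      s2 = lo + gr * (hi - lo);
      for (int i = 0; i < 3; ++i) q[i] = p0[i] + s2 * dseg[i];
      f2 = pt_ellipsoid(q, a, cp, &inside);
    }
    if (inside) { for (int i = 0; i < 3; ++i) { seg_pt[i] = q[i]; ell_pt[i] = q[i]; } return 0.0; }
  }
  double s = 0.5 * (lo + hi);
  for (int i = 0; i < 3; ++i) seg_pt[i] = p0[i] + s * dseg[i];
  double d = pt_ellipsoid(seg_pt, a, ell_pt, &inside);
  // the true minimiser may sit at an endpoint; check both explicitly
  double cpe[3];
  double d0 = pt_ellipsoid(p0, a, cpe, &inside);
  if (d0 < d) { d = d0; for (int i = 0; i < 3; ++i) { seg_pt[i] = p0[i]; ell_pt[i] = cpe[i]; } }
  double d1e = pt_ellipsoid(p1, a, cpe, &inside);
  if (d1e < d) { d = d1e; for (int i = 0; i < 3; ++i) { seg_pt[i] = p1[i]; ell_pt[i] = cpe[i]; } }
  return d;
}

// Triangle vs solid ellipsoid: projected-gradient descent of the convex point
// distance over the (convex) triangle domain, initialised at the point of the
// triangle closest to the ellipsoid centre.
static double tri_ellipsoid(const double* A, const double* B, const double* C,
                            const double* a, double* tri_pt, double* ell_pt,
                            bool* degenerate) {
  const double origin[3] = {0.0, 0.0, 0.0};
  double q[3];
  if (!closest_pt_triangle(origin, A, B, C, q)) { *degenerate = true; return R_PosInf; }
  *degenerate = false;
  double cp[3];
  bool inside;
  double d = pt_ellipsoid(q, a, cp, &inside);
  if (inside) {
    for (int i = 0; i < 3; ++i) { tri_pt[i] = q[i]; ell_pt[i] = q[i]; }
    return 0.0;
  }
  double step = std::max(d, 1e-3);
  for (int it = 0; it < 200 && step > 1e-11; ++it) {
    double g[3], qn[3], qp[3];
    for (int i = 0; i < 3; ++i) g[i] = (q[i] - cp[i]) / d;
    for (int i = 0; i < 3; ++i) qp[i] = q[i] - step * g[i];
    closest_pt_triangle(qp, A, B, C, qn);
    double cpn[3];
    double dn = pt_ellipsoid(qn, a, cpn, &inside);
    if (inside) {
      for (int i = 0; i < 3; ++i) { tri_pt[i] = qn[i]; ell_pt[i] = qn[i]; }
      return 0.0;
    }
    if (dn < d - 1e-16) {
      d = dn;
      for (int i = 0; i < 3; ++i) { q[i] = qn[i]; cp[i] = cpn[i]; }
      step *= 1.6;
    } else {
      step *= 0.5;
    }
  }
  for (int i = 0; i < 3; ++i) { tri_pt[i] = q[i]; ell_pt[i] = cp[i]; }
  return d;
}

// Parity ray cast to test whether the ellipsoid centre lies inside a closed
// mesh (handles the mesh-encloses-ellipsoid case). The ray direction is
// deliberately oblique so it does not graze axis-aligned edges.
static bool origin_inside_mesh(const double* V, int nv, const int* F, int nf) {
  const double orig[3] = {0.0, 0.0, 0.0};
  const double dir[3] = {0.5575475878, 0.6907861596, 0.4603907303};
  int crossings = 0;
  for (int f = 0; f < nf; ++f) {
    const double* A = V + 3 * F[f];
    const double* B = V + 3 * F[f + nf];
    const double* C = V + 3 * F[f + 2 * nf];
    double e1[3], e2[3], pvec[3], tvec[3], qvec[3];
    sub3(B, A, e1); sub3(C, A, e2);
    cross3(dir, e2, pvec);
    double det = dot3(e1, pvec);
    if (std::fabs(det) < 1e-14) continue;
    double inv = 1.0 / det;
    sub3(orig, A, tvec);
    double u = dot3(tvec, pvec) * inv;
    if (u < 0.0 || u > 1.0) continue;
    cross3(tvec, e1, qvec);
    double v = dot3(dir, qvec) * inv;
    if (v < 0.0 || u + v > 1.0) continue;
    double t = dot3(e2, qvec) * inv;
    if (t > 0.0) ++crossings;
  }
  return (crossings % 2) == 1;
}

// Mesh vs solid ellipsoid with per-triangle bound pruning: a triangle whose
// distance to the ellipsoid centre exceeds current_min + max(a) cannot improve
// the minimum.
double mesh_ellipsoid(const double* V, int nv, const int* F, int nf,
                      const double* a, double* mesh_pt, double* ell_pt,
                      int* n_degenerate) {
  double amax = std::max(a[0], std::max(a[1], a[2]));
  const double origin[3] = {0.0, 0.0, 0.0};
  double best = R_PosInf;
  *n_degenerate = 0;
  for (int f = 0; f < nf; ++f) {
    const double* A = V + 3 * F[f];
    const double* B = V + 3 * F[f + nf];
    const double* C = V + 3 * F[f + 2 * nf];
    double qc[3];
    if (!closest_pt_triangle(origin, A, B, C, qc)) { ++(*n_degenerate); continue; }
    if (norm3(qc) - amax >= best) continue;
    double tp[3], ep[3];
    bool degen;
    double d = tri_ellipsoid(A, B, C, a, tp, ep, &degen);
    if (degen) { ++(*n_degenerate); continue; }
    if (d < best) {
      best = d;
      for (int i = 0; i < 3; ++i) { mesh_pt[i] = tp[i]; ell_pt[i] = ep[i]; }
      if (best == 0.0) break;
    }
  }
  if (best > 0.0 && best < R_PosInf && origin_inside_mesh(V, nv, F, nf)) {
    best = 0.0;
    for (int i = 0; i < 3; ++i) { mesh_pt[i] = 0.0; ell_pt[i] = 0.0; }
  }
  return best;
}

// ---- R-facing wrappers (body frame; the R layer handles poses) -------------

// [[Rcpp::export(name = ".pt_ellipsoid_cpp")]]
List pt_ellipsoid_cpp(NumericVector p, NumericVector axes) {
  double cp[3];
  bool inside;
  double pp[3] = {p[0], p[1], p[2]};
  double aa[3] = {axes[0], axes[1], axes[2]};
  double d = pt_ellipsoid(pp, aa, cp, &inside);
  return List::create(_["distance"] = d, _["contained"] = inside,
                      _["closest"] = NumericVector::create(cp[0], cp[1], cp[2]));
}

// [[Rcpp::export(name = ".seg_ellipsoid_cpp")]]
List seg_ellipsoid_cpp(NumericVector p0, NumericVector p1, NumericVector axes) {
  double sp[3], ep[3];
  double q0[3] = {p0[0], p0[1], p0[2]};
  double q1[3] = {p1[0], p1[1], p1[2]};
  double aa[3] = {axes[0], axes[1], axes[2]};
  double d = seg_ellipsoid(q0, q1, aa, sp, ep);
  return List::create(_["distance"] = d,
                      _["segment_point"] = NumericVector::create(sp[0], sp[1], sp[2]),
                      _["ellipsoid_point"] = NumericVector::create(ep[0], ep[1], ep[2]));
}

// [[Rcpp::export(name = ".mesh_ellipsoid_cpp")]]
List mesh_ellipsoid_cpp(NumericMatrix V, IntegerMatrix Fc, NumericVector axes) {
  int nv = V.nrow(), nf = Fc.nrow();
  std::vector<double> vv(3 * nv);
  for (int i = 0; i < nv; ++i)
    for (int j = 0; j < 3; ++j) vv[3 * i + j] = V(i, j);
  std::vector<int> ff(3 * nf);
  for (int i = 0; i < nf; ++i)
    for (int j = 0; j < 3; ++j) ff[i + j * nf] = Fc(i, j) - 1;  // 1-based in R
  double aa[3] = {axes[0], axes[1], axes[2]};
  double mp[3], ep[3];
  int ndeg;
  double d = mesh_ellipsoid(vv.data(), nv, ff.data(), nf, aa, mp, ep, &ndeg);
  return List::create(_["distance"] = d, _["n_degenerate"] = ndeg,
                      _["mesh_point"] = NumericVector::create(mp[0], mp[1], mp[2]),
                      _["ellipsoid_point"] = NumericVector::create(ep[0], ep[1], ep[2]));
}
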