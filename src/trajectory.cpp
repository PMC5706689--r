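// Time-stepped trajectory engine: kite kinematics (three rotations about the
// seabed joint), animal translation, per-step minimum-distance collision test
// against tether capsule and kite surface, with a conservative broad phase so
// the exact narrow-phase solves run only when the shapes can possibly be
// within the collision threshold.
#include <Rcpp.h>
#include <cmath>
#include "kitecollide.h"
using namespace Rcpp;

struct Flight {
  double T, D, H, h, w, Lt;
};

// attachment-point kinematics: vertical oscillation with period T/2, lateral
// with period T (figure-of-eight); beta measured from the vertical so that
// height above seabed = Lt * cos(beta).
static void attach_at(double t, double delta, const Flight& fp,
                      double* beta, double* gamma, double* A) {
  double tau = t - delta;
  double cosb = (fp.H - fp.D + 0.5 * fp.h * std::sin(4.0 * M_PI / fp.T * tau)) / fp.Lt;
  *beta = std::acos(cosb);
  double sinb = std::sin(*beta);
  *gamma = (fp.w == 0.0)
             ? 0.0
             : std::asin(0.5 * fp.w * std::sin(2.0 * M_PI / fp.T * tau) /
                         (fp.Lt * sinb));
  A[0] = fp.Lt * sinb * std::cos(*gamma);
  A[1] = fp.Lt * sinb * std::sin(*gamma);
  A[2] = fp.Lt * cosb;
}

// R0 = Rz(gamma) * Ry(beta); maps body z to the tether direction.
static void rot_bg(double beta, double gamma, double R[9]) {
  double cb = std::cos(beta), sb = std::sin(beta);
  double cg = std::cos(gamma), sg = std::sin(gamma);
  R[0] = cg * cb; R[1] = -sg; R[2] = cg * sb;
  R[3] = sg * cb; R[4] = cg;  R[5] = sg * sb;
  R[6] = -sb;     R[7] = 0.0; R[8] = cb;
}

// full pose Rk = R0 * Rz(alpha): spin about the tether axis puts the kite
// chord axis (body x) along the flight direction.
static void rot_full(const double R0[9], double alpha, double Rk[9]) {
  double ca = std::cos(alpha), sa = std::sin(alpha);
  for (int r = 0; r < 3; ++r) {
    Rk[3 * r + 0] = R0[3 * r + 0] * ca + R0[3 * r + 1] * sa;
    Rk[3 * r + 1] = -R0[3 * r + 0] * sa + R0[3 * r + 1] * ca;
    Rk[3 * r + 2] = R0[3 * r + 2];
  }
}

// heading from the two most recent attachment points, expressed in the
// current (beta, gamma) frame; coincident points keep the previous heading.
static double heading(const double* Aprev, const double* Acur,
                      const double R0[9], double alpha_prev) {
  double m[3] = {Acur[0] - Aprev[0], Acur[1] - Aprev[1], Acur[2] - Aprev[2]};
  double n = std::sqrt(m[0] * m[0] + m[1] * m[1] + m[2] * m[2]);
  if (n < 1e-12) return alpha_prev;
  double ux = R0[0] * m[0] + R0[3] * m[1] + R0[6] * m[2];
  double uy = R0[1] * m[0] + R0[4] * m[1] + R0[7] * m[2];
  return std::atan2(uy, ux);
}

// [[Rcpp::export(name = ".attach_cpp")]]
NumericVector attach_cpp(double t, double delta, double T, double D, double H,
                         double h, double w, double Lt) {
  Flight fp = {T, D, H, h, w, Lt};
  double beta, gamma, A[3];
  attach_at(t, delta, fp, &beta, &gamma, A);
  return NumericVector::create(_["beta"] = beta, _["gamma"] = gamma,
                               _["x"] = A[0], _["y"] = A[1], _["z"] = A[2]);
}

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// [[Rcpp::export(name = ".run_trials_cpp")]]
NumericMatrix run_trials_cpp(NumericVector y0, NumericVector z0,
                             NumericVector delta,
                             double T, double D, double H, double h, double w,
                             double Lt,
                             NumericMatrix kiteV, IntegerMatrix kiteF,
                             double tether_radius,
                             double semi_major, double semi_minor,
                             double v, double dt, double threshold,
                             double x_stop,
                             bool include_kite, bool include_tether) {
  Flight fp = {T, D, H, h, w, Lt};
  int ntrial = y0.size();
  int nv = kiteV.nrow(), nf = kiteF.nrow();
  std::vector<double> bodyV(3 * nv);
  double kite_bound = 0.0;
  for (int i = 0; i < nv; ++i) {
    double r2 = 0.0;
    for (int j = 0; j < 3; ++j) {
      bodyV[3 * i + j] = kiteV(i, j);
      r2 += kiteV(i, j) * kiteV(i, j);
    }
    kite_bound = std::max(kite_bound, std::sqrt(r2));
  }
  std::vector<int> faces(3 * nf);
  for (int i = 0; i < nf; ++i)
    for (int j = 0; j < 3; ++j) faces[i + j * nf] = kiteF(i, j) - 1;
  std::vector<double> worldV(3 * nv);

  double axes[3] = {semi_major, semi_minor, semi_minor};
  int max_steps = (int)std::ceil(x_stop / (v * dt)) + 2;

  NumericMatrix out(ntrial, 8);
  colnames(out) = CharacterVector::create("collided", "component", "t_collision",
                                          "x", "y", "z", "relative_speed",
                                          "n_steps");

  for (int i = 0; i < ntrial; ++i) {
    double del = delta[i];
    // bootstrap the heading from path points at -2dt and -dt
    double bP, gP, Aprev[3], R0prev[9], Rkprev[9], alpha_prev;
    {
      double b2, g2, A2[3];
      attach_at(-2.0 * dt, del, fp, &b2, &g2, A2);
      attach_at(-dt, del, fp, &bP, &gP, Aprev);
      rot_bg(bP, gP, R0prev);
      alpha_prev = heading(A2, Aprev, R0prev, 0.0);
      rot_full(R0prev, alpha_prev, Rkprev);
    }

    int component = 0, steps = 0;
    double t_coll = NA_REAL, loc[3] = {NA_REAL, NA_REAL, NA_REAL};
    double rel_speed = NA_REAL;
    bool collided = false;

    for (int k = 0; k <= max_steps; ++k) {
      double t = k * dt;
      double beta, gamma, A[3], R0[9], Rk[9];
      attach_at(t, del, fp, &beta, &gamma, A);
      rot_bg(beta, gamma, R0);
      double alpha = heading(Aprev, A, R0, alpha_prev);
      rot_full(R0, alpha, Rk);
      double c[3] = {v * t, y0[i], z0[i]};
      ++steps;

      // tether capsule [origin, A]
      double d_tether = R_PosInf;
      double te_seg[3], te_ell[3];
      bool te_overlap = false;
      if (include_tether) {
        double sA = clamp01((c[0] * A[0] + c[1] * A[1] + c[2] * A[2]) /
                            (Lt * Lt));
        double dx = c[0] - sA * A[0], dy = c[1] - sA * A[1], dz = c[2] - sA * A[2];
        double broad = std::sqrt(dx * dx + dy * dy + dz * dz) -
                       semi_major - tether_radius;
        if (broad <= threshold + 1e-6) {
          double e0[3] = {-c[0], -c[1], -c[2]};
          double e1[3] = {A[0] - c[0], A[1] - c[1], A[2] - c[2]};
          double dte = seg_ellipsoid(e0, e1, axes, te_seg, te_ell);
          te_overlap = (dte <= 0.0);
          d_tether = std::max(0.0, dte - tether_radius);
        }
      }

      // kite surface posed at the attachment point
      double d_kite = R_PosInf;
      double ki_mesh[3], ki_ell[3];
      if (include_kite) {
        double dx = c[0] - A[0], dy = c[1] - A[1], dz = c[2] - A[2];
        double broad = std::sqrt(dx * dx + dy * dy + dz * dz) -
                       semi_major - kite_bound;
        if (broad <= threshold + 1e-6) {
          for (int vtx = 0; vtx < nv; ++vtx) {
            const double* b = &bodyV[3 * vtx];
            for (int r = 0; r < 3; ++r)
              worldV[3 * vtx + r] = A[r] + Rk[3 * r] * b[0] +
                                    Rk[3 * r + 1] * b[1] +
                                    Rk[3 * r + 2] * b[2] - c[r];
          }
          int ndeg;
          d_kite = mesh_ellipsoid(worldV.data(), nv, faces.data(), nf, axes,
                                  ki_mesh, ki_ell, &ndeg);
        }
      }

      bool hit_k = d_kite < threshold, hit_t = d_tether < threshold;
      if (hit_k || hit_t) {
        collided = true;
        component = (hit_k && hit_t) ? 3 : (hit_k ? 1 : 2);
        t_coll = t;
        double p_dev[3], p_prev[3];
        bool use_kite = hit_k && (!hit_t || d_kite <= d_tether);
        if (use_kite) {
          for (int r = 0; r < 3; ++r) {
            loc[r] = 0.5 * (ki_mesh[r] + ki_ell[r]) + c[r];
            p_dev[r] = ki_mesh[r] + c[r];
          }
          // advect the body-frame contact point with the previous pose
          double rel[3] = {p_dev[0] - A[0], p_dev[1] - A[1], p_dev[2] - A[2]};
          double b[3];
          for (int r = 0; r < 3; ++r)
            b[r] = Rk[r] * rel[0] + Rk[3 + r] * rel[1] + Rk[6 + r] * rel[2];
          for (int r = 0; r < 3; ++r)
            p_prev[r] = Aprev[r] + Rkprev[3 * r] * b[0] +
                        Rkprev[3 * r + 1] * b[1] + Rkprev[3 * r + 2] * b[2];
        } else {
          double dte = std::sqrt((te_ell[0] - te_seg[0]) * (te_ell[0] - te_seg[0]) +
                                 (te_ell[1] - te_seg[1]) * (te_ell[1] - te_seg[1]) +
                                 (te_ell[2] - te_seg[2]) * (te_ell[2] - te_seg[2]));
          double cap_pt[3];
          for (int r = 0; r < 3; ++r) {
            cap_pt[r] = te_overlap || dte < 1e-12
                          ? te_seg[r]
                          : te_seg[r] + tether_radius * (te_ell[r] - te_seg[r]) / dte;
            loc[r] = 0.5 * (cap_pt[r] + (te_overlap ? te_seg[r] : te_ell[r])) + c[r];
            p_dev[r] = te_seg[r] + c[r];
          }
          double spar = std::sqrt(p_dev[0] * p_dev[0] + p_dev[1] * p_dev[1] +
                                  p_dev[2] * p_dev[2]) / Lt;
          for (int r = 0; r < 3; ++r) p_prev[r] = spar * Aprev[r];
        }
        double vd[3];
        for (int r = 0; r < 3; ++r) vd[r] = (p_dev[r] - p_prev[r]) / dt;
        double rx = v - vd[0];
        rel_speed = std::sqrt(rx * rx + vd[1] * vd[1] + vd[2] * vd[2]);
        break;
      }

      if (c[0] > x_stop) break;

      for (int r = 0; r < 3; ++r) Aprev[r] = A[r];
      for (int r = 0; r < 9; ++r) Rkprev[r] = Rk[r];
      alpha_prev = alpha;
    }

    out(i, 0) = collided ? 1.0 : 0.0;
    out(i, 1) = component;
    out(i, 2) = t_coll;
    out(i, 3) = loc[0];
    out(i, 4) = loc[1];
    out(i, 5) = loc[2];
    out(i, 6) = rel_speed;
    out(i, 7) = steps;
  }
  return out;
}
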