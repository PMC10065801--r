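// Brute-force validation oracles for the escape geometry.
//
// These deliberately avoid the closed-form crossing/time equations: the
// crossing point is found by marching along the escape ray in small
// distance steps, and the arrival times by stepping both animals forward in
// small time steps.  They exist so the analytic implementation in R/ can be
// checked against an independent construction on random inputs.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline bool in_danger(double x, double y, double D_width,
                             double R_device, double D_attack) {
  if (std::fabs(y) > D_width) return false;
  double face = (R_device - D_attack) - std::sqrt(R_device * R_device - y * y);
  return x >= face;
}

//' Brute-force crossing point by marching along the escape ray
//'
//' Validation oracle: marches along the ray at angle \code{et_deg} in steps
//' of \code{ds} mm until the point leaves the danger zone, independently of
//' the closed-form crossing equations.
//'
//' @param et_deg Folded escape trajectory, degrees.
//' @param D_width,R_device,D_attack Danger-zone geometry, mm.
//' @param ds Marching step, mm.
//' @param s_max Give up beyond this ray parameter, mm.
//' @return Ray parameter of the first point outside the danger zone (mm),
//'   or \code{Inf}.
//' @export
// [[Rcpp::export]]
double march_crossing(double et_deg, double D_width, double R_device,
                      double D_attack, double ds = 1e-3,
                      double s_max = 2000.0) {
  double th = et_deg * M_PI / 180.0;
  double cs = std::cos(th), sn = std::sin(th);
  for (double s = 0.0; s <= s_max; s += ds) {
    if (!in_danger(s * cs, s * sn, D_width, R_device, D_attack))
      return s;
  }
  return R_PosInf;
}

//' Brute-force escape-time margin by time stepping
//'
//' Validation oracle: simulates one escape per input by stepping time in
//' \code{dt} ms increments. The prey advances along its ray with the
//' two-stage speed profile (linear to \code{D1} over \code{T1}, then
//' \code{U_prey}); the predator tip advances at \code{U_pred} and stops at
//' \code{-D_attack}. The prey escapes iff its centre of mass plus
//' \code{L_prey} clears the danger-zone boundary before the device edge at
//' the crossing height arrives there.
//'
//' @param et_deg Folded escape trajectories, degrees.
//' @param T1 Fast-start durations, ms.
//' @param D_width,R_device,D_attack,D_initial,D1,L_prey Geometry, mm.
//' @param U_prey,U_pred Speeds, mm/ms.
//' @param dt Time step, ms.
//' @param ds Marching step for the crossing search, mm.
//' @param s_max Give up beyond this ray parameter, mm.
//' @return Predator minus prey arrival time (ms); \code{+Inf} if the
//'   predator never arrives, \code{NA} if no crossing was found.
//' @export
// [[Rcpp::export]]
NumericVector stepping_tdiff(NumericVector et_deg, NumericVector T1,
                             NumericVector D_width, NumericVector R_device,
                             NumericVector D_attack, NumericVector D_initial,
                             NumericVector D1, NumericVector L_prey,
                             NumericVector U_prey, NumericVector U_pred,
                             double dt = 1e-3, double ds = 1e-3,
                             double s_max = 2000.0) {
  int n = et_deg.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double th = et_deg[i] * M_PI / 180.0;
    double cs = std::cos(th), sn = std::sin(th);
    double dist = R_PosInf;
    for (double s = 0.0; s <= s_max; s += ds) {
      if (!in_danger(s * cs, s * sn, D_width[i], R_device[i], D_attack[i])) {
        dist = s;
        break;
      }
    }
    if (!R_finite(dist)) { out[i] = NA_REAL; continue; }
    double xc = dist * cs, yc = dist * sn;

    // prey: first time its displacement reaches dist + L_prey
    double target = dist + L_prey[i];
    double t_prey = R_PosInf;
    for (double t = 0.0;; t += dt) {
      double s = (t <= T1[i]) ? D1[i] * t / T1[i]
                              : D1[i] + U_prey[i] * (t - T1[i]);
      if (s >= target) { t_prey = t; break; }
      if (t > 1e6) break;  // safety net; unreachable for valid inputs
    }

    // predator: device edge at the crossing height reaches the crossing
    double delta = R_device[i] - std::sqrt(R_device[i] * R_device[i] - yc * yc);
    double slack = 2.0 * (ds + U_pred[i] * dt);
    double t_pred = R_PosInf;
    double t_stop = (D_initial[i] + D_attack[i]) / U_pred[i];
    for (double t = 0.0; t <= t_stop + dt; t += dt) {
      double x_tip = D_initial[i] - U_pred[i] * t;
      if (x_tip < -D_attack[i]) x_tip = -D_attack[i];
      double x_edge = x_tip + delta;
      if (x_edge <= xc + slack) { t_pred = t; break; }
    }
    out[i] = (R_finite(t_pred) ? t_pred : R_PosInf) - t_prey;
  }
  return out;
}
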