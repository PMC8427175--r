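// Compiled fast path for kinematic-drive maneuvers.
//
// Integrates the body quaternion and the inertial-frame angular momentum
// of the free-floating body+tail system while the tail joint trajectory is
// prescribed by per-axis natural cubic splines (held at zero beyond the
// last knot). Dormand-Prince RK5(4) with adaptive steps; output times are
// hit exactly by clamping the step. Mirrors the R reference integrator in
// R/dynamics.R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::mat;
using arma::vec;

namespace {

mat skew(const vec& v) {
  mat K(3, 3, arma::fill::zeros);
  K(0, 1) = -v(2); K(0, 2) = v(1);
  K(1, 0) = v(2);  K(1, 2) = -v(0);
  K(2, 0) = -v(1); K(2, 1) = v(0);
  return K;
}

mat rot_axis_angle(const vec& axis, double angle) {
  mat K = skew(axis);
  return arma::eye(3, 3) + std::sin(angle) * K +
         (1.0 - std::cos(angle)) * (K * K);
}

mat quat_to_rot(const vec& q) {
  double w = q(0), x = q(1), y = q(2), z = q(3);
  mat R(3, 3);
  R(0, 0) = 1 - 2 * (y * y + z * z); R(0, 1) = 2 * (x * y - w * z); R(0, 2) = 2 * (x * z + w * y);
  R(1, 0) = 2 * (x * y + w * z); R(1, 1) = 1 - 2 * (x * x + z * z); R(1, 2) = 2 * (y * z - w * x);
  R(2, 0) = 2 * (x * z - w * y); R(2, 1) = 2 * (y * z + w * x); R(2, 2) = 1 - 2 * (x * x + y * y);
  return R;
}

vec quat_derivative(const vec& q, const vec& w) {
  vec dq(4);
  dq(0) = 0.5 * (-q(1) * w(0) - q(2) * w(1) - q(3) * w(2));
  dq(1) = 0.5 * ( q(0) * w(0) + q(2) * w(2) - q(3) * w(1));
  dq(2) = 0.5 * ( q(0) * w(1) - q(1) * w(2) + q(3) * w(0));
  dq(3) = 0.5 * ( q(0) * w(2) + q(1) * w(1) - q(2) * w(0));
  return dq;
}

// natural cubic spline, coef rows: a + b*dt + c*dt^2 + d*dt^3 per interval;
// zero outside [knots.front(), knots.back()]
struct Spline {
  vec knots;
  mat coef;  // (n-1) x 4
  void eval(double t, double& q, double& qd) const {
    const double t0 = knots(0), t1 = knots(knots.n_elem - 1);
    if (t <= t0 || t >= t1) { q = 0.0; qd = 0.0; return; }
    arma::uword i = knots.n_elem - 2;
    for (arma::uword k = 1; k < knots.n_elem; ++k) {
      if (t < knots(k)) { i = k - 1; break; }
    }
    double dt = t - knots(i);
    q = coef(i, 0) + dt * (coef(i, 1) + dt * (coef(i, 2) + dt * coef(i, 3)));
    qd = coef(i, 1) + dt * (2.0 * coef(i, 2) + 3.0 * dt * coef(i, 3));
  }
};

struct Params {
  double m1, m2, mu;
  mat I1, I2;
  vec d2, pj, a1, a2;
  bool aero_on;
  double C1, C2;
  Spline s1, s2;
};

// aerodynamic pitch/roll spring-damper, generalized forces on Z-Y-X Euler
// angles mapped to a body-frame torque (world-z / yaw component is zero)
vec aero_torque(const vec& quat, const vec& omega, const Params& P) {
  double w = quat(0), x = quat(1), y = quat(2), z = quat(3);
  double sp = 2 * (w * y - z * x);
  sp = std::max(-1.0, std::min(1.0, sp));
  double alpha = std::asin(sp);
  double beta = std::atan2(2 * (w * x + y * z), 1 - 2 * (x * x + y * y));
  double ca = std::cos(alpha);
  if (std::fabs(ca) < 1e-8) ca = (ca >= 0 ? 1e-8 : -1e-8);
  double sb = std::sin(beta), cb = std::cos(beta);
  double h = sb * omega(1) + cb * omega(2);
  double alpha_dot = cb * omega(1) - sb * omega(2);
  double beta_dot = omega(0) + std::tan(alpha) * h;
  double Qa = -(P.C1 * alpha + P.C2 * alpha_dot);
  double Qb = -(P.C1 * beta + P.C2 * beta_dot);
  mat E(3, 3, arma::fill::zeros);
  E(0, 0) = -std::sin(alpha); E(0, 1) = 0;  E(0, 2) = 1;
  E(1, 0) = ca * sb;          E(1, 1) = cb; E(1, 2) = 0;
  E(2, 0) = ca * cb;          E(2, 1) = -sb; E(2, 2) = 0;
  vec Q = {0.0, Qa, Qb};
  return arma::solve(E.t(), Q);
}

void joint_state(double t, const Params& P, vec& q, vec& qd) {
  double a, ad, b, bd;
  P.s1.eval(t, a, ad);
  P.s2.eval(t, b, bd);
  q = {a, b};
  qd = {ad, bd};
}

// omega from momentum + prescribed joint rates at configuration q
vec solve_omega(const vec& q, const vec& qd, const vec& Lb, const Params& P,
                mat& Rj_out, vec& s_out, mat& Jv_out) {
  mat R1a = rot_axis_angle(P.a1, q(0));
  mat R2a = rot_axis_angle(P.a2, q(1));
  mat Rj = R1a * R2a;
  vec Rjd2 = Rj * P.d2;
  vec s = P.pj + Rjd2;
  mat Jv(3, 2);
  Jv.col(0) = arma::cross(P.a1, Rjd2);
  Jv.col(1) = R1a * arma::cross(P.a2, vec(R2a * P.d2));
  mat Gw = Rj.t();
  mat Gq(3, 2);
  Gq.col(0) = R2a.t() * P.a1;
  Gq.col(1) = P.a2;
  mat K = skew(s);
  mat Mww = P.I1 + Gw.t() * P.I2 * Gw + P.mu * K.t() * K;
  mat Mwq = P.mu * (K * Jv) + Gw.t() * (P.I2 * Gq);
  Rj_out = Rj; s_out = s; Jv_out = Jv;
  return arma::solve(Mww, Lb - Mwq * qd);
}

// state y = (quat[4], Lw[3])
vec rhs(double t, const vec& y, const Params& P) {
  vec quat = arma::normalise(y.subvec(0, 3));
  vec Lw = y.subvec(4, 6);
  vec q, qd;
  joint_state(t, P, q, qd);
  mat R1 = quat_to_rot(quat);
  vec Lb = R1.t() * Lw;
  mat Rj; vec s; mat Jv;
  vec omega = solve_omega(q, qd, Lb, P, Rj, s, Jv);
  vec dy(7, arma::fill::zeros);
  dy.subvec(0, 3) = quat_derivative(quat, omega);
  if (P.aero_on) dy.subvec(4, 6) = R1 * aero_torque(quat, omega, P);
  return dy;
}

}  // namespace

// [[Rcpp::export]]
arma::mat sim_kinematic_cpp(double m1, const arma::mat& I1, double m2,
                            const arma::mat& I2, const arma::vec& d2,
                            const arma::vec& pj, double mu,
                            const arma::vec& a1, const arma::vec& a2,
                            const arma::vec& knots1, const arma::mat& coef1,
                            const arma::vec& knots2, const arma::mat& coef2,
                            const arma::vec& quat0, const arma::vec& Lw0,
                            const arma::vec& times,
                            bool aero_on, double C1, double C2,
                            double rtol, double atol) {
  Params P;
  P.m1 = m1; P.m2 = m2; P.mu = mu;
  P.I1 = I1; P.I2 = I2; P.d2 = d2; P.pj = pj;
  P.a1 = a1; P.a2 = a2;
  P.aero_on = aero_on; P.C1 = C1; P.C2 = C2;
  P.s1.knots = knots1; P.s1.coef = coef1;
  P.s2.knots = knots2; P.s2.coef = coef2;

  // Dormand-Prince RK5(4) tableau
  const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
  const double a21 = 1.0 / 5;
  const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
               a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
               a64 = 49.0 / 176, a65 = -5103.0 / 18656;
  const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
               b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  const double e1 = 35.0 / 384 - 5179.0 / 57600,
               e3 = 500.0 / 1113 - 7571.0 / 16695,
               e4 = 125.0 / 192 - 393.0 / 640,
               e5 = -2187.0 / 6784 + 92097.0 / 339200,
               e6 = 11.0 / 84 - 187.0 / 2100,
               e7 = -1.0 / 40;

  const arma::uword nt = times.n_elem;
  mat out(nt, 11);
  vec y(7);
  y.subvec(0, 3) = quat0;
  y.subvec(4, 6) = Lw0;
  double t = times(0);
  double h = 1e-4;
  const double t_end = times(nt - 1);

  auto record = [&](arma::uword i, double ti, const vec& yi) {
    vec quat = arma::normalise(yi.subvec(0, 3));
    vec q, qd;
    joint_state(ti, P, q, qd);
    mat R1 = quat_to_rot(quat);
    vec Lb = R1.t() * yi.subvec(4, 6);
    mat Rj; vec s; mat Jv;
    vec omega = solve_omega(q, qd, Lb, P, Rj, s, Jv);
    out(i, 0) = quat(0); out(i, 1) = quat(1);
    out(i, 2) = quat(2); out(i, 3) = quat(3);
    out(i, 4) = omega(0); out(i, 5) = omega(1); out(i, 6) = omega(2);
    out(i, 7) = q(0); out(i, 8) = q(1);
    out(i, 9) = qd(0); out(i, 10) = qd(1);
  };

  record(0, t, y);
  arma::uword next_out = 1;
  vec k1 = rhs(t, y, P);
  int max_steps = 2000000;
  while (next_out < nt && max_steps-- > 0) {
    bool clipped = false;
    double h_try = h;
    if (t + h_try >= times(next_out)) {
      h_try = times(next_out) - t;
      clipped = true;
    }
    vec k2 = rhs(t + c2 * h_try, y + h_try * (a21 * k1), P);
    vec k3 = rhs(t + c3 * h_try, y + h_try * (a31 * k1 + a32 * k2), P);
    vec k4 = rhs(t + c4 * h_try, y + h_try * (a41 * k1 + a42 * k2 + a43 * k3), P);
    vec k5 = rhs(t + c5 * h_try,
                 y + h_try * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4), P);
    vec k6 = rhs(t + h_try,
                 y + h_try * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 +
                              a65 * k5), P);
    vec y5 = y + h_try * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6);
    vec k7 = rhs(t + h_try, y5, P);
    vec err = h_try * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 +
                       e7 * k7);
    double err_norm = 0.0;
    for (arma::uword j = 0; j < 7; ++j) {
      double sc = atol + rtol * std::max(std::fabs(y(j)), std::fabs(y5(j)));
      double r = err(j) / sc;
      err_norm += r * r;
    }
    err_norm = std::sqrt(err_norm / 7.0);
    double fac = 0.9 * std::pow(std::max(err_norm, 1e-10), -0.2);
    fac = std::max(0.2, std::min(5.0, fac));
    if (err_norm <= 1.0 || h_try <= 1e-12) {
      t += h_try;
      y = y5;
      k1 = k7;  // FSAL
      if (clipped && std::fabs(t - times(next_out)) < 1e-12) {
        record(next_out, t, y);
        ++next_out;
      }
      // grow from the nominal step, not a step clipped to an output time
      if (!clipped) h = std::max(1e-12, h_try * fac);
    } else {
      h = std::max(1e-12, h_try * fac);
    }
    if (!y.is_finite()) Rcpp::stop("non-finite state at t = %f", t);
    (void)t_end;
  }
  if (next_out < nt) Rcpp::stop("integrator exceeded step budget at t = %f", t);
  return out;
}
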