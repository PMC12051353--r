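// Core numerics: Hill-type muscle curves, smoothed Bhargava metabolic model,
// planar rigid-body kinematics and inverse dynamics (recursive Newton-Euler),
// Hunt-Crossley foot-ground contact, exponential passive joint torques, and
// the direct-collocation NLP evaluators (constraints, cost, sparse
// finite-difference Jacobians with structural coloring, augmented-Lagrangian
// value/gradient).
//
// Conventions: x forward, y up, z out of the page; angles in radians.
// Pelvis tilt positive anterior, hip/knee flexion positive, ankle and
// midtarsal dorsiflexion positive. Ground is y = 0, gravity -g in y.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// small helpers

static inline double smoothpos(double x, double eps) {
  // C-infinity positive part: 0.5*(x + sqrt(x^2 + eps^2))
  return 0.5 * (x + std::sqrt(x * x + eps * eps));
}
static inline double pen_smooth(double x, double eps) {
  // smoothed positive part for contact penetration: the sqrt form inside
  // the smoothing band, multiplied by a tanh cutoff so the force is
  // exactly zero (to machine precision) away from the ground
  double sp = 0.5 * (x + std::sqrt(x * x + eps * eps));
  double w = 0.5 + 0.5 * std::tanh(x / eps + 5.0);
  return sp * w;
}
static inline double cross2(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}

// ---------------------------------------------------------------------------
// Hill-type curves

// Gaussian-sum active force-length (De-Groote-style coefficients), normalized
// so the multiplier equals exactly 1 at optimal fiber length.
static const double B1[3] = {0.814483478343008, 0.433004984392647, 0.100};
static const double B2[3] = {1.055033428970575, 0.716775413397760, 1.000};
static const double B3[3] = {0.162384573599574, -0.029947116970696,
                             0.353553390593274};
static const double B4[3] = {0.063303448465465, 0.200356847296188, 0.000};

static double afl_raw(double l) {
  double f = 0.0;
  for (int i = 0; i < 3; ++i) {
    double den = B3[i] + B4[i] * l;
    double z = (l - B2[i]) / den;
    f += B1[i] * std::exp(-0.5 * z * z);
  }
  return f;
}
static double afl_norm_const() {
  static double c = afl_raw(1.0);
  return c;
}
static double active_fl(double l) { return afl_raw(l) / afl_norm_const(); }

// Exponential passive force-length with smooth onset; baseline onset at
// normalized length 1.0, shift s translates the curve to shorter lengths.
static const double KPE = 4.0;
static const double E0 = 0.6;
static const double PAS_EPS = 1e-3;  // onset smoothing band

static double passive_fl(double l, double s) {
  double x = smoothpos(l + s - 1.0, PAS_EPS);
  return (std::exp((KPE / E0) * x) - 1.0) / (std::exp(KPE) - 1.0);
}

// Force-velocity: Hill concentric branch blended (tanh) with a saturating
// eccentric branch; equals 1 at zero velocity, ~0 at max shortening,
// saturates toward 1.5 for fast lengthening.
static const double FV_AF = 0.25;     // Hill shape parameter
static const double FV_ECC_GAIN = 0.5;
static const double FV_ECC_HALF = 0.16;
static const double FV_BLEND = 0.05;  // blend width in vtilde

static double fv_raw(double v) {
  double w = 0.5 - 0.5 * std::tanh(v / FV_BLEND);  // ~1 shortening, ~0 length.
  // the concentric Hill hyperbola has a pole at v = FV_AF; smoothly clamp
  // its argument into [-1, ~0] so the expression stays bounded and smooth
  double vc = -smoothpos(-v, 0.02);
  vc = -1.0 + smoothpos(vc + 1.0, 0.02);
  double fc = (1.0 + vc) / (1.0 - vc / FV_AF);
  double vabs = std::sqrt(v * v + 1e-4);
  double fe = 1.0 + FV_ECC_GAIN * v / (vabs + FV_ECC_HALF);
  return w * fc + (1.0 - w) * fe;
}
static double fv_norm_const() {
  static double c = fv_raw(0.0);
  return c;
}
static double force_vel(double v) { return fv_raw(v) / fv_norm_const(); }

// smooth floor keeping normalized fiber length away from zero
static double lmn_guard(double l) {
  return 0.2 + smoothpos(l - 0.2, 1e-2);
}

// Raasch-style smooth first-order activation dynamics.
static double act_rate(double e, double a, double tact, double tdeact,
                       double b) {
  double w = 0.5 + 0.5 * std::tanh(b * (e - a));
  return (e - a) * (w / tact + (1.0 - w) / tdeact);
}

// tendon force-length (normalized): exponential toe curve
static double tendon_fl(double ltn, double kT) {
  return 0.2 * std::exp(kT * (ltn - 0.995)) - 0.25;
}

// [[Rcpp::export]]
NumericVector cpp_active_fl(NumericVector l) {
  NumericVector out(l.size());
  for (int i = 0; i < l.size(); ++i) out[i] = active_fl(l[i]);
  return out;
}
// [[Rcpp::export]]
NumericVector cpp_passive_fl(NumericVector l, double shift) {
  NumericVector out(l.size());
  for (int i = 0; i < l.size(); ++i) out[i] = passive_fl(l[i], shift);
  return out;
}
// [[Rcpp::export]]
NumericVector cpp_force_vel(NumericVector v) {
  NumericVector out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = force_vel(v[i]);
  return out;
}
// [[Rcpp::export]]
NumericVector cpp_act_rate(NumericVector e, NumericVector a, double tact,
                           double tdeact, double b) {
  NumericVector out(e.size());
  for (int i = 0; i < e.size(); ++i)
    out[i] = act_rate(e[i], a[i], tact, tdeact, b);
  return out;
}
// [[Rcpp::export]]
NumericVector cpp_tendon_fl(NumericVector ltn, double kT) {
  NumericVector out(ltn.size());
  for (int i = 0; i < ltn.size(); ++i) out[i] = tendon_fl(ltn[i], kT);
  return out;
}

// Fiber force along the tendon for a full parameter/state description.
// [[Rcpp::export]]
double cpp_muscle_force(double fmax, double lopt, double penn_opt,
                        double sigma, double shift, double a, double lm_norm,
                        double vm_norm) {
  double w = lopt * std::sin(penn_opt);  // constant-thickness pennation
  double lm = lm_norm * lopt;
  double cospenn = (lm <= w) ? 0.0 : std::sqrt(lm * lm - w * w) / lm;
  double f = fmax * (sigma * a * active_fl(lm_norm) * force_vel(vm_norm) +
                     passive_fl(lm_norm, shift));
  return f * cospenn;
}

// Static fiber-tendon equilibrium (elastic tendon) by bisection on lm_norm.
// [[Rcpp::export]]
List cpp_fiber_equilibrium(double fmax, double lopt, double lslack,
                           double penn_opt, double sigma, double shift,
                           double kT, double lmt, double a, bool rigid) {
  double w = lopt * std::sin(penn_opt);
  if (rigid) {
    double proj = lmt - lslack;
    double lm = std::sqrt(proj * proj + w * w);
    return List::create(_["lm_norm"] = lm / lopt, _["converged"] = true,
                        _["residual"] = 0.0);
  }
  auto resid = [&](double lmn) {
    double lm = lmn * lopt;
    double proj = (lm <= w) ? 0.0 : std::sqrt(lm * lm - w * w);
    double cospenn = (lm <= 0) ? 1.0 : proj / lm;
    double ltn = (lmt - proj) / lslack;
    double ffib = fmax * (sigma * a * active_fl(lmn) + passive_fl(lmn, shift));
    double ften = fmax * tendon_fl(ltn, kT);
    return ften - ffib * cospenn;
  };
  double lo = 0.3, hi = 1.8;
  double flo = resid(lo), fhi = resid(hi);
  if (flo * fhi > 0.0) {
    return List::create(_["lm_norm"] = NA_REAL, _["converged"] = false,
                        _["residual"] = NA_REAL);
  }
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi);
    double fm = resid(mid);
    if ((flo <= 0 && fm <= 0) || (flo >= 0 && fm >= 0)) {
      lo = mid; flo = fm;
    } else {
      hi = mid; fhi = fm;
    }
    if (hi - lo < 1e-12) break;
  }
  double lmn = 0.5 * (lo + hi);
  return List::create(_["lm_norm"] = lmn, _["converged"] = true,
                      _["residual"] = resid(lmn));
}

// ---------------------------------------------------------------------------
// Smoothed Bhargava-style metabolic energy rate (W) for one muscle.
// Conditionals (shortening vs lengthening, positive work) are replaced by
// tanh blends of configurable sharpness; sharp = Inf-like large recovers the
// piecewise model.

static const double MUSCLE_DENSITY = 1058.7;    // kg/m^3
static const double SPECIFIC_TENSION = 2.5e5;   // N/m^2
static const double SLOW_FRAC = 0.5;
static const double BASAL_WKG = 1.2;            // W per kg muscle

static double metabolic_one(double fmax, double lopt, double vmax,
                            double sigma, double shift, double a, double e,
                            double lm_norm, double vm_norm, double sharp,
                            bool smooth) {
  double mmass = MUSCLE_DENSITY * lopt * fmax / SPECIFIC_TENSION;
  double fl = active_fl(lmn_guard(lm_norm));
  double fv = force_vel(vm_norm);
  double fce = fmax * sigma * a * fl * fv;          // active fiber force, N
  double fiso = fmax * sigma * a * fl;              // activated isometric, N
  double vm = vm_norm * vmax * lopt;                // fiber velocity, m/s

  double hA = mmass * (40.0 * SLOW_FRAC + 133.0 * (1.0 - SLOW_FRAC)) * e;
  double hM = mmass * (74.0 * SLOW_FRAC + 111.0 * (1.0 - SLOW_FRAC)) * a * fl;

  // shortening/lengthening heat: coefficient switches with sign of vm
  double alpha_s = 0.16 * fiso + 0.18 * fce;
  double alpha_l = 0.157 * fce;
  double ws = smooth ? (0.5 - 0.5 * std::tanh(sharp * vm))
                     : (vm < 0.0 ? 1.0 : 0.0);
  double hS = -(ws * alpha_s + (1.0 - ws) * alpha_l) * vm;

  // positive mechanical work of the contractile element
  double wdot = -fce * vm;
  double wpos = smooth ? wdot * (0.5 + 0.5 * std::tanh(sharp * wdot))
                       : (wdot > 0.0 ? wdot : 0.0);

  return hA + hM + hS + wpos + BASAL_WKG * mmass;
}

// [[Rcpp::export]]
double cpp_metabolic_rate(double fmax, double lopt, double vmax, double sigma,
                          double shift, double a, double e, double lm_norm,
                          double vm_norm, double sharp, bool smooth) {
  return metabolic_one(fmax, lopt, vmax, sigma, shift, a, e, lm_norm, vm_norm,
                       sharp, smooth);
}

// ---------------------------------------------------------------------------
// packed planar model

struct Model {
  int nq, nb, nm, nc, npas;
  arma::mat seg;      // nb x 9: parent, coord, dir, jx, jy, comx, comy, m, I
  arma::vec fmax, lopt, lslack, vmax, sigma, shift, lref;
  arma::mat marm;     // nm x nq constant moment arms
  arma::mat contact;  // nc x 4: body, cx, cy, radius
  double ck, cdamp, cmu, cvs;
  arma::mat passive;  // npas x 8: coord, k1l, k2l, qlow, k1h, k2h, qhigh, damp
  double grav;
};

static Model unpack(const List& pack) {
  Model md;
  md.seg = as<arma::mat>(pack["seg"]);
  md.nb = md.seg.n_rows;
  md.nq = as<int>(pack["nq"]);
  md.fmax = as<arma::vec>(pack["fmax"]);
  md.lopt = as<arma::vec>(pack["lopt"]);
  md.lslack = as<arma::vec>(pack["lslack"]);
  md.vmax = as<arma::vec>(pack["vmax"]);
  md.sigma = as<arma::vec>(pack["sigma"]);
  md.shift = as<arma::vec>(pack["shift"]);
  md.lref = as<arma::vec>(pack["lref"]);
  md.marm = as<arma::mat>(pack["marm"]);
  md.nm = md.fmax.n_elem;
  md.contact = as<arma::mat>(pack["contact"]);
  md.nc = md.contact.n_rows;
  md.ck = as<double>(pack["contact_k"]);
  md.cdamp = as<double>(pack["contact_damp"]);
  md.cmu = as<double>(pack["contact_mu"]);
  md.cvs = as<double>(pack["contact_vsmooth"]);
  md.passive = as<arma::mat>(pack["passive"]);
  md.npas = md.passive.n_rows;
  md.grav = as<double>(pack["gravity"]);
  return md;
}

struct BodyKin {
  double phi, om, al;
  double px, py, vx, vy, ax, ay;        // body frame origin (= joint)
  double cx, cy, vcx, vcy, acx, acy;    // center of mass
};

static void forward_kin(const Model& md, const arma::vec& q,
                        const arma::vec& qd, const arma::vec& qdd,
                        std::vector<BodyKin>& K) {
  K.resize(md.nb);
  for (int b = 0; b < md.nb; ++b) {
    BodyKin kb;
    int parent = (int)md.seg(b, 0);
    if (parent < 0) {  // pelvis root: tx, ty, tilt (tilt dir in seg col 2)
      double dir = md.seg(b, 2);
      kb.px = q[0]; kb.py = q[1];
      kb.vx = qd[0]; kb.vy = qd[1];
      kb.ax = qdd[0]; kb.ay = qdd[1];
      kb.phi = dir * q[2]; kb.om = dir * qd[2]; kb.al = dir * qdd[2];
    } else {
      const BodyKin& kp = K[parent];
      int jc = (int)md.seg(b, 1);
      double dir = md.seg(b, 2);
      double cphi = std::cos(kp.phi), sphi = std::sin(kp.phi);
      double jx = md.seg(b, 3), jy = md.seg(b, 4);
      double ux = cphi * jx - sphi * jy;
      double uy = sphi * jx + cphi * jy;
      kb.px = kp.px + ux; kb.py = kp.py + uy;
      kb.vx = kp.vx - kp.om * uy; kb.vy = kp.vy + kp.om * ux;
      kb.ax = kp.ax - kp.al * uy - kp.om * kp.om * ux;
      kb.ay = kp.ay + kp.al * ux - kp.om * kp.om * uy;
      kb.phi = kp.phi + dir * q[jc];
      kb.om = kp.om + dir * qd[jc];
      kb.al = kp.al + dir * qdd[jc];
    }
    double cphi = std::cos(kb.phi), sphi = std::sin(kb.phi);
    double lx = md.seg(b, 5), ly = md.seg(b, 6);
    double wx = cphi * lx - sphi * ly;
    double wy = sphi * lx + cphi * ly;
    kb.cx = kb.px + wx; kb.cy = kb.py + wy;
    kb.vcx = kb.vx - kb.om * wy; kb.vcy = kb.vy + kb.om * wx;
    kb.acx = kb.ax - kb.al * wy - kb.om * kb.om * wx;
    kb.acy = kb.ay + kb.al * wx - kb.om * kb.om * wy;
    K[b] = kb;
  }
}

// Hunt-Crossley sphere forces. Returns per-sphere rows:
// [body, fx, fy, px, py, center_y] with force applied at the lowest point.
static arma::mat contact_forces(const Model& md,
                                const std::vector<BodyKin>& K) {
  arma::mat out(md.nc, 6, arma::fill::zeros);
  for (int i = 0; i < md.nc; ++i) {
    int b = (int)md.contact(i, 0);
    double cx = md.contact(i, 1), cy = md.contact(i, 2);
    double r = md.contact(i, 3);
    const BodyKin& kb = K[b];
    double cphi = std::cos(kb.phi), sphi = std::sin(kb.phi);
    double wx = cphi * cx - sphi * cy;
    double wy = sphi * cx + cphi * cy;
    double X = kb.px + wx, Y = kb.py + wy;
    double VX = kb.vx - kb.om * wy, VY = kb.vy + kb.om * wx;
    double pen = r - Y;                   // penetration depth
    double d = pen_smooth(pen, 1e-3);     // 1 mm smoothing band
    double ddot = -VY;
    double vfac = smoothpos(1.0 + 1.5 * md.cdamp * ddot, 0.1);
    double fn = md.ck * d * std::sqrt(d) * vfac;
    double ft = -md.cmu * fn * std::tanh(VX / md.cvs);
    out(i, 0) = b; out(i, 1) = ft; out(i, 2) = fn;
    out(i, 3) = X; out(i, 4) = Y - r; out(i, 5) = Y;
  }
  return out;
}

// Recursive Newton-Euler inverse dynamics: generalized applied forces
// required to realize (q, qd, qdd) with optional gravity and external
// (contact) forces already acting.
static arma::vec inv_dyn(const Model& md, const std::vector<BodyKin>& K,
                         bool gravity, const arma::mat* ext) {
  int nb = md.nb;
  arma::vec Fx(nb, arma::fill::zeros), Fy(nb, arma::fill::zeros),
      Nz(nb, arma::fill::zeros);
  double g = gravity ? md.grav : 0.0;
  for (int b = 0; b < nb; ++b) {
    double m = md.seg(b, 7), I = md.seg(b, 8);
    const BodyKin& kb = K[b];
    double fx = m * kb.acx;
    double fy = m * (kb.acy + g);
    double nz = I * kb.al +
        cross2(kb.cx - kb.px, kb.cy - kb.py, m * kb.acx, m * (kb.acy + g));
    Fx[b] = fx; Fy[b] = fy; Nz[b] = nz;
  }
  if (ext) {
    for (arma::uword i = 0; i < ext->n_rows; ++i) {
      int b = (int)(*ext)(i, 0);
      double fx = (*ext)(i, 1), fy = (*ext)(i, 2);
      double px = (*ext)(i, 3), py = (*ext)(i, 4);
      Fx[b] -= fx; Fy[b] -= fy;
      Nz[b] -= cross2(px - K[b].px, py - K[b].py, fx, fy);
    }
  }
  arma::vec Q(md.nq, arma::fill::zeros);
  for (int b = nb - 1; b >= 0; --b) {
    int parent = (int)md.seg(b, 0);
    if (parent >= 0) {
      int jc = (int)md.seg(b, 1);
      double dir = md.seg(b, 2);
      Q[jc] += dir * Nz[b];
      Fx[parent] += Fx[b];
      Fy[parent] += Fy[b];
      Nz[parent] += Nz[b] +
          cross2(K[b].px - K[parent].px, K[b].py - K[parent].py, Fx[b], Fy[b]);
    } else {
      double dir = md.seg(b, 2);
      Q[0] += Fx[b];
      Q[1] += Fy[b];
      Q[2] += dir * Nz[b];
    }
  }
  return Q;
}

// Muscle fiber kinematics under the rigid-tendon planar assumption.
static void muscle_kin(const Model& md, const arma::vec& q,
                       const arma::vec& qd, arma::vec& lmn, arma::vec& vmn) {
  lmn.set_size(md.nm); vmn.set_size(md.nm);
  for (int m = 0; m < md.nm; ++m) {
    double lmt = md.lref[m];
    double vmt = 0.0;
    for (int j = 0; j < md.nq; ++j) {
      double r = md.marm(m, j);
      if (r != 0.0) { lmt -= r * q[j]; vmt -= r * qd[j]; }
    }
    lmn[m] = lmn_guard((lmt - md.lslack[m]) / md.lopt[m]);
    vmn[m] = vmt / (md.lopt[m] * md.vmax[m]);
  }
}

static void muscle_forces_torques(const Model& md, const arma::vec& lmn,
                                  const arma::vec& vmn, const arma::vec& a,
                                  arma::vec& F, arma::vec& tau) {
  F.set_size(md.nm);
  tau.zeros(md.nq);
  for (int m = 0; m < md.nm; ++m) {
    double f = md.fmax[m] *
        (md.sigma[m] * a[m] * active_fl(lmn[m]) * force_vel(vmn[m]) +
         passive_fl(lmn[m], md.shift[m]));
    F[m] = f;
    for (int j = 0; j < md.nq; ++j) {
      double r = md.marm(m, j);
      if (r != 0.0) tau[j] += r * f;
    }
  }
}

static arma::vec passive_torques(const Model& md, const arma::vec& q,
                                 const arma::vec& qd) {
  arma::vec tp(md.nq, arma::fill::zeros);
  for (int i = 0; i < md.npas; ++i) {
    int j = (int)md.passive(i, 0);
    double k1l = md.passive(i, 1), k2l = md.passive(i, 2),
           qlo = md.passive(i, 3), k1h = md.passive(i, 4),
           k2h = md.passive(i, 5), qhi = md.passive(i, 6),
           damp = md.passive(i, 7);
    tp[j] = k1l * std::exp(k2l * (qlo - q[j])) -
            k1h * std::exp(k2h * (q[j] - qhi)) - damp * qd[j];
  }
  return tp;
}

// ---------------------------------------------------------------------------
// R-facing wrappers over the mechanics

// [[Rcpp::export]]
List cpp_kinematics(List pack, NumericVector q, NumericVector qd,
                    NumericVector qdd) {
  Model md = unpack(pack);
  std::vector<BodyKin> K;
  forward_kin(md, as<arma::vec>(q), as<arma::vec>(qd), as<arma::vec>(qdd), K);
  arma::mat out(md.nb, 10);
  for (int b = 0; b < md.nb; ++b) {
    out(b, 0) = K[b].px; out(b, 1) = K[b].py; out(b, 2) = K[b].phi;
    out(b, 3) = K[b].cx; out(b, 4) = K[b].cy;
    out(b, 5) = K[b].vcx; out(b, 6) = K[b].vcy; out(b, 7) = K[b].om;
    out(b, 8) = K[b].acx; out(b, 9) = K[b].acy;
  }
  return List::create(_["body"] = out);
}

// [[Rcpp::export]]
NumericMatrix cpp_contact(List pack, NumericVector q, NumericVector qd) {
  Model md = unpack(pack);
  arma::vec qdd(md.nq, arma::fill::zeros);
  std::vector<BodyKin> K;
  forward_kin(md, as<arma::vec>(q), as<arma::vec>(qd), qdd, K);
  return wrap(contact_forces(md, K));
}

// [[Rcpp::export]]
NumericVector cpp_inverse_dynamics(List pack, NumericVector q,
                                   NumericVector qd, NumericVector qdd,
                                   bool gravity, bool contact) {
  Model md = unpack(pack);
  std::vector<BodyKin> K;
  forward_kin(md, as<arma::vec>(q), as<arma::vec>(qd), as<arma::vec>(qdd), K);
  arma::vec Q;
  if (contact) {
    arma::mat ext = contact_forces(md, K);
    Q = inv_dyn(md, K, gravity, &ext);
  } else {
    Q = inv_dyn(md, K, gravity, nullptr);
  }
  return wrap(Q);
}

// [[Rcpp::export]]
NumericMatrix cpp_mass_matrix(List pack, NumericVector q) {
  Model md = unpack(pack);
  arma::vec qv = as<arma::vec>(q);
  arma::vec z(md.nq, arma::fill::zeros);
  arma::mat M(md.nq, md.nq);
  std::vector<BodyKin> K;
  for (int j = 0; j < md.nq; ++j) {
    arma::vec ej(md.nq, arma::fill::zeros);
    ej[j] = 1.0;
    forward_kin(md, qv, z, ej, K);
    M.col(j) = inv_dyn(md, K, false, nullptr);
  }
  return wrap(M);
}

// [[Rcpp::export]]
List cpp_mech_energy(List pack, NumericVector q, NumericVector qd) {
  Model md = unpack(pack);
  arma::vec z(md.nq, arma::fill::zeros);
  std::vector<BodyKin> K;
  forward_kin(md, as<arma::vec>(q), as<arma::vec>(qd), z, K);
  double T = 0.0, V = 0.0;
  for (int b = 0; b < md.nb; ++b) {
    double m = md.seg(b, 7), I = md.seg(b, 8);
    T += 0.5 * m * (K[b].vcx * K[b].vcx + K[b].vcy * K[b].vcy) +
         0.5 * I * K[b].om * K[b].om;
    V += m * md.grav * K[b].cy;
  }
  return List::create(_["kinetic"] = T, _["potential"] = V,
                      _["total"] = T + V);
}

// [[Rcpp::export]]
List cpp_muscle_state(List pack, NumericVector q, NumericVector qd,
                      NumericVector a) {
  Model md = unpack(pack);
  arma::vec lmn, vmn, F, tau;
  muscle_kin(md, as<arma::vec>(q), as<arma::vec>(qd), lmn, vmn);
  muscle_forces_torques(md, lmn, vmn, as<arma::vec>(a), F, tau);
  return List::create(_["lm_norm"] = lmn, _["vm_norm"] = vmn,
                      _["force"] = F, _["torque"] = tau);
}

// [[Rcpp::export]]
NumericVector cpp_passive_torques(List pack, NumericVector q,
                                  NumericVector qd) {
  Model md = unpack(pack);
  return wrap(passive_torques(md, as<arma::vec>(q), as<arma::vec>(qd)));
}

// ---------------------------------------------------------------------------
// direct-collocation NLP over a half gait cycle (trapezoidal defects,
// implicit skeletal dynamics with joint accelerations as controls)

struct OcpCfg {
  int N;
  double vtarget;
  double w1, w2, w3, w4;
  double sharp, tact, tdeact, actb;
  arma::vec cscale;
  arma::ivec qswap;   // symmetric image of each coordinate
  arma::ivec mswap;   // symmetric image of each muscle
  double masstot;
};

static OcpCfg read_cfg(const List& cfg) {
  OcpCfg c;
  c.N = as<int>(cfg["N"]);
  c.vtarget = as<double>(cfg["v_target"]);
  NumericVector w = cfg["weights"];
  c.w1 = w[0]; c.w2 = w[1]; c.w3 = w[2]; c.w4 = w[3];
  c.sharp = as<double>(cfg["sharp"]);
  c.tact = as<double>(cfg["tau_act"]);
  c.tdeact = as<double>(cfg["tau_deact"]);
  c.actb = as<double>(cfg["act_blend"]);
  c.cscale = as<arma::vec>(cfg["cscale"]);
  c.qswap = as<arma::ivec>(cfg["qswap"]);
  c.mswap = as<arma::ivec>(cfg["mswap"]);
  c.masstot = as<double>(cfg["mass_total"]);
  return c;
}

// variable layout per node: q(nq) qd(nq) a(nm) e(nm) ua(nq); then tf
static inline int blocksize(const Model& md) { return 3 * md.nq + 2 * md.nm; }

struct NodeEval {
  arma::vec adot;   // nm
  arma::vec dyn;    // nq dynamics residual (unscaled)
  double L;         // cost integrand
  arma::vec terms;  // 4 cost terms
  arma::vec phi;    // raw cost residuals: Edot(nm), a(nm), ua(nq), Tp(nq)
};

static void eval_node(const Model& md, const OcpCfg& cfg, const double* zn,
                      NodeEval& out) {
  int nq = md.nq, nm = md.nm;
  arma::vec q(nq), qd(nq), a(nm), e(nm), ua(nq);
  for (int i = 0; i < nq; ++i) q[i] = zn[i];
  for (int i = 0; i < nq; ++i) qd[i] = zn[nq + i];
  for (int i = 0; i < nm; ++i) a[i] = zn[2 * nq + i];
  for (int i = 0; i < nm; ++i) e[i] = zn[2 * nq + nm + i];
  for (int i = 0; i < nq; ++i) ua[i] = zn[2 * nq + 2 * nm + i];

  out.adot.set_size(nm);
  for (int m = 0; m < nm; ++m)
    out.adot[m] = act_rate(e[m], a[m], cfg.tact, cfg.tdeact, cfg.actb);

  std::vector<BodyKin> K;
  forward_kin(md, q, qd, ua, K);
  arma::mat ext = contact_forces(md, K);
  arma::vec Qreq = inv_dyn(md, K, true, &ext);

  arma::vec lmn, vmn, F, taum;
  muscle_kin(md, q, qd, lmn, vmn);
  muscle_forces_torques(md, lmn, vmn, a, F, taum);
  arma::vec tp = passive_torques(md, q, qd);
  out.dyn = Qreq - taum - tp;

  out.phi.set_size(2 * nm + 2 * nq);
  double Esq = 0.0;
  for (int m = 0; m < nm; ++m) {
    double Ed = metabolic_one(md.fmax[m], md.lopt[m], md.vmax[m], md.sigma[m],
                              md.shift[m], a[m], e[m], lmn[m], vmn[m],
                              cfg.sharp, true);
    Esq += Ed * Ed;
    out.phi[m] = Ed;
  }
  for (int m = 0; m < nm; ++m) out.phi[nm + m] = a[m];
  for (int i = 0; i < nq; ++i) out.phi[2 * nm + i] = ua[i];
  for (int i = 0; i < nq; ++i) out.phi[2 * nm + nq + i] = tp[i];
  double Asq = arma::dot(a, a);
  double Usq = arma::dot(ua, ua);
  double Tsq = arma::dot(tp, tp);
  out.terms = {cfg.w1 * Esq, cfg.w2 * Asq, cfg.w3 * Usq, cfg.w4 * Tsq};
  out.L = arma::sum(out.terms);
}


// ---------------------------------------------------------------------------
// Cyclic direct-collocation transcription over a half gait cycle.
//
// Decision variables: nodes 0..N-1 (q, qd, a, e, ua per node) plus the free
// half-cycle duration t_f. The periodicity-with-left/right-symmetry task
// constraint and the average-speed constraint are enforced by construction:
// the state and controls at node N are defined as the symmetry image of
// node 0 with the pelvis advanced by v_target * t_f. Constraints are then
// only the trapezoidal defects (intervals 0..N-1, the last one closing the
// cycle onto the mapped node 0) and the implicit-dynamics path constraints
// at nodes 0..N-1 (the mapped node N row is the mirror image of node 0's
// and therefore redundant on a left/right symmetric model).

// Append the mapped node N to a decision vector, giving the full
// (N+1)-node trajectory used for evaluation and post-processing.
static arma::vec extend_z(const Model& md, const OcpCfg& cfg,
                          const arma::vec& z) {
  int nq = md.nq, nm = md.nm, N = cfg.N;
  int bs = blocksize(md);
  double tf = z[bs * N];
  arma::vec zx(bs * (N + 1) + 1);
  zx.subvec(0, bs * N - 1) = z.subvec(0, bs * N - 1);
  const double* z0 = z.memptr();
  double* zn = zx.memptr() + (size_t)N * bs;
  for (int i = 0; i < nq; ++i) zn[i] = z0[cfg.qswap[i]];
  zn[0] = z0[0] + cfg.vtarget * tf;
  for (int i = 0; i < nq; ++i) zn[nq + i] = z0[nq + cfg.qswap[i]];
  for (int i = 0; i < nm; ++i) zn[2 * nq + i] = z0[2 * nq + cfg.mswap[i]];
  for (int i = 0; i < nm; ++i) {
    zn[2 * nq + nm + i] = z0[2 * nq + nm + cfg.mswap[i]];
  }
  for (int i = 0; i < nq; ++i) {
    zn[2 * nq + 2 * nm + i] = z0[2 * nq + 2 * nm + cfg.qswap[i]];
  }
  zx[bs * (N + 1)] = tf;
  return zx;
}

// [[Rcpp::export]]
NumericVector cpp_extend_z(NumericVector z, List pack, List cfg) {
  Model md = unpack(pack);
  OcpCfg oc = read_cfg(cfg);
  return wrap(extend_z(md, oc, as<arma::vec>(z)));
}

// Full trajectory evaluation: scaled constraints, cost, per-node integrand.
static void eval_traj(const Model& md, const OcpCfg& cfg, const arma::vec& z,
                      arma::vec& cons, double& cost, arma::vec& Lnodes,
                      arma::vec& termint, double& dist, double& tf,
                      arma::mat* phiout = nullptr) {
  int nq = md.nq, nm = md.nm, N = cfg.N;
  int bs = blocksize(md);
  int ns = 2 * nq + nm;  // state dimension q,qd,a
  arma::vec zx = extend_z(md, cfg, z);
  tf = zx[bs * (N + 1)];
  dist = cfg.vtarget * tf;
  double h = tf / N;

  // dynamics and cost integrand at free nodes 0..N-1; the mapped node N has
  // identical integrand and mirrored dynamics by symmetry
  std::vector<NodeEval> ev(N);
  Lnodes.set_size(N);
  if (phiout) phiout->set_size(N, 2 * nm + 2 * nq);
  for (int k = 0; k < N; ++k) {
    eval_node(md, cfg, zx.memptr() + (size_t)k * bs, ev[k]);
    Lnodes[k] = ev[k].L;
    if (phiout) phiout->row(k) = ev[k].phi.t();
  }
  // activation rates at the mapped node N (for the closing defect):
  // mirror of node 0's rates
  arma::vec adotN(nm);
  for (int i = 0; i < nm; ++i) adotN[i] = ev[0].adot[cfg.mswap[i]];

  int mdef = ns * N;
  int mtot = mdef + nq * N;
  cons.set_size(mtot);
  for (int k = 0; k < N; ++k) {
    const double* a0 = zx.memptr() + (size_t)k * bs;
    const double* a1 = zx.memptr() + (size_t)(k + 1) * bs;
    const arma::vec& ad0 = ev[k].adot;
    const arma::vec& ad1 = (k + 1 < N) ? ev[k + 1].adot : adotN;
    int r0 = k * ns;
    for (int i = 0; i < nq; ++i) {
      cons[r0 + i] = a1[i] - a0[i] - 0.5 * h * (a0[nq + i] + a1[nq + i]);
    }
    for (int i = 0; i < nq; ++i) {
      cons[r0 + nq + i] = a1[nq + i] - a0[nq + i] -
          0.5 * h * (a0[2 * nq + 2 * nm + i] + a1[2 * nq + 2 * nm + i]);
    }
    for (int i = 0; i < nm; ++i) {
      cons[r0 + 2 * nq + i] = a1[2 * nq + i] - a0[2 * nq + i] -
          0.5 * h * (ad0[i] + ad1[i]);
    }
  }
  for (int k = 0; k < N; ++k) {
    for (int i = 0; i < nq; ++i) cons[mdef + k * nq + i] = ev[k].dyn[i];
  }
  cons %= cfg.cscale;

  // cost: trapezoidal integral over the half cycle divided by distance;
  // since L(node N) = L(node 0) by symmetry the quadrature collapses to a
  // plain sum, and h/d = 1/(v_target * N) is constant
  double S = arma::sum(Lnodes);
  cost = S / (cfg.vtarget * N);
  termint.zeros(4);
  for (int k = 0; k < N; ++k) termint += ev[k].terms;
  termint /= (cfg.vtarget * N);
}

// [[Rcpp::export]]
List cpp_nlp_eval(NumericVector z, List pack, List cfg) {
  Model md = unpack(pack);
  OcpCfg oc = read_cfg(cfg);
  arma::vec cons, Lnodes, termint;
  double cost, dist, tf;
  eval_traj(md, oc, as<arma::vec>(z), cons, cost, Lnodes, termint, dist, tf);
  return List::create(_["cost"] = cost, _["constraints"] = cons,
                      _["integrand"] = Lnodes, _["terms"] = termint,
                      _["distance"] = dist, _["tf"] = tf);
}

// Structural sparsity: owner (free) nodes of each constraint row. The
// closing interval N-1 couples node N-1 with node 0 through the symmetry
// map.
static void row_owners(const Model& md, const OcpCfg& cfg,
                       arma::imat& owners) {
  int nq = md.nq, nm = md.nm, N = cfg.N;
  int ns = 2 * nq + nm;
  int mdef = ns * N;
  int mtot = mdef + nq * N;
  owners.set_size(mtot, 2);
  owners.fill(-1);
  for (int k = 0; k < N; ++k) {
    for (int i = 0; i < ns; ++i) {
      owners(k * ns + i, 0) = k;
      owners(k * ns + i, 1) = (k + 1 < N) ? (k + 1) : 0;
    }
  }
  for (int k = 0; k < N; ++k) {
    for (int i = 0; i < nq; ++i) owners(mdef + k * nq + i, 0) = k;
  }
}

// FD coloring groups: node 0 alone (it owns the closing defect), remaining
// nodes by k mod 3, tf separate.
static void make_groups(int N, std::vector<int>& ngroup) {
  ngroup.resize(N);
  ngroup[0] = 3;
  for (int k = 1; k < N; ++k) ngroup[k] = k % 3;
}

// Colored finite-difference Jacobian of the scaled constraints.
// [[Rcpp::export]]
List cpp_nlp_jac(NumericVector z_, List pack, List cfg, double fdstep,
                 bool centered = false) {
  Model md = unpack(pack);
  OcpCfg oc = read_cfg(cfg);
  arma::vec z = as<arma::vec>(z_);
  int N = oc.N, bs = blocksize(md);
  int nvar = bs * N + 1;

  arma::vec c0, Lnodes, termint;
  double cost0, dist, tf;
  eval_traj(md, oc, z, c0, cost0, Lnodes, termint, dist, tf);
  int mtot = c0.n_elem;

  arma::imat owners;
  row_owners(md, oc, owners);
  std::vector<int> ngroup;
  make_groups(N, ngroup);
  std::vector<std::vector<std::pair<int, int>>> grows(4);
  for (int r = 0; r < mtot; ++r) {
    for (int s = 0; s < 2; ++s) {
      int nd = owners(r, s);
      if (nd >= 0 && !(s == 1 && nd == owners(r, 0))) {
        grows[ngroup[nd]].push_back({r, nd});
      }
    }
  }

  std::vector<int> ti, tj;
  std::vector<double> tv;
  ti.reserve(200000); tj.reserve(200000); tv.reserve(200000);

  arma::vec zp, cp, cm, Lp, tp_;
  double costp, distp, tfp;
  for (int g = 0; g < 4; ++g) {
    if (grows[g].empty()) continue;
    for (int s = 0; s < bs; ++s) {
      zp = z;
      for (int k = 0; k < N; ++k) {
        if (ngroup[k] == g) zp[(size_t)k * bs + s] += fdstep;
      }
      eval_traj(md, oc, zp, cp, costp, Lp, tp_, distp, tfp);
      if (centered) {
        zp = z;
        for (int k = 0; k < N; ++k) {
          if (ngroup[k] == g) zp[(size_t)k * bs + s] -= fdstep;
        }
        eval_traj(md, oc, zp, cm, costp, Lp, tp_, distp, tfp);
      }
      for (auto& pr : grows[g]) {
        double dv = centered
            ? (cp[pr.first] - cm[pr.first]) / (2 * fdstep)
            : (cp[pr.first] - c0[pr.first]) / fdstep;
        if (dv != 0.0) {
          ti.push_back(pr.first);
          tj.push_back(pr.second * bs + s);
          tv.push_back(dv);
        }
      }
    }
  }
  // tf column
  zp = z; zp[nvar - 1] += fdstep;
  eval_traj(md, oc, zp, cp, costp, Lp, tp_, distp, tfp);
  if (centered) {
    zp = z; zp[nvar - 1] -= fdstep;
    eval_traj(md, oc, zp, cm, costp, Lp, tp_, distp, tfp);
  }
  for (int r = 0; r < mtot; ++r) {
    double dv = centered ? (cp[r] - cm[r]) / (2 * fdstep)
                         : (cp[r] - c0[r]) / fdstep;
    if (dv != 0.0) {
      ti.push_back(r); tj.push_back(nvar - 1); tv.push_back(dv);
    }
  }

  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["v"] = wrap(tv), _["m"] = mtot, _["n"] = nvar,
                      _["c"] = c0, _["cost"] = cost0);
}

// Per-node trajectory outputs for post-processing: ground-reaction forces
// per leg, joint torque decomposition, metabolic rate, fiber kinematics.
// [[Rcpp::export]]
List cpp_traj_outputs(NumericVector z_, List pack, List cfg) {
  Model md = unpack(pack);
  OcpCfg oc = read_cfg(cfg);
  arma::vec zx = extend_z(md, oc, as<arma::vec>(z_));
  int N = oc.N, bs = blocksize(md), nq = md.nq, nm = md.nm;
  arma::mat grf_r(N + 1, 2, arma::fill::zeros),
      grf_l(N + 1, 2, arma::fill::zeros);
  arma::mat tau_mus(N + 1, nq), tau_pas(N + 1, nq);
  arma::vec edot(N + 1, arma::fill::zeros);
  arma::mat lmn_all(N + 1, nm), act_all(N + 1, nm);
  // bodies 4,5 are right hindfoot/forefoot, 8,9 left (fixed layout)
  for (int k = 0; k <= N; ++k) {
    const double* zn = zx.memptr() + (size_t)k * bs;
    arma::vec q(nq), qd(nq), a(nm), e(nm), ua(nq);
    for (int i = 0; i < nq; ++i) q[i] = zn[i];
    for (int i = 0; i < nq; ++i) qd[i] = zn[nq + i];
    for (int i = 0; i < nm; ++i) a[i] = zn[2 * nq + i];
    for (int i = 0; i < nm; ++i) e[i] = zn[2 * nq + nm + i];
    for (int i = 0; i < nq; ++i) ua[i] = zn[2 * nq + 2 * nm + i];
    std::vector<BodyKin> K;
    forward_kin(md, q, qd, ua, K);
    arma::mat ext = contact_forces(md, K);
    for (arma::uword i = 0; i < ext.n_rows; ++i) {
      int b = (int)ext(i, 0);
      if (b == 4 || b == 5) {
        grf_r(k, 0) += ext(i, 1); grf_r(k, 1) += ext(i, 2);
      } else if (b == 8 || b == 9) {
        grf_l(k, 0) += ext(i, 1); grf_l(k, 1) += ext(i, 2);
      }
    }
    arma::vec lmn, vmn, F, taum;
    muscle_kin(md, q, qd, lmn, vmn);
    muscle_forces_torques(md, lmn, vmn, a, F, taum);
    tau_mus.row(k) = taum.t();
    tau_pas.row(k) = passive_torques(md, q, qd).t();
    lmn_all.row(k) = lmn.t();
    act_all.row(k) = a.t();
    for (int m = 0; m < nm; ++m) {
      edot[k] += metabolic_one(md.fmax[m], md.lopt[m], md.vmax[m],
                               md.sigma[m], md.shift[m], a[m], e[m], lmn[m],
                               vmn[m], oc.sharp, true);
    }
  }
  return List::create(_["grf_r"] = grf_r, _["grf_l"] = grf_l,
                      _["tau_muscle"] = tau_mus, _["tau_passive"] = tau_pas,
                      _["metabolic_rate"] = edot, _["lm_norm"] = lmn_all,
                      _["activation"] = act_all);
}

// ---------------------------------------------------------------------------
// Gauss-Newton residual stack for the augmented-Lagrangian least-squares
// solver. The cost is an exact sum of squares, so the NLP is solved as
// constrained nonlinear least squares:
//   rho(z) = [ sqrt(mu) * (c(z) + lambda/mu) ;
//              sqrt(w_term / (v_target N)) * phi_k(z) ;
//              sqrt(track_w) * (q - q_ref) ]
// where phi_k = (Edot_m, a_m, ua_j, Tp_j) are the raw per-node cost
// residuals, so that the sum of squared cost rows equals the cost exactly
// (the h/d quadrature prefactor is the constant 1/(v_target N)).

static void gn_assemble(const Model& md, const OcpCfg& cfg,
                        const arma::vec& z, const arma::vec& c0,
                        const arma::mat& phi0, const arma::vec& lamshift,
                        double sqmu, double track_w,
                        const arma::vec& track_ref,
                        arma::vec& wcol, arma::vec& rho) {
  int nq = md.nq, nm = md.nm, N = cfg.N;
  int bs = blocksize(md);
  int nr = 2 * nm + 2 * nq;
  int mcon = c0.n_elem;
  double pref = 1.0 / std::sqrt(cfg.vtarget * N);
  wcol.set_size(nr);
  for (int i = 0; i < nm; ++i) wcol[i] = pref * std::sqrt(cfg.w1);
  for (int i = 0; i < nm; ++i) wcol[nm + i] = pref * std::sqrt(cfg.w2);
  for (int i = 0; i < nq; ++i) wcol[2 * nm + i] = pref * std::sqrt(cfg.w3);
  for (int i = 0; i < nq; ++i) {
    wcol[2 * nm + nq + i] = pref * std::sqrt(cfg.w4);
  }
  int mtrack = (track_w > 0.0) ? N * nq : 0;
  rho.set_size(mcon + N * nr + mtrack);
  for (int r = 0; r < mcon; ++r) rho[r] = sqmu * (c0[r] + lamshift[r]);
  for (int k = 0; k < N; ++k) {
    for (int r = 0; r < nr; ++r) {
      rho[mcon + k * nr + r] = wcol[r] * phi0(k, r);
    }
  }
  if (track_w > 0.0) {
    double sw = std::sqrt(track_w);
    int off = mcon + N * nr;
    for (int k = 0; k < N; ++k) {
      for (int i = 0; i < nq; ++i) {
        rho[off + k * nq + i] =
            sw * (z[(size_t)k * bs + i] - track_ref[(size_t)k * bs + i]);
      }
    }
  }
}

// Residual-only evaluation (cheap; used by the LM line search).
// [[Rcpp::export]]
List cpp_gn_eval(NumericVector z_, List pack, List cfg,
                 NumericVector lamshift_, double sqmu, double track_w,
                 NumericVector track_ref_) {
  Model md = unpack(pack);
  OcpCfg oc = read_cfg(cfg);
  arma::vec z = as<arma::vec>(z_);
  arma::vec track_ref = as<arma::vec>(track_ref_);
  arma::vec c0, L0, t0;
  arma::mat phi0;
  double cost0, dist, tf;
  eval_traj(md, oc, z, c0, cost0, L0, t0, dist, tf, &phi0);
  arma::vec wcol, rho;
  gn_assemble(md, oc, z, c0, phi0, as<arma::vec>(lamshift_), sqmu, track_w,
              track_ref, wcol, rho);
  return List::create(_["rho"] = rho, _["c"] = c0, _["cost"] = cost0,
                      _["obj"] = 0.5 * arma::dot(rho, rho));
}

// Sparse Jacobian of the stacked residual by structural coloring.
// [[Rcpp::export]]
List cpp_gn_jac(NumericVector z_, List pack, List cfg,
                NumericVector lamshift_, double sqmu, double fdstep,
                double track_w, NumericVector track_ref_) {
  Model md = unpack(pack);
  OcpCfg oc = read_cfg(cfg);
  arma::vec z = as<arma::vec>(z_);
  arma::vec lamshift = as<arma::vec>(lamshift_);
  arma::vec track_ref = as<arma::vec>(track_ref_);
  int N = oc.N, bs = blocksize(md), nq = md.nq, nm = md.nm;
  int nvar = bs * N + 1;
  int nr = 2 * nm + 2 * nq;

  arma::vec c0, L0, t0;
  arma::mat phi0;
  double cost0, dist, tf;
  eval_traj(md, oc, z, c0, cost0, L0, t0, dist, tf, &phi0);
  int mcon = c0.n_elem;
  arma::vec wcol, rho;
  gn_assemble(md, oc, z, c0, phi0, lamshift, sqmu, track_w, track_ref,
              wcol, rho);

  arma::imat owners;
  row_owners(md, oc, owners);
  std::vector<int> ngroup;
  make_groups(N, ngroup);
  std::vector<std::vector<std::pair<int, int>>> grows(4);
  for (int r = 0; r < mcon; ++r) {
    for (int s = 0; s < 2; ++s) {
      int nd = owners(r, s);
      if (nd >= 0 && !(s == 1 && nd == owners(r, 0))) {
        grows[ngroup[nd]].push_back({r, nd});
      }
    }
  }
  std::vector<std::vector<int>> gnodes(4);
  for (int k = 0; k < N; ++k) gnodes[ngroup[k]].push_back(k);

  std::vector<int> ti, tj;
  std::vector<double> tv;
  ti.reserve(300000); tj.reserve(300000); tv.reserve(300000);

  arma::vec zp, cp, Lp, tp_;
  arma::mat phip;
  double costp, distp, tfp;
  for (int g = 0; g < 4; ++g) {
    if (gnodes[g].empty()) continue;
    for (int s = 0; s < bs; ++s) {
      zp = z;
      for (int k : gnodes[g]) zp[(size_t)k * bs + s] += fdstep;
      eval_traj(md, oc, zp, cp, costp, Lp, tp_, distp, tfp, &phip);
      for (auto& pr : grows[g]) {
        double dv = sqmu * (cp[pr.first] - c0[pr.first]) / fdstep;
        if (dv != 0.0) {
          ti.push_back(pr.first);
          tj.push_back(pr.second * bs + s);
          tv.push_back(dv);
        }
      }
      for (int k : gnodes[g]) {
        for (int r = 0; r < nr; ++r) {
          double dv = wcol[r] * (phip(k, r) - phi0(k, r)) / fdstep;
          if (dv != 0.0) {
            ti.push_back(mcon + k * nr + r);
            tj.push_back(k * bs + s);
            tv.push_back(dv);
          }
        }
      }
    }
  }
  // t_f column (constraints only; the cost prefactor is tf-independent)
  zp = z; zp[nvar - 1] += fdstep;
  eval_traj(md, oc, zp, cp, costp, Lp, tp_, distp, tfp);
  for (int r = 0; r < mcon; ++r) {
    double dv = sqmu * (cp[r] - c0[r]) / fdstep;
    if (dv != 0.0) {
      ti.push_back(r); tj.push_back(nvar - 1); tv.push_back(dv);
    }
  }
  // kinematic-tracking rows: diagonal, analytic
  if (track_w > 0.0) {
    double sw = std::sqrt(track_w);
    int off = mcon + N * nr;
    for (int k = 0; k < N; ++k) {
      for (int i = 0; i < nq; ++i) {
        ti.push_back(off + k * nq + i);
        tj.push_back(k * bs + i);
        tv.push_back(sw);
      }
    }
  }

  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj), _["v"] = wrap(tv),
                      _["m"] = (int)rho.n_elem, _["n"] = nvar, _["rho"] = rho,
                      _["c"] = c0, _["cost"] = cost0,
                      _["obj"] = 0.5 * arma::dot(rho, rho),
                      _["distance"] = dist, _["tf"] = tf);
}
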