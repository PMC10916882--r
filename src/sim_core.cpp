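#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Lateral 1-DOF six-mass vocal-fold model, SI units throughout.
//
// State layout (12 masses): index = side*6 + section*2 + level
//   side    0 = left (negative lateral half-plane), 1 = right
//   section 0 = posterior, 1 = medial, 2 = anterior
//   level   0 = bottom (lower mass), 1 = top (upper mass)
//
// Config vector layout matches config_si() on the R side.
enum CfgField {
  M_BOTTOM, M_TOP, KA_BOTTOM, KA_TOP, P_S, XI_C, XI_L, K_V, R_A,
  ETA, ELL_L, ELL_V, SEG_WIDTH, ANCHOR_POST, ANCHOR_ANT, DT,
  INIT_DEFL, KC_FACTOR, SMOOTH_EPS
};

static inline int idx(int side, int sec, int lev) {
  return side * 6 + sec * 2 + lev;
}

// smoothed sign: 2*sigmoid(z/eps) - 1, the direction factor of the lateral
// coupling response (continuous at 0)
static inline double smoothsign(double z, double eps) {
  return 2.0 / (1.0 + std::exp(-z / eps)) - 1.0;
}

// lateral response magnitude of a spring with free length ell under lateral
// offset d between its ends: k * (sqrt(d^2 + ell^2) - ell)
static inline double lat_mag(double d, double k, double ell) {
  return k * (std::sqrt(d * d + ell * ell) - ell);
}

struct Model {
  double cfg[19];
  double rest[6];     // signed lateral rest positions (m), (L,R) x (P,M,A)
  double q_m[6];      // reciprocal mass factors
  double q_k[6];      // anchor stiffness factors
  double q_ps, q_xi;

  double mass(int side, int sec, int lev) const {
    double m0 = (lev == 0) ? cfg[M_BOTTOM] : cfg[M_TOP];
    return m0 / q_m[side * 3 + sec];
  }
  double ka(int side, int sec, int lev) const {
    double k0 = (lev == 0) ? cfg[KA_BOTTOM] : cfg[KA_TOP];
    return k0 * q_k[side * 3 + sec];
  }

  // total lateral force on every mass
  void forces(const double *x, const double *v, double *F) const {
    const double eps = cfg[SMOOTH_EPS];
    const double eta = cfg[ETA], ra = cfg[R_A];
    const double ell_v = cfg[ELL_V], ell_l = cfg[ELL_L];
    const double xi_l = cfg[XI_L];
    for (int i = 0; i < 12; ++i) F[i] = 0.0;

    // anchor force (cubic spring to rest position + damping)
    for (int s = 0; s < 2; ++s)
      for (int j = 0; j < 3; ++j)
        for (int l = 0; l < 2; ++l) {
          int i = idx(s, j, l);
          double dx = x[i] - rest[s * 3 + j];
          F[i] += -ka(s, j, l) * dx * (1.0 + eta * dx * dx) - ra * v[i];
        }

    // vertical coupling within each pair
    for (int s = 0; s < 2; ++s)
      for (int j = 0; j < 3; ++j) {
        int ib = idx(s, j, 0), it = idx(s, j, 1);
        double d = x[it] - x[ib];
        double f = smoothsign(d, eps) * lat_mag(d, cfg[K_V], ell_v);
        F[it] -= f;
        F[ib] += f;
      }

    // longitudinal chains: fixedP -- P -- M -- A -- fixedA, per side and level
    for (int s = 0; s < 2; ++s) {
      double sgn = (s == 0) ? -1.0 : 1.0;
      double xp = sgn * cfg[ANCHOR_POST];
      double xa = sgn * cfg[ANCHOR_ANT];
      for (int l = 0; l < 2; ++l) {
        double node[5] = {xp, x[idx(s, 0, l)], x[idx(s, 1, l)], x[idx(s, 2, l)], xa};
        double kk[4] = {
          xi_l * 2.0 * ka(s, 0, l),
          xi_l * (ka(s, 0, l) + ka(s, 1, l)),
          xi_l * (ka(s, 1, l) + ka(s, 2, l)),
          xi_l * 2.0 * ka(s, 2, l)
        };
        for (int sp = 0; sp < 4; ++sp) {
          double d = node[sp] - node[sp + 1];
          double f = smoothsign(d, eps) * lat_mag(d, kk[sp], ell_l);
          if (sp > 0) F[idx(s, sp - 1, l)] -= f;      // node sp is mass sp-1
          if (sp < 3) F[idx(s, sp, l)] += f;          // node sp+1 is mass sp
        }
      }
    }

    // collision: push-back when left overlaps right at a (section, level)
    double kc_f = cfg[KC_FACTOR] * cfg[XI_C] * q_xi;
    for (int j = 0; j < 3; ++j)
      for (int l = 0; l < 2; ++l) {
        int il = idx(0, j, l), ir = idx(1, j, l);
        double pen = x[il] - x[ir];
        if (pen > 0.0) {
          double kc = kc_f * 0.5 * (ka(0, j, l) + ka(1, j, l));
          double f = kc * 0.5 * pen;   // penetration depth per side = pen/2
          F[il] -= f;
          F[ir] += f;
        }
      }

    // Bernoulli driving pressure on the lower masses of open, convergent
    // columns; full pressure below a closed upper section; nothing above the
    // point of closure
    double plate = cfg[SEG_WIDTH] * cfg[ELL_V];
    double ps = cfg[P_S] * q_ps;
    for (int j = 0; j < 3; ++j) {
      double w1 = x[idx(1, j, 0)] - x[idx(0, j, 0)];
      double w2 = x[idx(1, j, 1)] - x[idx(0, j, 1)];
      if (w1 > 0.0) {
        double p1;
        if (w2 <= 0.0)      p1 = ps;
        else if (w2 < w1)   p1 = ps * (1.0 - (w2 / w1) * (w2 / w1));
        else                p1 = 0.0;
        double f = p1 * plate;
        F[idx(0, j, 0)] -= f;
        F[idx(1, j, 0)] += f;
      }
    }
  }

  void accel(const double *x, const double *v, double *a) const {
    double F[12];
    forces(x, v, F);
    for (int s = 0; s < 2; ++s)
      for (int j = 0; j < 3; ++j)
        for (int l = 0; l < 2; ++l) {
          int i = idx(s, j, l);
          a[i] = F[i] / mass(s, j, l);
        }
  }
};

static Model make_model(NumericVector cfg, NumericVector q, NumericVector rest) {
  if (cfg.size() != 19) stop("config vector must have 19 fields");
  if (q.size() != 14) stop("scaling vector must have 14 components");
  if (rest.size() != 6) stop("rest-position grid must have 6 entries");
  Model m;
  for (int i = 0; i < 19; ++i) m.cfg[i] = cfg[i];
  for (int i = 0; i < 6; ++i) { m.q_m[i] = q[i]; m.q_k[i] = q[6 + i]; }
  m.q_ps = q[12];
  m.q_xi = q[13];
  for (int i = 0; i < 6; ++i) m.rest[i] = rest[i];
  return m;
}

// [[Rcpp::export(name = ".forces_cpp")]]
NumericVector forces_cpp(NumericVector x, NumericVector v,
                         NumericVector q, NumericVector rest,
                         NumericVector cfg) {
  Model m = make_model(cfg, q, rest);
  NumericVector F(12);
  double Fd[12];
  m.forces(REAL(x), REAL(v), Fd);
  for (int i = 0; i < 12; ++i) F[i] = Fd[i];
  return F;
}

// [[Rcpp::export(name = ".accel_cpp")]]
NumericVector accel_cpp(NumericVector x, NumericVector v,
                        NumericVector q, NumericVector rest,
                        NumericVector cfg) {
  Model m = make_model(cfg, q, rest);
  NumericVector a(12);
  double ad[12];
  m.accel(REAL(x), REAL(v), ad);
  for (int i = 0; i < 12; ++i) a[i] = ad[i];
  return a;
}

// Classical RK4 integration of the 12-mass lateral system.
// Returns trajectories (6 x n, metres, signed minimal-|x| member per pair,
// tie -> lower mass) and optionally the full state history.
// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(NumericVector q, NumericVector rest, NumericVector cfg,
                  int n_steps, bool keep_history = false) {
  Model m = make_model(cfg, q, rest);
  const double dt = m.cfg[DT];
  double x[12], v[12];
  // initial condition: lower masses deflected outward, upper at rest, v = 0
  for (int s = 0; s < 2; ++s) {
    double sgn = (s == 0) ? -1.0 : 1.0;
    for (int j = 0; j < 3; ++j) {
      x[idx(s, j, 0)] = m.rest[s * 3 + j] + sgn * m.cfg[INIT_DEFL];
      x[idx(s, j, 1)] = m.rest[s * 3 + j];
      v[idx(s, j, 0)] = 0.0;
      v[idx(s, j, 1)] = 0.0;
    }
  }

  NumericMatrix traj(6, n_steps);
  NumericMatrix xh, vh;
  if (keep_history) {
    xh = NumericMatrix(12, n_steps);
    vh = NumericMatrix(12, n_steps);
  }
  std::fill(traj.begin(), traj.end(), NA_REAL);

  double k1x[12], k1v[12], k2x[12], k2v[12], k3x[12], k3v[12], k4x[12], k4v[12];
  double xt[12], vt[12];
  bool ok = true;
  int bad_step = NA_INTEGER;

  for (int step = 0; step < n_steps; ++step) {
    // k1
    m.accel(x, v, k1v);
    for (int i = 0; i < 12; ++i) k1x[i] = v[i];
    // k2
    for (int i = 0; i < 12; ++i) {
      xt[i] = x[i] + 0.5 * dt * k1x[i];
      vt[i] = v[i] + 0.5 * dt * k1v[i];
    }
    m.accel(xt, vt, k2v);
    for (int i = 0; i < 12; ++i) k2x[i] = vt[i];
    // k3
    for (int i = 0; i < 12; ++i) {
      xt[i] = x[i] + 0.5 * dt * k2x[i];
      vt[i] = v[i] + 0.5 * dt * k2v[i];
    }
    m.accel(xt, vt, k3v);
    for (int i = 0; i < 12; ++i) k3x[i] = vt[i];
    // k4
    for (int i = 0; i < 12; ++i) {
      xt[i] = x[i] + dt * k3x[i];
      vt[i] = v[i] + dt * k3v[i];
    }
    m.accel(xt, vt, k4v);
    for (int i = 0; i < 12; ++i) k4x[i] = vt[i];

    bool finite = true;
    for (int i = 0; i < 12; ++i) {
      x[i] += dt / 6.0 * (k1x[i] + 2.0 * k2x[i] + 2.0 * k3x[i] + k4x[i]);
      v[i] += dt / 6.0 * (k1v[i] + 2.0 * k2v[i] + 2.0 * k3v[i] + k4v[i]);
      if (!std::isfinite(x[i]) || !std::isfinite(v[i])) finite = false;
    }
    if (!finite) {
      ok = false;
      bad_step = step + 1;
      break;
    }

    for (int s = 0; s < 2; ++s)
      for (int j = 0; j < 3; ++j) {
        double xb = x[idx(s, j, 0)], xu = x[idx(s, j, 1)];
        // minimal distance to the midline; tie -> lower mass
        traj(s * 3 + j, step) = (std::fabs(xu) < std::fabs(xb)) ? xu : xb;
      }
    if (keep_history)
      for (int i = 0; i < 12; ++i) {
        xh(i, step) = x[i];
        vh(i, step) = v[i];
      }
  }

  List out = List::create(
    Named("traj") = traj,
    Named("ok") = ok,
    Named("bad_step") = bad_step
  );
  if (keep_history) {
    out["x_hist"] = xh;
    out["v_hist"] = vh;
  }
  return out;
}
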