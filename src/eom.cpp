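// Equations of motion of the planar head-neck chain under prescribed base
// (T1) motion, in relative joint coordinates (revolute rotations from the
// initial posture, plus one prismatic elongation when present).
//
// Conventions match the R side: X anterior, Z superior, rotation about +Y,
// local-to-global R(th) = [c, s; -s, c] on (x, z); R'' = -R.
//
// The generalized equations are M(q) qdd = Q(q, qd, t), assembled from the
// CG Jacobians of each body (virtual-power form).  The prescribed base
// motion enters only through the acceleration remainder gamma (support
// excitation) because gravity is uniform and the springs depend on q alone.
//
// The right-hand side is exposed both as an Rcpp function (for single-state
// evaluation from R) and as the plain-C routine `whipneck_rhs` driven
// directly by deSolve's compiled-function interface; the active model and
// base-motion splines for the latter are installed with .eom_set_model_cpp.

#include <RcppArmadillo.h>
#include <vector>
using namespace Rcpp;

#define MAXN 16

// Natural cubic spline in the piecewise-polynomial form used by
// stats::splinefun (knots x, values y, coefficients b, c, d); evaluation
// clamps to the boundary polynomials outside the knot span.
struct Spline {
  std::vector<double> x, y, b, c, d;
  bool empty() const { return x.empty(); }
  double eval(double t, int deriv) const {
    const int n = (int)x.size();
    if (t < x[0]) {             // linear extrapolation, boundary slope
      if (deriv == 0) return y[0] + b[0] * (t - x[0]);
      if (deriv == 1) return b[0];
      return 0.0;
    }
    if (t > x[n - 1]) {
      if (deriv == 0) return y[n - 1] + b[n - 1] * (t - x[n - 1]);
      if (deriv == 1) return b[n - 1];
      return 0.0;
    }
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) {       // binary search: largest knot <= t
      int mid = (lo + hi) / 2;
      if (x[mid] <= t) lo = mid; else hi = mid;
    }
    double dx = t - x[lo];
    if (deriv == 0) return y[lo] + dx * (b[lo] + dx * (c[lo] + dx * d[lo]));
    if (deriv == 1) return b[lo] + dx * (2.0 * c[lo] + 3.0 * d[lo] * dx);
    return 2.0 * c[lo] + 6.0 * d[lo] * dx;
  }
};

struct Model {
  int n;
  double mass[MAXN], iyy[MAXN], sx[MAXN], sz[MAXN], gx[MAXN], gz[MAXN],
         theta0[MAXN], A1[MAXN], B1[MAXN], A2[MAXN], B2[MAXN], C[MAXN],
         preload[MAXN];
  int jtype[MAXN];             // 0 revolute, 1 prismatic
  double kv, cv, ux, uz, g, th_base0;
  bool has_motion, has_rot;
  Spline spl_x, spl_z, spl_r;
  double rot0;
};

static void model_from_list(const List& cp, Model& p) {
  p.n = as<int>(cp["n"]);
  if (p.n > MAXN) stop("chain too long");
  NumericVector mass = cp["mass"], iyy = cp["iyy"], sx = cp["sx"],
    sz = cp["sz"], gx = cp["gx"], gz = cp["gz"], theta0 = cp["theta0"],
    A1 = cp["A1"], B1 = cp["B1"], A2 = cp["A2"], B2 = cp["B2"], C = cp["C"],
    preload = cp["preload"];
  IntegerVector jtype = cp["jtype"];
  for (int i = 0; i < p.n; ++i) {
    p.mass[i] = mass[i]; p.iyy[i] = iyy[i];
    p.sx[i] = sx[i]; p.sz[i] = sz[i]; p.gx[i] = gx[i]; p.gz[i] = gz[i];
    p.theta0[i] = theta0[i];
    p.A1[i] = A1[i]; p.B1[i] = B1[i]; p.A2[i] = A2[i]; p.B2[i] = B2[i];
    p.C[i] = C[i]; p.preload[i] = preload[i];
    p.jtype[i] = jtype[i];
  }
  p.kv = as<double>(cp["kv"]); p.cv = as<double>(cp["cv"]);
  p.ux = as<double>(cp["axx"]); p.uz = as<double>(cp["axz"]);
  p.g = as<double>(cp["g"]); p.th_base0 = as<double>(cp["th_base0"]);
  p.has_motion = false; p.has_rot = false; p.rot0 = 0.0;
}

static void spline_from_list(const List& sl, Spline& s) {
  NumericVector x = sl["x"], y = sl["y"], b = sl["b"], c = sl["c"], d = sl["d"];
  s.x.assign(x.begin(), x.end()); s.y.assign(y.begin(), y.end());
  s.b.assign(b.begin(), b.end()); s.c.assign(c.begin(), c.end());
  s.d.assign(d.begin(), d.end());
}

static inline double spring_m(const Model& p, int i, double x) {
  if (x < 0.0) return p.A1[i] * (std::exp(p.B1[i] * x) - 1.0);
  return p.A2[i] * (std::exp(p.B2[i] * x) - 1.0);
}
static inline double spring_u(const Model& p, int i, double x) {
  if (x == 0.0) return 0.0;
  double A = (x < 0.0) ? p.A1[i] : p.A2[i];
  double B = (x < 0.0) ? p.B1[i] : p.B2[i];
  return A * ((std::exp(B * x) - 1.0) / B - x);
}

// base = (th_off, w, al, ax, az, vx, vz)
static void eval_base(const Model& p, double t, double* base) {
  for (int i = 0; i < 7; ++i) base[i] = 0.0;
  if (!p.has_motion) return;
  base[3] = p.spl_x.eval(t, 2); base[4] = p.spl_z.eval(t, 2);
  base[5] = p.spl_x.eval(t, 1); base[6] = p.spl_z.eval(t, 1);
  if (p.has_rot) {
    base[0] = p.spl_r.eval(t, 0) - p.rot0;
    base[1] = p.spl_r.eval(t, 1);
    base[2] = p.spl_r.eval(t, 2);
  }
}

// Workspace: per-body kinematics, CG Jacobians, mass matrix and forces.
struct WS {
  double th[MAXN], w[MAXN];
  double O[MAXN][2], CG[MAXN][2], Vel[MAXN][2], gcg[MAXN][2];
  double J[MAXN][2][MAXN];
  double M[MAXN][MAXN], Q[MAXN];
  int last_rev[MAXN];
};

static void assemble(const Model& p, const double* q, const double* qd,
                     const double* base, WS& s) {
  const int n = p.n;
  const double th_off = base[0], w_b = base[1], al_b = base[2];

  double JO[2][MAXN];
  double O_prev[2] = {0.0, 0.0};
  double vO_prev[2] = {base[5], base[6]};
  double gO_prev[2] = {base[3], base[4]};
  double th_prev = p.th_base0 + th_off, w_prev = w_b;
  double crot = 0.0;
  int last_rev_prev = -1;

  for (int a = 0; a < n; ++a) { JO[0][a] = 0.0; JO[1][a] = 0.0; }
  for (int a = 0; a < n; ++a) {
    s.Q[a] = 0.0;
    for (int b = 0; b < n; ++b) s.M[a][b] = 0.0;
  }
  const double gvec_z = -p.g;

  for (int i = 0; i < n; ++i) {
    double vx = p.sx[i], vz = p.sz[i];
    double gOx = gO_prev[0], gOz = gO_prev[1];
    double vOx = vO_prev[0], vOz = vO_prev[1];
    double cp_ = std::cos(th_prev), sp_ = std::sin(th_prev);
    if (p.jtype[i] == 1) {
      vx += q[i] * p.ux; vz += q[i] * p.uz;
      double Rux = cp_ * p.ux + sp_ * p.uz;
      double Ruz = -sp_ * p.ux + cp_ * p.uz;
      double dRux = -sp_ * p.ux + cp_ * p.uz;
      double dRuz = -cp_ * p.ux - sp_ * p.uz;
      JO[0][i] += Rux; JO[1][i] += Ruz;
      vOx += qd[i] * Rux; vOz += qd[i] * Ruz;
      gOx += 2.0 * qd[i] * w_prev * dRux;
      gOz += 2.0 * qd[i] * w_prev * dRuz;
    }
    double Rvx = cp_ * vx + sp_ * vz, Rvz = -sp_ * vx + cp_ * vz;
    double dRvx = -sp_ * vx + cp_ * vz, dRvz = -cp_ * vx - sp_ * vz;
    if (last_rev_prev >= 0)
      for (int a = 0; a <= last_rev_prev; ++a)
        if (p.jtype[a] == 0) { JO[0][a] += dRvx; JO[1][a] += dRvz; }
    double Ox = O_prev[0] + Rvx, Oz = O_prev[1] + Rvz;
    vOx += w_prev * dRvx; vOz += w_prev * dRvz;
    gOx += al_b * dRvx - w_prev * w_prev * Rvx;
    gOz += al_b * dRvz - w_prev * w_prev * Rvz;

    int last_rev = last_rev_prev;
    if (p.jtype[i] == 0) { crot += q[i]; last_rev = i; }
    double th_i = p.theta0[i] + th_off + crot;
    double w_i = w_b;
    for (int a = 0; a <= last_rev; ++a) if (p.jtype[a] == 0) w_i += qd[a];

    double ci = std::cos(th_i), si = std::sin(th_i);
    double Rgx = ci * p.gx[i] + si * p.gz[i];
    double Rgz = -si * p.gx[i] + ci * p.gz[i];
    double dRgx = -si * p.gx[i] + ci * p.gz[i];
    double dRgz = -ci * p.gx[i] - si * p.gz[i];

    double (&Ji)[2][MAXN] = s.J[i];
    for (int a = 0; a < n; ++a) { Ji[0][a] = JO[0][a]; Ji[1][a] = JO[1][a]; }
    bool has_g = (p.gx[i] != 0.0 || p.gz[i] != 0.0);
    if (last_rev >= 0 && has_g)
      for (int a = 0; a <= last_rev; ++a)
        if (p.jtype[a] == 0) { Ji[0][a] += dRgx; Ji[1][a] += dRgz; }

    s.th[i] = th_i; s.w[i] = w_i; s.last_rev[i] = last_rev;
    s.O[i][0] = Ox; s.O[i][1] = Oz;
    s.CG[i][0] = Ox + Rgx; s.CG[i][1] = Oz + Rgz;
    s.Vel[i][0] = vOx + w_i * dRgx; s.Vel[i][1] = vOz + w_i * dRgz;
    s.gcg[i][0] = gOx + al_b * dRgx - w_i * w_i * Rgx;
    s.gcg[i][1] = gOz + al_b * dRgz - w_i * w_i * Rgz;

    if (p.mass[i] > 0.0) {
      double fx = p.mass[i] * (0.0 - s.gcg[i][0]);
      double fz = p.mass[i] * (gvec_z - s.gcg[i][1]);
      for (int a = 0; a <= i; ++a) {
        double jax = Ji[0][a], jaz = Ji[1][a];
        if (jax == 0.0 && jaz == 0.0) continue;
        s.Q[a] += jax * fx + jaz * fz;
        for (int b = 0; b <= i; ++b)
          s.M[a][b] += p.mass[i] * (jax * Ji[0][b] + jaz * Ji[1][b]);
      }
    }
    if (p.iyy[i] > 0.0 && last_rev >= 0) {
      for (int a = 0; a <= last_rev; ++a) {
        if (p.jtype[a] != 0) continue;
        for (int b = 0; b <= last_rev; ++b)
          if (p.jtype[b] == 0) s.M[a][b] += p.iyy[i];
        s.Q[a] -= p.iyy[i] * al_b;
      }
    }

    O_prev[0] = Ox; O_prev[1] = Oz;
    vO_prev[0] = vOx; vO_prev[1] = vOz;
    gO_prev[0] = gOx; gO_prev[1] = gOz;
    th_prev = th_i; w_prev = w_i; last_rev_prev = last_rev;
  }

  // joint internal forces (spring + damper + gravity preload)
  for (int i = 0; i < n; ++i) {
    if (p.jtype[i] == 0)
      s.Q[i] += p.preload[i] - spring_m(p, i, q[i]) - p.C[i] * qd[i];
    else
      s.Q[i] += p.preload[i] - p.kv * q[i] - p.cv * qd[i];
  }
}

static bool solve_qdd(const Model& p, const WS& s, double* qdd) {
  const int n = p.n;
  arma::mat M(n, n);
  arma::vec Q(n), x;
  for (int a = 0; a < n; ++a) {
    Q[a] = s.Q[a];
    for (int b = 0; b < n; ++b) M(a, b) = s.M[a][b];
  }
  if (!arma::solve(x, M, Q, arma::solve_opts::likely_sympd)) return false;
  for (int a = 0; a < n; ++a) qdd[a] = x[a];
  return true;
}

// damper dissipation rate and support (prescribed-motion) power
static void power_terms(const Model& p, const WS& s, const double* qd,
                        const double* qdd, const double* base,
                        double& Ddot, double& Wdot) {
  const int n = p.n;
  Ddot = 0.0;
  double Fx = 0.0, Fz = 0.0, Msup = 0.0;
  for (int i = 0; i < n; ++i) {
    Ddot += (p.jtype[i] == 0) ? p.C[i] * qd[i] * qd[i]
                              : p.cv * qd[i] * qd[i];
  }
  for (int i = 0; i < n; ++i) {
    if (p.mass[i] <= 0.0 && p.iyy[i] <= 0.0) continue;
    double ax = s.gcg[i][0], az = s.gcg[i][1];
    for (int a = 0; a <= i; ++a) {
      ax += s.J[i][0][a] * qdd[a];
      az += s.J[i][1][a] * qdd[a];
    }
    double aldd = base[2];
    for (int a = 0; a <= s.last_rev[i]; ++a)
      if (p.jtype[a] == 0) aldd += qdd[a];
    double fx = p.mass[i] * ax, fz = p.mass[i] * (az + p.g);
    Fx += fx; Fz += fz;
    Msup += p.iyy[i] * aldd + s.CG[i][1] * fx - s.CG[i][0] * fz;
  }
  Wdot = Fx * base[5] + Fz * base[6] + Msup * base[1];
}

// ---- persistent model for the deSolve compiled interface -------------------

static Model g_model;
static bool g_model_set = false;

// [[Rcpp::export(name = ".eom_set_model_cpp")]]
bool eom_set_model_cpp(List cp, Nullable<List> motion) {
  model_from_list(cp, g_model);
  if (motion.isNotNull()) {
    List mo(motion);
    g_model.has_motion = true;
    spline_from_list(mo["x"], g_model.spl_x);
    spline_from_list(mo["z"], g_model.spl_z);
    if (mo.containsElementNamed("rot") && !Rf_isNull(mo["rot"])) {
      g_model.has_rot = true;
      spline_from_list(mo["rot"], g_model.spl_r);
      g_model.rot0 = as<double>(mo["rot0"]);
    }
  }
  g_model_set = true;
  return true;
}

// deSolve-compatible right-hand side: y = (q, qd, D, W).
extern "C" void whipneck_rhs(int* neq, double* t, double* y, double* ydot,
                             double* yout, int* ip) {
  const Model& p = g_model;
  const int n = p.n;
  double base[7];
  eval_base(p, *t, base);
  WS s;
  assemble(p, y, y + n, base, s);
  double qdd[MAXN];
  if (!solve_qdd(p, s, qdd)) {
    for (int i = 0; i < *neq; ++i) ydot[i] = R_NaN;
    return;
  }
  double Ddot, Wdot;
  power_terms(p, s, y + n, qdd, base, Ddot, Wdot);
  for (int i = 0; i < n; ++i) { ydot[i] = y[n + i]; ydot[n + i] = qdd[i]; }
  ydot[2 * n] = Ddot;
  ydot[2 * n + 1] = Wdot;
}

// Register the plain-C right-hand side so deSolve can resolve it by name.
// [[Rcpp::init]]
void whipneck_register_rhs(DllInfo* dll) {
  static const R_CMethodDef cMethods[] = {
    {"whipneck_rhs", (DL_FUNC) &whipneck_rhs, 6},
    {NULL, NULL, 0}
  };
  R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
}

// ---- stateless single-evaluation entry points ------------------------------

// [[Rcpp::export(name = ".eom_qdd_cpp")]]
NumericVector eom_qdd_cpp(List cp, NumericVector q, NumericVector qd,
                          NumericVector base) {
  Model p; model_from_list(cp, p);
  WS s;
  std::vector<double> qq(q.begin(), q.end()), qdv(qd.begin(), qd.end()),
    bb(base.begin(), base.end());
  assemble(p, qq.data(), qdv.data(), bb.data(), s);
  double qdd[MAXN];
  if (!solve_qdd(p, s, qdd)) stop("singular generalized mass matrix");
  return NumericVector(qdd, qdd + p.n);
}

// [[Rcpp::export(name = ".eom_mq_cpp")]]
List eom_mq_cpp(List cp, NumericVector q, NumericVector qd,
                NumericVector base) {
  Model p; model_from_list(cp, p);
  WS s;
  std::vector<double> qq(q.begin(), q.end()), qdv(qd.begin(), qd.end()),
    bb(base.begin(), base.end());
  assemble(p, qq.data(), qdv.data(), bb.data(), s);
  NumericMatrix M(p.n, p.n);
  NumericVector Q(p.n);
  for (int a = 0; a < p.n; ++a) {
    Q[a] = s.Q[a];
    for (int b = 0; b < p.n; ++b) M(a, b) = s.M[a][b];
  }
  return List::create(_["M"] = M, _["Q"] = Q);
}

// Output channels over a trajectory.  Y rows are states (q, qd, D, W); base
// rows are (th_off, w, al, ax, az, vx, vz, px, pz) with (px, pz) the
// absolute base position.  Returns per row: qdd (n) | theta (n) | head CG
// x, z | head ax, az, |a| | OC x, z | OC Fx, Fz (head frame), My | T | V.
// [[Rcpp::export(name = ".eom_channels_cpp")]]
NumericMatrix eom_channels_cpp(List cp, NumericMatrix Y, NumericMatrix base_) {
  Model p; model_from_list(cp, p);
  const int n = p.n, nt = Y.nrow(), H = n - 1;
  NumericMatrix out(nt, 2 * n + 12);
  WS s;
  double q[MAXN], qd[MAXN], base[7], qdd[MAXN];

  for (int r = 0; r < nt; ++r) {
    for (int i = 0; i < n; ++i) { q[i] = Y(r, i); qd[i] = Y(r, n + i); }
    for (int i = 0; i < 7; ++i) base[i] = base_(r, i);
    const double px_abs = base_(r, 7), pz_abs = base_(r, 8);
    assemble(p, q, qd, base, s);
    if (!solve_qdd(p, s, qdd)) stop("singular generalized mass matrix");

    for (int i = 0; i < n; ++i) {
      out(r, i) = qdd[i];
      out(r, n + i) = s.th[i];
    }
    // head kinematics and occipital-condyle loads (Newton-Euler on the head)
    double ahx = s.gcg[H][0], ahz = s.gcg[H][1];
    for (int a = 0; a <= H; ++a) {
      ahx += s.J[H][0][a] * qdd[a];
      ahz += s.J[H][1][a] * qdd[a];
    }
    double aldd_h = base[2];
    for (int a = 0; a <= s.last_rev[H]; ++a)
      if (p.jtype[a] == 0) aldd_h += qdd[a];
    double Fgx = p.mass[H] * ahx, Fgz = p.mass[H] * (ahz + p.g);
    double c = std::cos(s.th[H]), sn = std::sin(s.th[H]);
    double Fx_loc = c * Fgx - sn * Fgz;
    double Fz_loc = sn * Fgx + c * Fgz;
    double prx = s.O[H][0] - s.CG[H][0], prz = s.O[H][1] - s.CG[H][1];
    double My = p.iyy[H] * aldd_h - (prz * Fgx - prx * Fgz);

    // energy ledger: kinetic, and potential (gravity + springs + preload)
    double T = 0.0, V = 0.0;
    for (int i = 0; i < n; ++i) {
      if (p.mass[i] > 0.0) {
        T += 0.5 * p.mass[i] * (s.Vel[i][0] * s.Vel[i][0] +
                                s.Vel[i][1] * s.Vel[i][1]);
        V += p.mass[i] * p.g * (s.CG[i][1] + pz_abs);
      }
      if (p.iyy[i] > 0.0) T += 0.5 * p.iyy[i] * s.w[i] * s.w[i];
      if (p.jtype[i] == 0) V += spring_u(p, i, q[i]);
      else V += 0.5 * p.kv * q[i] * q[i];
      V -= p.preload[i] * q[i];
    }

    int k = 2 * n;
    out(r, k + 0) = s.CG[H][0] + px_abs;
    out(r, k + 1) = s.CG[H][1] + pz_abs;
    out(r, k + 2) = ahx;
    out(r, k + 3) = ahz;
    out(r, k + 4) = std::sqrt(ahx * ahx + ahz * ahz);
    out(r, k + 5) = s.O[H][0] + px_abs;
    out(r, k + 6) = s.O[H][1] + pz_abs;
    out(r, k + 7) = Fx_loc;
    out(r, k + 8) = Fz_loc;
    out(r, k + 9) = My;
    out(r, k + 10) = T;
    out(r, k + 11) = V;
  }
  return out;
}
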