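// Core numerics: CV geometry for the parabolic-solid volume, Gaussian bias
// evaluation, the BAOAB Langevin loop with on-the-fly well-tempered hill
// deposition, and the grid sums of the Tiwary-Parrinello c(t) estimator.
//
// Units throughout: A, ps, amu, kcal/mol, K.  Velocities in A/ps.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

static const double KB_KCAL = 0.0019872041;  // kcal/mol/K
static const double AKMA    = 418.4;         // 1 kcal/mol = 418.4 amu A^2 ps^-2
static const double EXPCUT  = 34.0;          // drop Gaussian tails below e^-34
static const double EPS_A   = 1e-8;          // axial margin above the apex offset
static const double RP_REG  = 1e-2;          // transverse regularisation (A) for grad(theta)

// ---------------------------------------------------------------- helpers --
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double wrap_pi(double d) {
  return d - 2.0 * M_PI * std::floor((d + M_PI) / (2.0 * M_PI));
}

// ------------------------------------------------------ parabolic volume ---
struct VolFrame {
  double o[3], u[3], e1[3], e2[3];
  double k, a0, rho_max, tau_max, wall_k, a_min;
};

// Reference direction for theta: e1 is the unit projection of +y (or +z when
// the axis is nearly parallel to y) onto the plane perpendicular to the axis;
// e2 = axis x e1.  theta = atan2(p.e2, p.e1).
static VolFrame parse_vol(const List& v) {
  VolFrame V;
  NumericVector o = v["origin"], u = v["axis"];
  for (int i = 0; i < 3; ++i) { V.o[i] = o[i]; V.u[i] = u[i]; }
  double nu = std::sqrt(dot3(V.u, V.u));
  if (nu <= 0) stop("volume axis has zero length");
  for (int i = 0; i < 3; ++i) V.u[i] /= nu;
  double ref[3] = {0.0, 1.0, 0.0};
  if (std::fabs(V.u[1]) > 0.9) { ref[0] = 0.0; ref[1] = 0.0; ref[2] = 1.0; }
  double ru = dot3(ref, V.u);
  for (int i = 0; i < 3; ++i) V.e1[i] = ref[i] - ru * V.u[i];
  double n1 = std::sqrt(dot3(V.e1, V.e1));
  for (int i = 0; i < 3; ++i) V.e1[i] /= n1;
  cross3(V.u, V.e1, V.e2);
  V.k       = as<double>(v["k"]);
  V.a0      = as<double>(v["a0"]);
  V.rho_max = as<double>(v["rho_max"]);
  V.tau_max = as<double>(v["tau_max"]);
  V.wall_k  = as<double>(v["wall_k"]);
  V.a_min   = as<double>(v["a_min"]);
  return V;
}

// cv[0]=rho, cv[1]=tau, cv[2]=theta; returns false when a <= a0 + EPS_A
// (paraboloid parameterisation degenerate).
static bool cvs_of(const double* r, const double* h, const VolFrame& V,
                   double* cv, double* a_out = 0, double* rp_out = 0) {
  double d[3], q[3], p[3];
  for (int i = 0; i < 3; ++i) { d[i] = r[i] - h[i]; q[i] = r[i] - V.o[i]; }
  cv[0] = std::sqrt(dot3(d, d));
  double a = dot3(q, V.u);
  for (int i = 0; i < 3; ++i) p[i] = q[i] - a * V.u[i];
  double rp = std::sqrt(dot3(p, p));
  if (a_out) *a_out = a;
  if (rp_out) *rp_out = rp;
  if (a <= V.a0 + EPS_A) { cv[1] = R_PosInf; cv[2] = 0.0; return false; }
  cv[1] = rp / std::sqrt(V.k * (a - V.a0));
  cv[2] = (rp < 1e-12) ? 0.0 : std::atan2(dot3(p, V.e2), dot3(p, V.e1));
  return true;
}

// Rows of G: grad rho, grad tau, grad theta (each a 3-vector).
static bool cv_grads_of(const double* r, const double* h, const VolFrame& V,
                        double* cv, double G[3][3]) {
  double d[3], q[3], p[3];
  for (int i = 0; i < 3; ++i) { d[i] = r[i] - h[i]; q[i] = r[i] - V.o[i]; }
  double rho = std::sqrt(dot3(d, d));
  double a = dot3(q, V.u);
  for (int i = 0; i < 3; ++i) p[i] = q[i] - a * V.u[i];
  double rp = std::sqrt(dot3(p, p));
  if (a <= V.a0 + EPS_A) return false;
  double s = std::sqrt(V.k * (a - V.a0));
  double tau = rp / s;
  cv[0] = rho; cv[1] = tau;
  cv[2] = (rp < 1e-12) ? 0.0 : std::atan2(dot3(p, V.e2), dot3(p, V.e1));
  double rr = (rho > 1e-12) ? rho : 1e-12;
  for (int i = 0; i < 3; ++i) G[0][i] = d[i] / rr;
  // on-axis tie-break: transverse direction taken along e1
  double ph[3];
  if (rp > 1e-12) for (int i = 0; i < 3; ++i) ph[i] = p[i] / rp;
  else            for (int i = 0; i < 3; ++i) ph[i] = V.e1[i];
  double ax = tau / (2.0 * (a - V.a0));
  for (int i = 0; i < 3; ++i) G[1][i] = ph[i] / s - ax * V.u[i];
  // grad theta = (x' e2 - y' e1) / r_perp^2, regularised near the axis so the
  // magnitude is capped at 1/RP_REG
  if (rp < 1e-12) {
    for (int i = 0; i < 3; ++i) G[2][i] = 0.0;
  } else {
    double xp = dot3(p, V.e1), yp = dot3(p, V.e2);
    double rp2 = std::max(rp, RP_REG); rp2 *= rp2;
    for (int i = 0; i < 3; ++i) G[2][i] = (xp * V.e2[i] - yp * V.e1[i]) / rp2;
  }
  return true;
}

// Half-harmonic walls on rho > rho_max, tau > tau_max and a < a_min.
static double restraint_of(const double* r, const double* h, const VolFrame& V,
                           double* frc /* may be null: -dE/dr added in */) {
  double cv[3], a, rp;
  bool ok = cvs_of(r, h, V, cv, &a, &rp);
  double E = 0.0;
  if (cv[0] > V.rho_max) {
    double x = cv[0] - V.rho_max;
    E += V.wall_k * x * x;
    if (frc) {
      double d[3]; for (int i = 0; i < 3; ++i) d[i] = r[i] - h[i];
      double rr = std::max(cv[0], 1e-12);
      for (int i = 0; i < 3; ++i) frc[i] -= 2.0 * V.wall_k * x * d[i] / rr;
    }
  }
  if (a < V.a_min) {
    double x = V.a_min - a;
    E += V.wall_k * x * x;
    if (frc) for (int i = 0; i < 3; ++i) frc[i] += 2.0 * V.wall_k * x * V.u[i];
  }
  if (ok && cv[1] > V.tau_max) {
    double x = cv[1] - V.tau_max;
    E += V.wall_k * x * x;
    if (frc) {
      double cvv[3], G[3][3];
      if (cv_grads_of(r, h, V, cvv, G))
        for (int i = 0; i < 3; ++i) frc[i] -= 2.0 * V.wall_k * x * G[1][i];
    }
  }
  return E;
}

// -------------------------------------------------------- toy potentials ---
// tag: 0 double well (1D), 1 host-guest (3D), 2 harmonic, 3 flat
struct Pot {
  int tag, dim;
  double B, sep, A;              // double well
  double kspr; double x0h[3];    // harmonic
  std::vector<double> sx, sy, sz, sd, sw;  // host-guest sites
};

static Pot parse_pot(const List& p) {
  Pot P; std::memset(&P, 0, sizeof(double) * 0);
  std::string tag = as<std::string>(p["tag"]);
  P.dim = as<int>(p["dim"]);
  P.B = P.sep = P.A = P.kspr = 0.0;
  P.x0h[0] = P.x0h[1] = P.x0h[2] = 0.0;
  if (tag == "double_well") {
    P.tag = 0;
    P.B = as<double>(p["barrier"]); P.sep = as<double>(p["separation"]);
    P.A = as<double>(p["asymmetry"]);
  } else if (tag == "host_guest") {
    P.tag = 1;
    NumericMatrix S = p["sites"];   // columns x y z depth range
    for (int i = 0; i < S.nrow(); ++i) {
      P.sx.push_back(S(i, 0)); P.sy.push_back(S(i, 1)); P.sz.push_back(S(i, 2));
      P.sd.push_back(S(i, 3)); P.sw.push_back(S(i, 4));
    }
  } else if (tag == "harmonic") {
    P.tag = 2;
    P.kspr = as<double>(p["k_spring"]);
    NumericVector x0 = p["x0"];
    for (int i = 0; i < P.dim; ++i) P.x0h[i] = x0[i];
  } else if (tag == "flat") {
    P.tag = 3;
  } else stop("unknown potential tag '%s'", tag.c_str());
  return P;
}

static double pot_energy(const Pot& P, const double* x) {
  switch (P.tag) {
  case 0: {
    double z = 2.0 * x[0] / P.sep, w = z * z - 1.0;
    return P.B * w * w + 0.5 * P.A * (z + 1.0);
  }
  case 1: {
    double U = 0.0;
    for (size_t i = 0; i < P.sx.size(); ++i) {
      double dx = x[0] - P.sx[i], dy = x[1] - P.sy[i], dz = x[2] - P.sz[i];
      double r2 = dx * dx + dy * dy + dz * dz, w2 = P.sw[i] * P.sw[i];
      double e = 0.5 * r2 / w2;
      if (e < EXPCUT) U -= P.sd[i] * std::exp(-e);
    }
    return U;
  }
  case 2: {
    double U = 0.0;
    for (int i = 0; i < P.dim; ++i) {
      double d = x[i] - P.x0h[i]; U += 0.5 * P.kspr * d * d;
    }
    return U;
  }
  default: return 0.0;
  }
}

static void pot_grad(const Pot& P, const double* x, double* g) {
  for (int i = 0; i < P.dim; ++i) g[i] = 0.0;
  switch (P.tag) {
  case 0: {
    double z = 2.0 * x[0] / P.sep;
    g[0] = (4.0 * P.B * z * (z * z - 1.0) + 0.5 * P.A) * (2.0 / P.sep);
    break;
  }
  case 1: {
    for (size_t i = 0; i < P.sx.size(); ++i) {
      double d[3] = {x[0] - P.sx[i], x[1] - P.sy[i], x[2] - P.sz[i]};
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      double w2 = P.sw[i] * P.sw[i], e = 0.5 * r2 / w2;
      if (e < EXPCUT) {
        double f = P.sd[i] * std::exp(-e) / w2;
        for (int j = 0; j < 3; ++j) g[j] += f * d[j];
      }
    }
    break;
  }
  case 2:
    for (int i = 0; i < P.dim; ++i) g[i] = P.kspr * (x[i] - P.x0h[i]);
    break;
  default: break;
  }
}

// ------------------------------------------------------------- bias sums ---
// Hills stored row-wise in flat vectors (ncv values per hill).
static double bias_at(int nh, int ncv, const double* C, const double* S,
                      const double* H, const int* per, const double* s,
                      double* grad /* ncv, may be null */) {
  double V = 0.0;
  if (grad) for (int j = 0; j < ncv; ++j) grad[j] = 0.0;
  std::vector<double> dsig(ncv);
  for (int i = 0; i < nh; ++i) {
    const double* ci = C + (size_t)i * ncv;
    const double* si = S + (size_t)i * ncv;
    double e = 0.0; bool skip = false;
    for (int j = 0; j < ncv; ++j) {
      double d = s[j] - ci[j];
      if (per[j]) d = wrap_pi(d);
      d /= si[j];
      dsig[j] = d;
      e += 0.5 * d * d;
      if (e > EXPCUT) { skip = true; break; }
    }
    if (skip) continue;
    double g = H[i] * std::exp(-e);
    V += g;
    if (grad) for (int j = 0; j < ncv; ++j) grad[j] -= g * dsig[j] / si[j];
  }
  return V;
}

// ------------------------------------------------------------- exports -----

// [[Rcpp::export]]
NumericVector cpp_potential_energy(List pot, NumericMatrix X) {
  Pot P = parse_pot(pot);
  int n = X.nrow();
  if (X.ncol() != P.dim) stop("position matrix has %d columns, potential dim is %d",
                              X.ncol(), P.dim);
  NumericVector out(n);
  double x[3] = {0, 0, 0};
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < P.dim; ++j) x[j] = X(i, j);
    out[i] = pot_energy(P, x);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_potential_gradient(List pot, NumericVector xr) {
  Pot P = parse_pot(pot);
  if (xr.size() != P.dim) stop("position has length %d, potential dim is %d",
                               (int)xr.size(), P.dim);
  double x[3] = {0, 0, 0}, g[3] = {0, 0, 0};
  for (int j = 0; j < P.dim; ++j) x[j] = xr[j];
  pot_grad(P, x, g);
  NumericVector out(P.dim);
  for (int j = 0; j < P.dim; ++j) out[j] = g[j];
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_cvs_matrix(NumericMatrix X, NumericVector host, List vol) {
  VolFrame V = parse_vol(vol);
  double h[3] = {host[0], host[1], host[2]};
  int n = X.nrow();
  NumericMatrix out(n, 3);
  double r[3], cv[3];
  for (int i = 0; i < n; ++i) {
    r[0] = X(i, 0); r[1] = X(i, 1); r[2] = X(i, 2);
    cvs_of(r, h, V, cv);   // degenerate rows get tau = Inf
    out(i, 0) = cv[0]; out(i, 1) = cv[1]; out(i, 2) = cv[2];
  }
  colnames(out) = CharacterVector::create("rho", "tau", "theta");
  return out;
}

// [[Rcpp::export]]
List cpp_cv_gradients(NumericVector r, NumericVector host, List vol) {
  VolFrame V = parse_vol(vol);
  double rr[3] = {r[0], r[1], r[2]}, h[3] = {host[0], host[1], host[2]};
  double cv[3], G[3][3];
  if (!cv_grads_of(rr, h, V, cv, G))
    stop("degenerate geometry: axial coordinate not above the paraboloid apex offset");
  NumericMatrix g(3, 3);
  for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j) g(i, j) = G[i][j];
  rownames(g) = CharacterVector::create("rho", "tau", "theta");
  return List::create(_["cvs"] = NumericVector::create(cv[0], cv[1], cv[2]),
                      _["gradients"] = g);
}

// [[Rcpp::export]]
NumericVector cpp_restraint_energy(NumericMatrix X, NumericVector host, List vol) {
  VolFrame V = parse_vol(vol);
  double h[3] = {host[0], host[1], host[2]};
  int n = X.nrow();
  NumericVector out(n);
  double r[3];
  for (int i = 0; i < n; ++i) {
    r[0] = X(i, 0); r[1] = X(i, 1); r[2] = X(i, 2);
    out[i] = restraint_of(r, h, V, 0);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_restraint_force(NumericVector r, NumericVector host, List vol) {
  VolFrame V = parse_vol(vol);
  double rr[3] = {r[0], r[1], r[2]}, h[3] = {host[0], host[1], host[2]};
  double f[3] = {0, 0, 0};
  restraint_of(rr, h, V, f);
  return NumericVector::create(f[0], f[1], f[2]);
}

// [[Rcpp::export]]
NumericVector cpp_bias_energy(NumericMatrix centers, NumericMatrix sigmas,
                              NumericVector heights, NumericMatrix S,
                              LogicalVector periodic) {
  int nh = centers.nrow(), ncv = centers.ncol(), n = S.nrow();
  if (S.ncol() != ncv) stop("evaluation points have %d columns, hills have %d CVs",
                            S.ncol(), ncv);
  std::vector<double> C(nh * ncv), SG(nh * ncv), H(nh);
  std::vector<int> per(ncv);
  for (int i = 0; i < nh; ++i) {
    H[i] = heights[i];
    for (int j = 0; j < ncv; ++j) {
      C[(size_t)i * ncv + j] = centers(i, j);
      SG[(size_t)i * ncv + j] = sigmas(i, j);
    }
  }
  for (int j = 0; j < ncv; ++j) per[j] = periodic[j] ? 1 : 0;
  NumericVector out(n);
  std::vector<double> s(ncv);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < ncv; ++j) s[j] = S(i, j);
    out[i] = bias_at(nh, ncv, C.data(), SG.data(), H.data(), per.data(), s.data(), 0);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_bias_gradient(NumericMatrix centers, NumericMatrix sigmas,
                                NumericVector heights, NumericVector s,
                                LogicalVector periodic) {
  int nh = centers.nrow(), ncv = centers.ncol();
  std::vector<double> C(nh * ncv), SG(nh * ncv), H(nh), sv(ncv), g(ncv);
  std::vector<int> per(ncv);
  for (int i = 0; i < nh; ++i) {
    H[i] = heights[i];
    for (int j = 0; j < ncv; ++j) {
      C[(size_t)i * ncv + j] = centers(i, j);
      SG[(size_t)i * ncv + j] = sigmas(i, j);
    }
  }
  for (int j = 0; j < ncv; ++j) { per[j] = periodic[j] ? 1 : 0; sv[j] = s[j]; }
  bias_at(nh, ncv, C.data(), SG.data(), H.data(), per.data(), sv.data(), g.data());
  NumericVector out(ncv);
  for (int j = 0; j < ncv; ++j) out[j] = g[j];
  return out;
}

// Tiwary-Parrinello c(t): at each eval time, V(s,t) is the bias from hills with
// deposition time <= t (matching the convention that a COLVAR frame written at
// a hill time already contains that hill).  Uniform grid assumed: cell volumes
// cancel in the ratio.
// [[Rcpp::export]]
NumericVector cpp_compute_ct(NumericMatrix centers, NumericMatrix sigmas,
                             NumericVector heights, NumericVector hill_times,
                             NumericMatrix grid, LogicalVector periodic,
                             double gamma, double beta, NumericVector eval_times) {
  int nh = centers.nrow(), ncv = (nh > 0) ? centers.ncol() : grid.ncol();
  int G = grid.nrow(), nt = eval_times.size();
  if (grid.ncol() != ncv) stop("grid has %d columns, hills have %d CVs",
                               grid.ncol(), ncv);
  for (int i = 1; i < nt; ++i)
    if (eval_times[i] < eval_times[i - 1]) stop("eval_times must be non-decreasing");
  std::vector<int> per(ncv);
  for (int j = 0; j < ncv; ++j) per[j] = periodic[j] ? 1 : 0;
  std::vector<double> V(G, 0.0);
  NumericVector ct(nt);
  double bg = beta * gamma / (gamma - 1.0);   // exponent of the numerator
  double bd = beta / (gamma - 1.0);           // exponent of the denominator
  int ih = 0;
  for (int it = 0; it < nt; ++it) {
    double t = eval_times[it];
    while (ih < nh && hill_times[ih] <= t) {
      double h = heights[ih];
      std::vector<double> c(ncv), sg(ncv);
      for (int j = 0; j < ncv; ++j) { c[j] = centers(ih, j); sg[j] = sigmas(ih, j); }
      for (int g = 0; g < G; ++g) {
        double e = 0.0; bool skip = false;
        for (int j = 0; j < ncv; ++j) {
          double d = grid(g, j) - c[j];
          if (per[j]) d = wrap_pi(d);
          d /= sg[j];
          e += 0.5 * d * d;
          if (e > EXPCUT) { skip = true; break; }
        }
        if (!skip) V[g] += h * std::exp(-e);
      }
      ++ih;
    }
    double m = V[0];
    for (int g = 1; g < G; ++g) if (V[g] > m) m = V[g];
    double sn = 0.0, sd = 0.0;
    for (int g = 0; g < G; ++g) {
      sn += std::exp(bg * (V[g] - m));
      sd += std::exp(bd * (V[g] - m));
    }
    ct[it] = ((bg * m + std::log(sn)) - (bd * m + std::log(sd))) / beta;
  }
  return ct;
}

// ------------------------------------------------- the LV-MetaD run loop ---
// BAOAB splitting with exact Ornstein-Uhlenbeck friction.  One force
// evaluation per step; R's RNG supplies the O-step Gaussians (dim draws per
// step), so set.seed() on the R side makes runs bit-reproducible.
// [[Rcpp::export]]
List cpp_run_lv_metad(List potL, Nullable<List> volL, NumericVector host,
                      List lang, List metad, List obs) {
  Pot P = parse_pot(potL);
  int dim = P.dim;
  bool has_vol = volL.isNotNull();
  VolFrame V;
  if (dim == 3 && !has_vol) stop("3D runs require a volume spec");
  if (has_vol) V = parse_vol(volL.get());
  double h3[3] = {0, 0, 0};
  if (host.size() == 3) { h3[0] = host[0]; h3[1] = host[1]; h3[2] = host[2]; }

  double dt   = as<double>(lang["timestep"]);
  double fric = as<double>(lang["friction"]);
  double T    = as<double>(lang["temperature"]);
  double mass = as<double>(lang["mass"]);
  long nsteps = (long)as<double>(lang["n_steps"]);
  int out_stride = as<int>(lang["out_stride"]);
  NumericVector x0 = lang["x0"], v0 = lang["v0"];

  double h0 = as<double>(metad["h0"]);
  int dep_stride = as<int>(metad["stride_steps"]);
  bool confine = as<bool>(metad["confine"]);
  double gamma = as<double>(metad["gamma"]);
  NumericVector widths = metad["widths"];
  LogicalVector periodicR = metad["periodic"];
  int ncv = (dim == 1) ? 1 : 3;
  std::vector<int> per(ncv);
  for (int j = 0; j < ncv; ++j) per[j] = periodicR[j] ? 1 : 0;
  double kbdT = KB_KCAL * T * (gamma - 1.0);
  bool do_metad = (h0 > 0.0 && dep_stride > 0);

  // observables: d = |x - d_ref| * d_scale (1D: |x| * d_scale); N = sum of
  // rational switches over guest-site / polar-site distances
  double dref[3] = {0, 0, 0};
  double dscale = 0.1;
  bool has_dref = false;
  NumericMatrix csites;
  int nsite = 0;
  double sw_n = 8, sw_m = 12, sw_d0 = 0.0, sw_r0 = 2.5;
  if (obs.containsElementNamed("d_ref")) {
    NumericVector dr = obs["d_ref"];
    if (dr.size() == 3) { dref[0] = dr[0]; dref[1] = dr[1]; dref[2] = dr[2]; has_dref = true; }
  }
  if (obs.containsElementNamed("d_scale")) dscale = as<double>(obs["d_scale"]);
  if (obs.containsElementNamed("contact_sites")) {
    csites = as<NumericMatrix>(obs["contact_sites"]);
    nsite = csites.nrow();
    List sw = obs["switching"];
    sw_n = as<double>(sw["n"]); sw_m = as<double>(sw["m"]);
    sw_d0 = as<double>(sw["d0"]); sw_r0 = as<double>(sw["r0"]);
  }

  std::vector<double> hT, hC, hS, hH;
  double x[3] = {0, 0, 0}, v[3] = {0, 0, 0}, f[3] = {0, 0, 0};
  for (int j = 0; j < dim; ++j) { x[j] = x0[j]; v[j] = v0[j]; }

  double c1 = std::exp(-fric * dt);
  double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  double sigv = std::sqrt(AKMA * KB_KCAL * T / mass);
  double facc = AKMA / mass;   // force (kcal/mol/A) -> acceleration (A/ps^2)

  long nrec = nsteps / out_stride + 1;
  NumericMatrix colvar(nrec, 7), traj(nrec, 2 + 2 * dim);
  long irec = 0;

  double scv[3] = {0, 0, 0}, Vb = 0.0, Upot = 0.0;

  // Computes total force at x; fills scv (CVs), Vb (bias), Upot.
  auto force_eval = [&](long step) {
    double g[3] = {0, 0, 0};
    pot_grad(P, x, g);
    Upot = pot_energy(P, x);
    for (int j = 0; j < dim; ++j) f[j] = -g[j];
    double bgrad[3] = {0, 0, 0};
    if (dim == 1) {
      scv[0] = x[0];
      Vb = bias_at((int)hH.size(), 1, hC.data(), hS.data(), hH.data(),
                   per.data(), scv, do_metad ? bgrad : 0);
      if (do_metad) f[0] -= bgrad[0];
    } else {
      double G[3][3];
      if (!cv_grads_of(x, h3, V, scv, G))
        stop("degenerate geometry at step %ld: axial coordinate fell below the apex offset (wall misconfigured)", step);
      Vb = bias_at((int)hH.size(), 3, hC.data(), hS.data(), hH.data(),
                   per.data(), scv, do_metad ? bgrad : 0);
      if (do_metad)
        for (int l = 0; l < 3; ++l)
          f[l] -= bgrad[0] * G[0][l] + bgrad[1] * G[1][l] + bgrad[2] * G[2][l];
      restraint_of(x, h3, V, f);
    }
    for (int j = 0; j < dim; ++j)
      if (!std::isfinite(f[j]))
        stop("non-finite force at step %ld (last recorded frame: t = %.6f ps)",
             step, (irec > 0) ? colvar(irec - 1, 0) : 0.0);
  };

  auto record = [&](double t) {
    colvar(irec, 0) = t;
    colvar(irec, 1) = scv[0];
    colvar(irec, 2) = (dim == 1) ? 0.0 : scv[1];
    colvar(irec, 3) = (dim == 1) ? 0.0 : scv[2];
    colvar(irec, 4) = Vb;
    double dval;
    if (dim == 1) dval = std::fabs(x[0] - (has_dref ? dref[0] : 0.0)) * dscale;
    else {
      double dd[3] = {x[0] - dref[0], x[1] - dref[1], x[2] - dref[2]};
      dval = std::sqrt(dot3(dd, dd)) * dscale;
    }
    colvar(irec, 5) = dval;
    double N = 0.0;
    if (dim == 3 && nsite > 0) {
      for (int i = 0; i < nsite; ++i) {
        double dd[3] = {x[0] - csites(i, 0), x[1] - csites(i, 1), x[2] - csites(i, 2)};
        double r = std::sqrt(dot3(dd, dd));
        double xx = (r - sw_d0) / sw_r0;
        if (xx < 0) xx = 0;
        double xn = std::pow(xx, sw_n), xm = std::pow(xx, sw_m);
        N += (std::fabs(1.0 - xm) < 1e-12) ? sw_n / sw_m : (1.0 - xn) / (1.0 - xm);
      }
    }
    colvar(irec, 6) = N;
    traj(irec, 0) = t;
    for (int j = 0; j < dim; ++j) { traj(irec, 1 + j) = x[j]; traj(irec, 1 + dim + j) = v[j]; }
    traj(irec, 1 + 2 * dim) = Upot;
    ++irec;
  };

  force_eval(0);
  record(0.0);

  for (long n = 1; n <= nsteps; ++n) {
    for (int j = 0; j < dim; ++j) v[j] += 0.5 * dt * f[j] * facc;   // B
    for (int j = 0; j < dim; ++j) x[j] += 0.5 * dt * v[j];          // A
    for (int j = 0; j < dim; ++j) v[j] = c1 * v[j] + c2 * sigv * norm_rand();  // O
    for (int j = 0; j < dim; ++j) x[j] += 0.5 * dt * v[j];          // A
    for (int j = 0; j < dim; ++j)
      if (!std::isfinite(x[j]))
        stop("non-finite position at step %ld (last recorded frame: t = %.6f ps)",
             n, (irec > 0) ? colvar(irec - 1, 0) : 0.0);
    force_eval(n);
    for (int j = 0; j < dim; ++j) v[j] += 0.5 * dt * f[j] * facc;   // B
    double t = n * dt;
    if (do_metad && n % dep_stride == 0) {
      // bias stays confined to the localized volume: no deposition while the
      // walker is out beyond a restraining wall
      bool inside = true;
      if (confine && dim == 3 && has_vol)
        inside = (scv[0] <= V.rho_max && scv[1] <= V.tau_max);
      if (inside) {
        double h = h0 * std::exp(-Vb / kbdT);
        hT.push_back(t);
        for (int j = 0; j < ncv; ++j) { hC.push_back(scv[j]); hS.push_back(widths[j]); }
        hH.push_back(h);
        Vb += h;   // frames written at hill times include the fresh hill
      }
    }
    if (n % out_stride == 0) record(t);
  }

  int nh = (int)hH.size();
  NumericMatrix hills(nh, 2 + 2 * ncv);
  for (int i = 0; i < nh; ++i) {
    hills(i, 0) = hT[i];
    for (int j = 0; j < ncv; ++j) {
      hills(i, 1 + j) = hC[(size_t)i * ncv + j];
      hills(i, 1 + ncv + j) = hS[(size_t)i * ncv + j];
    }
    hills(i, 1 + 2 * ncv) = hH[i];
  }
  colnames(colvar) = CharacterVector::create("time", "rho", "tau", "theta",
                                             "bias", "d", "nhb");
  return List::create(_["colvar"] = colvar, _["hills"] = hills,
                      _["trajectory"] = traj, _["ncv"] = ncv);
}
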