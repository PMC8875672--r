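// Compiled core: closed-form PK kernels, Michaelis-Menten ODE kernel,
// individual log-posterior with complex-step gradients, MAP objective,
// and a dynamic (No-U-Turn) Hamiltonian Monte Carlo sampler.
//
// All kernels are templated on the scalar type so that gradients of the
// log-posterior can be taken by complex-step differentiation (exact to
// machine precision, no subtractive cancellation). Branch conditions and
// event times are always real.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <random>

using namespace Rcpp;

typedef std::complex<double> cplx;

inline double re(double x) { return x; }
inline double re(const cplx &x) { return x.real(); }

// ---------------------------------------------------------------------------
// Linear disposition: concentration as a sum of exponentials.
//
// Models: 1 = one-compartment IV (pars CL, V)
//         2 = two-compartment IV (pars CL, V, k12, k21)
//         3 = one-compartment first-order absorption (pars CL, V, ka, F)
// Doses: rows (time, amt, rate); rate > 0 means constant-rate infusion of
// duration amt/rate into the central compartment, rate == 0 means an
// instantaneous dose (IV bolus for models 1-2, depot dose for model 3).
// ---------------------------------------------------------------------------

template <typename T>
struct Disp {
  int n;            // exponential terms
  T lam[2];         // rate constants
  T B[2];           // unit-dose bolus coefficients (already / V)
  bool degenerate;  // oral ka == ke limiting form
  T ka_deg, cdeg;   // for the degenerate form C = cdeg * D * t * exp(-ka t)
};

template <typename T>
Disp<T> make_disp(int model, const T *p) {
  Disp<T> d;
  d.degenerate = false;
  if (model == 1) {
    T cl = p[0], v = p[1];
    d.n = 1;
    d.lam[0] = cl / v;
    d.B[0] = T(1.0) / v;
  } else if (model == 2) {
    T cl = p[0], v = p[1], k12 = p[2], k21 = p[3];
    T k10 = cl / v;
    T s = k10 + k12 + k21;
    T disc = sqrt(s * s - T(4.0) * k10 * k21);
    T l1 = (s + disc) / T(2.0);
    T l2 = (s - disc) / T(2.0);
    d.n = 2;
    d.lam[0] = l1;
    d.lam[1] = l2;
    d.B[0] = (l1 - k21) / ((l1 - l2) * v);
    d.B[1] = (k21 - l2) / ((l1 - l2) * v);
  } else { // model 3
    T cl = p[0], v = p[1], ka = p[2], f = p[3];
    T ke = cl / v;
    if (std::abs(re(ka) - re(ke)) < 1e-8 * std::abs(re(ke))) {
      d.n = 0;
      d.degenerate = true;
      d.ka_deg = ka;
      d.cdeg = f * ka / v;
    } else {
      d.n = 2;
      d.lam[0] = ke;
      d.lam[1] = ka;
      T c = f * ka / (v * (ka - ke));
      d.B[0] = c;
      d.B[1] = -c;
    }
  }
  return d;
}

// Single-dose response at time t (>= 0) after the dose.
template <typename T>
T disp_single(const Disp<T> &d, double amt, double rate, double t) {
  if (t <= 0.0) return T(0.0);
  T c(0.0);
  if (d.degenerate) {
    // F * D * ka * t * exp(-ka t) / V ; infusions not supported here
    return d.cdeg * T(amt) * T(t) * exp(-d.ka_deg * T(t));
  }
  if (rate > 0.0) {
    double te = amt / rate;
    for (int j = 0; j < d.n; ++j) {
      T rb = T(rate) * d.B[j] / d.lam[j];
      if (t < te) {
        c += rb * (T(1.0) - exp(-d.lam[j] * T(t)));
      } else {
        c += rb * (T(1.0) - exp(-d.lam[j] * T(te))) * exp(-d.lam[j] * T(t - te));
      }
    }
  } else {
    for (int j = 0; j < d.n; ++j)
      c += T(amt) * d.B[j] * exp(-d.lam[j] * T(t));
  }
  return c;
}

// Steady state under a tau-periodic regimen of one (amt, rate) dose per
// interval: first-interval response plus the geometric tail of all earlier
// doses, valid once the infusion (if any) has ended by tau.
template <typename T>
T disp_ss(const Disp<T> &d, double amt, double rate, double t, double tau) {
  double tt = t - std::floor(t / tau) * tau;
  if (tt < 0) tt += tau;
  T c = disp_single(d, amt, rate, tt);
  if (d.degenerate) {
    // sum_{n>=1} (t + n tau) exp(-ka (t + n tau))
    T r = exp(-d.ka_deg * T(tau));
    T e0 = exp(-d.ka_deg * T(tt));
    c += d.cdeg * T(amt) * e0 * (T(tt) * r / (T(1.0) - r) +
                                 T(tau) * r / ((T(1.0) - r) * (T(1.0) - r)));
    return c;
  }
  for (int j = 0; j < d.n; ++j) {
    T Dj;
    if (rate > 0.0) {
      double te = amt / rate;
      Dj = T(rate) * d.B[j] / d.lam[j] *
           (T(1.0) - exp(-d.lam[j] * T(te))) * exp(d.lam[j] * T(te));
    } else {
      Dj = T(amt) * d.B[j];
    }
    T etau = exp(-d.lam[j] * T(tau));
    c += Dj * exp(-d.lam[j] * T(tt)) * etau / (T(1.0) - etau);
  }
  return c;
}

template <typename T>
void conc_linear_T(int model, const T *pars, const NumericMatrix &doses,
                   const NumericVector &times, bool ss, double tau, T *out) {
  Disp<T> d = make_disp(model, pars);
  int nt = times.size(), nd = doses.nrow();
  for (int i = 0; i < nt; ++i) {
    double t = times[i];
    T c(0.0);
    if (ss) {
      // representative dose row defines the repeating regimen
      c = disp_ss(d, doses(0, 1), doses(0, 2), t, tau);
    } else {
      for (int k = 0; k < nd; ++k) {
        double dt = t - doses(k, 0);
        if (dt > 0.0) c += disp_single(d, doses(k, 1), doses(k, 2), dt);
      }
    }
    out[i] = c;
  }
}

// ---------------------------------------------------------------------------
// Michaelis-Menten elimination with zero-order input (phenytoin).
// dA/dt = rin(t) - Vmax*C/(km + C) - cl_lin*C,  C = A/V, rin = F * rate
// during each dose's delivery window. Fixed-step classical RK4 marched
// exactly through every input breakpoint and output time.
// pars: vmax (mg/h), km (mg/L), V (L), cl_lin (L/h), F
// ---------------------------------------------------------------------------

template <typename T>
inline T mm_rhs(T A, double rin, T vmax, T km, T V, T cl_lin) {
  T C = A / V;
  return T(rin) - vmax * C / (km + C) - cl_lin * C;
}

template <typename T>
void conc_mm_T(const T *pars, const NumericMatrix &doses,
               const NumericVector &times, double step, T *out) {
  T vmax = pars[0], km = pars[1], V = pars[2], cl_lin = pars[3];
  double F = re(pars[4]);
  int nd = doses.nrow(), nt = times.size();

  // breakpoints: dose starts/ends and output times
  std::vector<double> nodes;
  nodes.push_back(0.0);
  for (int k = 0; k < nd; ++k) {
    double t0 = doses(k, 0);
    double rate = doses(k, 2);
    double te = (rate > 0.0) ? t0 + doses(k, 1) / rate : t0;
    nodes.push_back(t0);
    nodes.push_back(te);
  }
  for (int i = 0; i < nt; ++i) nodes.push_back(times[i]);
  std::sort(nodes.begin(), nodes.end());
  nodes.erase(std::unique(nodes.begin(), nodes.end(),
                          [](double a, double b) { return std::fabs(a - b) < 1e-12; }),
              nodes.end());

  std::vector<int> bolus_done(nd, 0);
  T A(0.0);
  double tcur = nodes.front();
  if (tcur > 0.0) { nodes.insert(nodes.begin(), 0.0); tcur = 0.0; }

  // map output times to nodes
  auto record = [&](double t) {
    for (int i = 0; i < nt; ++i)
      if (std::fabs(times[i] - t) < 1e-12) out[i] = A / V;
  };
  record(tcur);

  for (size_t s = 1; s < nodes.size(); ++s) {
    double tnext = nodes[s];
    if (tnext < 0.0) continue;
    // instantaneous doses exactly at tcur (rate == 0 treated as bolus input)
    for (int k = 0; k < nd; ++k) {
      if (!bolus_done[k] && doses(k, 2) <= 0.0 &&
          std::fabs(doses(k, 0) - tcur) < 1e-12) {
        A += T(F * doses(k, 1));
        bolus_done[k] = 1;
      }
    }
    // constant input rate over (tcur, tnext)
    double rin = 0.0;
    double tmid = 0.5 * (tcur + tnext);
    for (int k = 0; k < nd; ++k) {
      double t0 = doses(k, 0), rate = doses(k, 2);
      if (rate > 0.0 && tmid > t0 && tmid < t0 + doses(k, 1) / rate)
        rin += F * rate;
    }
    double span = tnext - tcur;
    int nstep = std::max(1, (int)std::ceil(span / step));
    double h = span / nstep;
    for (int m = 0; m < nstep; ++m) {
      T k1 = mm_rhs(A, rin, vmax, km, V, cl_lin);
      T k2 = mm_rhs(A + T(0.5 * h) * k1, rin, vmax, km, V, cl_lin);
      T k3 = mm_rhs(A + T(0.5 * h) * k2, rin, vmax, km, V, cl_lin);
      T k4 = mm_rhs(A + T(h) * k3, rin, vmax, km, V, cl_lin);
      A += T(h / 6.0) * (k1 + T(2.0) * k2 + T(2.0) * k3 + k4);
    }
    if (re(A) < 0.0) A = T(0.0);
    tcur = tnext;
    record(tcur);
  }
}

// [[Rcpp::export]]
NumericVector cpp_conc_linear(int model, NumericVector pars,
                              NumericMatrix doses, NumericVector times,
                              bool ss, double tau) {
  std::vector<double> p(pars.begin(), pars.end());
  NumericVector out(times.size());
  conc_linear_T(model, p.data(), doses, times, ss, tau, REAL(out));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conc_mm(NumericVector pars, NumericMatrix doses,
                          NumericVector times, double step) {
  std::vector<double> p(pars.begin(), pars.end());
  NumericVector out(times.size());
  conc_mm_T(p.data(), doses, times, step, REAL(out));
  return out;
}

// ---------------------------------------------------------------------------
// Individual log-posterior.
// Drug codes: 1 amikacin, 2 vancomycin, 3 theophylline, 4 phenytoin.
// eta maps to natural parameters via Parameter = mean * exp(eta); structural
// CL/V are derived from covariates (CrCl in L/h, LBW and TBW in kg).
// Residual sigma_i = cv_assay * Cpred_i + s_assay.
// ---------------------------------------------------------------------------

struct LPData {
  NumericMatrix doses;
  NumericVector obs_t, obs_y;
  NumericVector prior_mean, omega; // estimated parameters only, in order
  double crcl_lh, lbw, tbw;
  bool ss;
  double tau;
  double err_cv, err_s;
  double ode_step;
};

static const double LOG2PI = 1.837877066409345483560659472811;

template <typename T>
void predict_T(int drug, const T *eta, const LPData &d, T *conc) {
  if (drug == 1) {
    T cls = T(d.prior_mean[0]) * exp(eta[0]);
    T clnr = T(d.prior_mean[1]) * exp(eta[1]);
    T vnr = T(d.prior_mean[2]) * exp(eta[2]);
    T p[2] = {cls * T(d.crcl_lh) + clnr * T(d.lbw) * T(0.06), vnr * T(d.lbw)};
    conc_linear_T(1, p, d.doses, d.obs_t, d.ss, d.tau, conc);
  } else if (drug == 2) {
    T cls = T(d.prior_mean[0]) * exp(eta[0]);
    T clnr = T(d.prior_mean[1]) * exp(eta[1]);
    T vnr = T(d.prior_mean[2]) * exp(eta[2]);
    T k12 = T(d.prior_mean[3]) * exp(eta[3]);
    T k21 = T(d.prior_mean[4]) * exp(eta[4]);
    T p[4] = {cls * T(d.crcl_lh) + clnr * T(d.lbw) * T(0.06), vnr * T(d.lbw),
              k12, k21};
    conc_linear_T(2, p, d.doses, d.obs_t, d.ss, d.tau, conc);
  } else if (drug == 3) {
    T clnr = T(d.prior_mean[0]) * exp(eta[0]);
    T vnr = T(d.prior_mean[1]) * exp(eta[1]);
    T p[4] = {clnr * T(d.lbw) * T(0.001), vnr * T(d.lbw), T(0.27), T(1.0)};
    conc_linear_T(3, p, d.doses, d.obs_t, d.ss, d.tau, conc);
  } else {
    T vmax = T(d.prior_mean[0]) * exp(eta[0]); // mg/day
    T km = T(d.prior_mean[1]) * exp(eta[1]);
    T vnr = T(d.prior_mean[2]) * exp(eta[2]);
    T V = vnr * T(70.0) * pow(T(d.tbw / 70.0), T(0.6));
    T p[5] = {vmax / T(24.0), km, V, T(0.01) * T(d.crcl_lh), T(0.92)};
    conc_mm_T(p, d.doses, d.obs_t, d.ode_step, conc);
  }
}

template <typename T>
T logpost_T(int drug, const T *eta, const LPData &d) {
  int L = d.omega.size();
  T lp(0.0);
  for (int k = 0; k < L; ++k) {
    double w = d.omega[k];
    lp += T(-0.5) * (eta[k] / T(w)) * (eta[k] / T(w)) - T(std::log(w)) -
          T(0.5 * LOG2PI);
  }
  int n = d.obs_t.size();
  if (n > 0) {
    std::vector<T> conc(n);
    predict_T(drug, eta, d, conc.data());
    for (int i = 0; i < n; ++i) {
      T sig = T(d.err_cv) * conc[i] + T(d.err_s);
      T z = (T(d.obs_y[i]) - conc[i]) / sig;
      lp += T(-0.5) * z * z - log(sig) - T(0.5 * LOG2PI);
    }
  }
  return lp;
}

// MAP objective Phi: weighted squared residuals plus squared prior
// deviations on the log scale; sigma recomputed from the current prediction.
template <typename T>
T phi_T(int drug, const T *eta, const LPData &d) {
  int L = d.omega.size();
  T phi(0.0);
  for (int k = 0; k < L; ++k) {
    double w = d.omega[k];
    phi += (eta[k] / T(w)) * (eta[k] / T(w));
  }
  int n = d.obs_t.size();
  if (n > 0) {
    std::vector<T> conc(n);
    predict_T(drug, eta, d, conc.data());
    for (int i = 0; i < n; ++i) {
      T sig = T(d.err_cv) * conc[i] + T(d.err_s);
      T z = (T(d.obs_y[i]) - conc[i]) / sig;
      phi += z * z;
    }
  }
  return phi;
}

static LPData lp_from_list(const List &data) {
  LPData d = {as<NumericMatrix>(data["doses"]),
              as<NumericVector>(data["obs_t"]),
              as<NumericVector>(data["obs_y"]),
              as<NumericVector>(data["prior_mean"]),
              as<NumericVector>(data["omega"]),
              as<double>(data["crcl_lh"]),
              as<double>(data["lbw"]),
              as<double>(data["tbw"]),
              as<bool>(data["ss"]),
              as<double>(data["tau"]),
              as<double>(data["err_cv"]),
              as<double>(data["err_s"]),
              as<double>(data["ode_step"])};
  return d;
}

static void grad_complex(int drug, const double *eta, const LPData &d, int L,
                         double *g) {
  const double h = 1e-20;
  std::vector<cplx> ec(L);
  for (int k = 0; k < L; ++k) ec[k] = cplx(eta[k], 0.0);
  for (int k = 0; k < L; ++k) {
    ec[k] = cplx(eta[k], h);
    cplx lp = logpost_T(drug, ec.data(), d);
    g[k] = lp.imag() / h;
    ec[k] = cplx(eta[k], 0.0);
  }
}

// [[Rcpp::export]]
List cpp_logpost(int drug, NumericVector eta, List data, bool want_grad) {
  LPData d = lp_from_list(data);
  int L = eta.size();
  std::vector<double> e(eta.begin(), eta.end());
  double lp = logpost_T(drug, e.data(), d);
  List out = List::create(Named("value") = lp);
  if (want_grad) {
    NumericVector g(L);
    grad_complex(drug, e.data(), d, L, REAL(g));
    out["grad"] = g;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_phi(int drug, NumericVector eta, List data) {
  LPData d = lp_from_list(data);
  std::vector<double> e(eta.begin(), eta.end());
  return phi_T(drug, e.data(), d);
}

// [[Rcpp::export]]
NumericVector cpp_phi_grad(int drug, NumericVector eta, List data) {
  LPData d = lp_from_list(data);
  int L = eta.size();
  const double h = 1e-20;
  NumericVector g(L);
  std::vector<cplx> ec(L);
  for (int k = 0; k < L; ++k) ec[k] = cplx(eta[k], 0.0);
  for (int k = 0; k < L; ++k) {
    ec[k] = cplx(eta[k], h);
    cplx ph = phi_T(drug, ec.data(), d);
    g[k] = ph.imag() / h;
    ec[k] = cplx(eta[k], 0.0);
  }
  return g;
}

// [[Rcpp::export]]
NumericVector cpp_predict_eta(int drug, NumericVector eta, List data) {
  LPData d = lp_from_list(data);
  int n = d.obs_t.size();
  NumericVector out(n);
  std::vector<double> e(eta.begin(), eta.end());
  predict_T(drug, e.data(), d, REAL(out));
  return out;
}

// ---------------------------------------------------------------------------
// No-U-Turn sampler with dual-averaging step-size adaptation and diagonal
// mass-matrix estimation during warmup (slice-sampling tree variant).
// Self-contained deterministic RNG (xoshiro-free mt19937_64 + Box-Muller)
// so that draws are reproducible for a given seed.
// ---------------------------------------------------------------------------

struct RNG {
  std::mt19937_64 gen;
  bool have_spare = false;
  double spare = 0.0;
  explicit RNG(uint64_t seed) : gen(seed) {}
  double unif() {
    return ((gen() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

struct Posterior {
  int drug;
  LPData d;
  int L;
  long n_grad = 0;
  double lp(const double *eta) { return logpost_T(drug, eta, d); }
  void grad(const double *eta, double *g) {
    grad_complex(drug, eta, d, L, g);
    ++n_grad;
  }
};

struct Tree {
  std::vector<double> theta_m, r_m, theta_p, r_p, theta_prime;
  double n_prime = 0.0;
  int s_prime = 1;
  double alpha = 0.0;
  double n_alpha = 0.0;
  bool divergent = false;
};

class NutsChain {
public:
  Posterior *post;
  RNG rng;
  int L;
  std::vector<double> inv_mass; // inverse mass diagonal (position scale^2)
  double eps;
  const double delta_max = 1000.0;

  NutsChain(Posterior *p, uint64_t seed)
      : post(p), rng(seed), L(p->L), inv_mass(p->L, 1.0), eps(0.1) {}

  void leapfrog(std::vector<double> &th, std::vector<double> &r, double e) {
    std::vector<double> g(L);
    post->grad(th.data(), g.data());
    for (int k = 0; k < L; ++k) r[k] += 0.5 * e * g[k];
    for (int k = 0; k < L; ++k) th[k] += e * inv_mass[k] * r[k];
    post->grad(th.data(), g.data());
    for (int k = 0; k < L; ++k) r[k] += 0.5 * e * g[k];
  }

  double joint(const std::vector<double> &th, const std::vector<double> &r) {
    double k = 0.0;
    for (int j = 0; j < L; ++j) k += 0.5 * inv_mass[j] * r[j] * r[j];
    double lp = post->lp(th.data());
    if (!std::isfinite(lp)) return -INFINITY;
    return lp - k;
  }

  void sample_momentum(std::vector<double> &r) {
    for (int k = 0; k < L; ++k) r[k] = rng.norm() / std::sqrt(inv_mass[k]);
  }

  double find_reasonable_eps(const std::vector<double> &theta0) {
    double e = 0.1;
    std::vector<double> th = theta0, r(L);
    sample_momentum(r);
    double j0 = joint(th, r);
    std::vector<double> th1 = th, r1 = r;
    leapfrog(th1, r1, e);
    double j1 = joint(th1, r1);
    double a = (j1 - j0) > std::log(0.5) ? 1.0 : -1.0;
    for (int it = 0; it < 50; ++it) {
      e *= std::pow(2.0, a);
      th1 = th; r1 = r;
      leapfrog(th1, r1, e);
      j1 = joint(th1, r1);
      if (!std::isfinite(j1)) { e /= 2.0; break; }
      if (a * (j1 - j0) <= a * std::log(0.5)) break;
    }
    return e;
  }

  bool no_uturn(const std::vector<double> &tm, const std::vector<double> &rm,
                const std::vector<double> &tp, const std::vector<double> &rp) {
    double sm = 0.0, sp = 0.0;
    for (int k = 0; k < L; ++k) {
      double dth = tp[k] - tm[k];
      sm += dth * inv_mass[k] * rm[k];
      sp += dth * inv_mass[k] * rp[k];
    }
    return (sm >= 0.0) && (sp >= 0.0);
  }

  Tree build_tree(std::vector<double> th, std::vector<double> r, double logu,
                  int v, int depth, double j0) {
    Tree t;
    if (depth == 0) {
      leapfrog(th, r, v * eps);
      double j = joint(th, r);
      t.theta_m = th; t.r_m = r; t.theta_p = th; t.r_p = r;
      t.theta_prime = th;
      t.n_prime = (logu <= j) ? 1.0 : 0.0;
      t.s_prime = (logu < j + delta_max) ? 1 : 0;
      if (!t.s_prime) t.divergent = true;
      double da = j - j0;
      t.alpha = std::isfinite(da) ? std::min(1.0, std::exp(da)) : 0.0;
      t.n_alpha = 1.0;
      return t;
    }
    Tree t1 = build_tree(th, r, logu, v, depth - 1, j0);
    if (t1.s_prime) {
      Tree t2 = (v == -1)
                    ? build_tree(t1.theta_m, t1.r_m, logu, v, depth - 1, j0)
                    : build_tree(t1.theta_p, t1.r_p, logu, v, depth - 1, j0);
      if (v == -1) { t1.theta_m = t2.theta_m; t1.r_m = t2.r_m; }
      else { t1.theta_p = t2.theta_p; t1.r_p = t2.r_p; }
      double ntot = t1.n_prime + t2.n_prime;
      if (ntot > 0.0 && rng.unif() < t2.n_prime / ntot)
        t1.theta_prime = t2.theta_prime;
      t1.s_prime = t2.s_prime &&
                   no_uturn(t1.theta_m, t1.r_m, t1.theta_p, t1.r_p);
      t1.n_prime = ntot;
      t1.alpha += t2.alpha;
      t1.n_alpha += t2.n_alpha;
      t1.divergent = t1.divergent || t2.divergent;
    }
    return t1;
  }

  // One NUTS transition; returns (alpha_mean, divergent flag).
  std::pair<double, bool> transition(std::vector<double> &theta,
                                     int max_depth) {
    std::vector<double> r(L);
    sample_momentum(r);
    double j0 = joint(theta, r);
    double logu = j0 + std::log(rng.unif()); // u ~ U(0, exp(j0))
    std::vector<double> tm = theta, tp = theta, rm = r, rp = r;
    std::vector<double> sample = theta;
    double n = 1.0;
    int s = 1, depth = 0;
    double alpha = 0.5, n_alpha = 1.0;
    bool div = false;
    while (s && depth < max_depth) {
      int v = (rng.unif() < 0.5) ? -1 : 1;
      Tree t = (v == -1) ? build_tree(tm, rm, logu, v, depth, j0)
                         : build_tree(tp, rp, logu, v, depth, j0);
      if (v == -1) { tm = t.theta_m; rm = t.r_m; }
      else { tp = t.theta_p; rp = t.r_p; }
      if (t.s_prime && n + t.n_prime > 0.0 &&
          rng.unif() < t.n_prime / n)
        sample = t.theta_prime;
      n += t.n_prime;
      s = t.s_prime && no_uturn(tm, rm, tp, rp);
      alpha = t.alpha; n_alpha = t.n_alpha;
      div = div || t.divergent;
      ++depth;
    }
    theta = sample;
    return {n_alpha > 0 ? alpha / n_alpha : 0.0, div};
  }
};

// [[Rcpp::export]]
List cpp_nuts(int drug, List data, int chains, int warmup, int samples,
              double target_accept, int max_treedepth, int seed,
              NumericMatrix inits) {
  LPData d = lp_from_list(data);
  int L = d.omega.size();
  NumericMatrix draws(chains * samples, L);
  IntegerVector divergences(chains);
  NumericVector stepsizes(chains);
  long n_grad_total = 0;

  for (int c = 0; c < chains; ++c) {
    Posterior post;
    post.drug = drug;
    post.d = d;
    post.L = L;
    NutsChain ch(&post, (uint64_t)seed * 1000003ULL + (uint64_t)c + 1ULL);
    std::vector<double> theta(L);
    for (int k = 0; k < L; ++k) theta[k] = inits(c, k);

    // dual averaging setup
    ch.eps = ch.find_reasonable_eps(theta);
    double mu = std::log(10.0 * ch.eps);
    double logeps_bar = 0.0, hbar = 0.0;
    const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
    int ndiv = 0;

    // mass adaptation window
    int w_start = warmup / 4, w_end = (3 * warmup) / 4;
    std::vector<double> msum(L, 0.0), msum2(L, 0.0);
    int mcount = 0;
    int da_iter = 0;

    for (int it = 0; it < warmup; ++it) {
      auto res = ch.transition(theta, max_treedepth);
      ++da_iter;
      double m = (double)da_iter;
      hbar = (1.0 - 1.0 / (m + t0)) * hbar +
             (target_accept - res.first) / (m + t0);
      double logeps = mu - std::sqrt(m) / gamma * hbar;
      double w = std::pow(m, -kappa);
      logeps_bar = w * logeps + (1.0 - w) * logeps_bar;
      ch.eps = std::exp(logeps);
      if (it >= w_start && it < w_end) {
        for (int k = 0; k < L; ++k) {
          msum[k] += theta[k];
          msum2[k] += theta[k] * theta[k];
        }
        ++mcount;
      }
      if (it == w_end - 1 && mcount > 10) {
        for (int k = 0; k < L; ++k) {
          double mean = msum[k] / mcount;
          double var = msum2[k] / mcount - mean * mean;
          // regularize towards unit like Stan
          var = (mcount / (mcount + 5.0)) * var +
                (5.0 / (mcount + 5.0)) * 1e-3;
          if (var > 0.0 && std::isfinite(var)) ch.inv_mass[k] = var;
        }
        ch.eps = ch.find_reasonable_eps(theta);
        mu = std::log(10.0 * ch.eps);
        hbar = 0.0;
        logeps_bar = std::log(ch.eps);
        da_iter = 0;
      }
    }
    ch.eps = std::exp(logeps_bar);
    for (int it = 0; it < samples; ++it) {
      auto res = ch.transition(theta, max_treedepth);
      if (res.second) ++ndiv;
      for (int k = 0; k < L; ++k) draws(c * samples + it, k) = theta[k];
    }
    divergences[c] = ndiv;
    stepsizes[c] = ch.eps;
    n_grad_total += post.n_grad;
  }
  return List::create(Named("draws") = draws,
                      Named("divergences") = divergences,
                      Named("stepsize") = stepsizes,
                      Named("n_grad") = (double)n_grad_total);
}
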