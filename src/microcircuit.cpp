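// Conductance-based six-population microcircuit: dynamics, steady state,
// fixed-step RK4 integration, ERF prediction and finite-difference Jacobian.
//
// State vector (24 elements, fixed order):
//   [0..5]   V_p      membrane potential (mV), populations ss, sp, si, dp, tp, di
//   [6..23]  g_{p,r}  conductances, population-major, receptor order AMPA, NMDA, GABA
//
// Each condition is integrated from its own resting fixed point and observed
// relative to it, so pre-stimulus samples sit exactly at baseline.
//
// The inner loops run on plain arrays: an inversion evaluates the forward
// model tens of thousands of times through the Jacobian.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

constexpr int NP = 6;     // populations
constexpr int NS = 24;    // state dimension

struct McSpec {
  double VL, VE, VI;
  double C[NP], cL[NP];
  double tau[3];              // AMPA, NMDA, GABA (ms)
  double slope, thresh;       // firing sigmoid
  double mg_a, mg_b;          // magnesium gate coefficients
  int nE;
  std::vector<int> src, tgt, rec;   // 0-based
  std::vector<double> gamma;
  std::vector<int> flagged, gain_idx, b_idx;  // indices 0-based, -1 absent
  double in_onset, in_width, in_amp;
  int in_amp_idx;
  std::vector<int> input_pops;
  double obs_w[NP], obs_gain, obs_baseline;
  std::vector<double> times;
  double dt;
};

McSpec parse_spec(const List& s) {
  McSpec m;
  m.VL = as<double>(s["VL"]);
  m.VE = as<double>(s["VE"]);
  m.VI = as<double>(s["VI"]);
  NumericVector C = s["C"], cL = s["cL"], tau = s["tau"];
  for (int p = 0; p < NP; ++p) { m.C[p] = C[p]; m.cL[p] = cL[p]; }
  for (int k = 0; k < 3; ++k) m.tau[k] = tau[k];
  m.slope = as<double>(s["slope"]);
  m.thresh = as<double>(s["thresh"]);
  m.mg_a = as<double>(s["mg_a"]);
  m.mg_b = as<double>(s["mg_b"]);
  IntegerMatrix e = s["edges"];
  m.nE = e.nrow();
  m.src.resize(m.nE); m.tgt.resize(m.nE); m.rec.resize(m.nE);
  for (int i = 0; i < m.nE; ++i) {
    m.src[i] = e(i, 0) - 1; m.tgt[i] = e(i, 1) - 1; m.rec[i] = e(i, 2) - 1;
  }
  m.gamma = as<std::vector<double>>(s["gamma"]);
  m.flagged = as<std::vector<int>>(s["flagged"]);
  m.gain_idx = as<std::vector<int>>(s["gain_idx"]);
  m.b_idx = as<std::vector<int>>(s["b_idx"]);
  for (int i = 0; i < m.nE; ++i) { m.gain_idx[i] -= 1; m.b_idx[i] -= 1; }
  List inp = s["input"];
  m.in_onset = as<double>(inp["onset"]);
  m.in_width = as<double>(inp["width"]);
  m.in_amp = as<double>(inp["amplitude"]);
  m.in_amp_idx = as<int>(inp["amp_idx"]) - 1;
  m.input_pops = as<std::vector<int>>(inp["pops"]);
  for (size_t i = 0; i < m.input_pops.size(); ++i) m.input_pops[i] -= 1;
  List obs = s["obs"];
  NumericVector w = obs["w"];
  for (int p = 0; p < NP; ++p) m.obs_w[p] = w[p];
  m.obs_gain = as<double>(obs["gain"]);
  m.obs_baseline = as<double>(obs["baseline"]);
  m.times = as<std::vector<double>>(s["times"]);
  m.dt = as<double>(s["dt"]);
  return m;
}

// One condition's realized system: effective gains and input amplitude
struct System {
  const McSpec* m;
  std::vector<double> geff;
  double amp;
  bool input_mask[NP];

  System(const McSpec& spec, const arma::vec& free, bool deviant)
      : m(&spec), geff(spec.nE) {
    for (int i = 0; i < spec.nE; ++i) {
      double g = spec.gamma[i];
      if (spec.gain_idx[i] >= 0) g *= std::exp(free(spec.gain_idx[i]));
      if (deviant && spec.flagged[i] && spec.b_idx[i] >= 0)
        g *= std::exp(free(spec.b_idx[i]));
      geff[i] = g;
    }
    amp = spec.in_amp;
    if (spec.in_amp_idx >= 0) amp *= std::exp(free(spec.in_amp_idx));
    for (int p = 0; p < NP; ++p) input_mask[p] = false;
    for (size_t i = 0; i < spec.input_pops.size(); ++i)
      input_mask[spec.input_pops[i]] = true;
  }

  double input_at(double t) const {
    if (t < 0.0) return 0.0;
    const double z = (t - m->in_onset) / m->in_width;
    return amp * std::exp(-0.5 * z * z);
  }

  void derivative(const double* s, double u, double* out) const {
    const McSpec& sp = *m;
    double sigma[NP], drive[NP][3];
    for (int p = 0; p < NP; ++p) {
      sigma[p] = 1.0 / (1.0 + std::exp(-(s[p] - sp.thresh) * sp.slope));
      drive[p][0] = drive[p][1] = drive[p][2] = 0.0;
    }
    for (int i = 0; i < sp.nE; ++i)
      drive[sp.tgt[i]][sp.rec[i]] += geff[i] * sigma[sp.src[i]];
    for (int p = 0; p < NP; ++p) {
      const double V = s[p];
      const double gA = s[NP + 3 * p + 0];
      const double gN = s[NP + 3 * p + 1];
      const double gG = s[NP + 3 * p + 2];
      const double mgate = 1.0 / (1.0 + sp.mg_b * std::exp(-sp.mg_a * V));
      double I = sp.cL[p] * (sp.VL - V) + gA * (sp.VE - V) +
                 gG * (sp.VI - V) + gN * mgate * (sp.VE - V);
      if (input_mask[p]) I += u;
      out[p] = I / sp.C[p];
      out[NP + 3 * p + 0] = (drive[p][0] - gA) / sp.tau[0];
      out[NP + 3 * p + 1] = (drive[p][1] - gN) / sp.tau[1];
      out[NP + 3 * p + 2] = (drive[p][2] - gG) / sp.tau[2];
    }
  }

  void rk4_step(double* s, double t, double dt) const {
    double k1[NS], k2[NS], k3[NS], k4[NS], tmp[NS];
    derivative(s, input_at(t), k1);
    for (int j = 0; j < NS; ++j) tmp[j] = s[j] + 0.5 * dt * k1[j];
    derivative(tmp, input_at(t + 0.5 * dt), k2);
    for (int j = 0; j < NS; ++j) tmp[j] = s[j] + 0.5 * dt * k2[j];
    derivative(tmp, input_at(t + 0.5 * dt), k3);
    for (int j = 0; j < NS; ++j) tmp[j] = s[j] + dt * k3[j];
    derivative(tmp, input_at(t + dt), k4);
    for (int j = 0; j < NS; ++j)
      s[j] += (dt / 6.0) * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
  }
};

double resid_norm(const System& sys, const double* s) {
  double f[NS];
  sys.derivative(s, 0.0, f);
  double r = 0.0;
  for (int j = 0; j < NS; ++j) r = std::max(r, std::abs(f[j]));
  return r;
}

// Damped Newton polish with a central-difference state Jacobian; returns
// the final residual and stops early when stalled.
static void newton_polish(const System& sys, double tol, int maxit,
                          double* state, double& resid) {
  arma::vec f(NS), fc(NS), step(NS);
  arma::mat J(NS, NS);
  double tmp[NS], f1[NS], f2[NS];
  sys.derivative(state, 0.0, f.memptr());
  resid = arma::norm(f, "inf");
  int it = 0;
  while (resid > tol && it < maxit) {
    const double h = 1e-6;
    for (int j = 0; j < NS; ++j) {
      for (int k = 0; k < NS; ++k) tmp[k] = state[k];
      tmp[j] += h; sys.derivative(tmp, 0.0, f1);
      tmp[j] -= 2 * h; sys.derivative(tmp, 0.0, f2);
      for (int k = 0; k < NS; ++k) J(k, j) = (f1[k] - f2[k]) / (2 * h);
    }
    if (!arma::solve(step, J, -f, arma::solve_opts::no_approx)) break;
    double alpha = 1.0, rc = resid;
    double cand[NS];
    for (int bt = 0; bt < 30; ++bt) {
      for (int k = 0; k < NS; ++k) cand[k] = state[k] + alpha * step(k);
      sys.derivative(cand, 0.0, fc.memptr());
      rc = arma::norm(fc, "inf");
      if (rc < resid) break;
      alpha *= 0.5;
    }
    if (rc >= resid) break;
    for (int k = 0; k < NS; ++k) state[k] = cand[k];
    f = fc;
    resid = rc;
    ++it;
  }
}

// Rest state: alternate relaxation of the autonomous system with damped
// Newton polishing (slow NMDA modes can need seconds of relaxation before
// Newton's basin is reached).
bool steady_core(const System& sys, double tol, int maxit, double* state,
                 double& resid, const double* warm = nullptr) {
  if (warm) {
    for (int j = 0; j < NS; ++j) state[j] = warm[j];
  } else {
    for (int j = 0; j < NS; ++j) state[j] = 0.0;
    for (int p = 0; p < NP; ++p) state[p] = sys.m->VL;
    for (int k = 0; k < 400; ++k) sys.rk4_step(state, -1e9, 1.0);
  }
  newton_polish(sys, tol, maxit, state, resid);
  for (int round = 0; round < 6 && resid > tol; ++round) {
    for (int k = 0; k < 1000; ++k) sys.rk4_step(state, -1e9, 1.0);
    for (int j = 0; j < NS; ++j)
      if (!std::isfinite(state[j])) return false;
    newton_polish(sys, tol, maxit, state, resid);
  }
  for (int j = 0; j < NS; ++j)
    if (!std::isfinite(state[j])) return false;
  return resid <= tol;
}

void integrate_core(const System& sys, const double* init, arma::mat& out) {
  const McSpec& m = *sys.m;
  const size_t nT = m.times.size();
  double state[NS];
  for (int j = 0; j < NS; ++j) state[j] = init[j];
  for (int j = 0; j < NS; ++j) out(0, j) = state[j];
  double t = m.times[0];
  for (size_t i = 1; i < nT; ++i) {
    const double target = m.times[i];
    const int nstep = (int)std::lround((target - t) / m.dt);
    for (int k = 0; k < nstep; ++k) {
      sys.rk4_step(state, t, m.dt);
      t += m.dt;
    }
    t = target;
    for (int j = 0; j < NS; ++j) {
      if (!std::isfinite(state[j]))
        stop("non-finite state encountered at t = %f ms", t);
      out(i, j) = state[j];
    }
  }
}

// Observe one condition relative to its own resting state, writing into y
void predict_condition(const System& sys, const double* ss, double* y) {
  const McSpec& m = *sys.m;
  const size_t nT = m.times.size();
  arma::mat traj(nT, NS);
  integrate_core(sys, ss, traj);
  for (size_t i = 0; i < nT; ++i) {
    double v = m.obs_baseline;
    for (int p = 0; p < NP; ++p)
      if (m.obs_w[p] != 0.0)
        v += m.obs_gain * m.obs_w[p] * (traj(i, p) - ss[p]);
    y[i] = v;
  }
}

arma::vec predict_core(const McSpec& m, const arma::vec& free) {
  System sys_s(m, free, false), sys_d(m, free, true);
  double ss_s[NS], ss_d[NS], resid;
  if (!steady_core(sys_s, 1e-9, 50, ss_s, resid))
    stop("steady-state search failed to converge: residual %g", resid);
  // the deviant fixed point is close to the standard one: warm start
  if (!steady_core(sys_d, 1e-9, 50, ss_d, resid, ss_s)) {
    if (!steady_core(sys_d, 1e-9, 50, ss_d, resid))
      stop("steady-state search failed to converge: residual %g", resid);
  }
  const size_t nT = m.times.size();
  arma::vec y(2 * nT);
  predict_condition(sys_s, ss_s, y.memptr());
  predict_condition(sys_d, ss_d, y.memptr() + nT);
  return y;
}

} // namespace

// [[Rcpp::export]]
arma::vec mc_deriv_cpp(List spec, arma::vec state, arma::vec free,
                       double input_value, bool deviant) {
  McSpec m = parse_spec(spec);
  if (!state.is_finite()) stop("non-finite state");
  System sys(m, free, deviant);
  arma::vec out(NS);
  sys.derivative(state.memptr(), input_value, out.memptr());
  return out;
}

// [[Rcpp::export]]
List mc_steady_cpp(List spec, arma::vec free, double tol, int maxit,
                   bool deviant) {
  McSpec m = parse_spec(spec);
  System sys(m, free, deviant);
  double state[NS], resid;
  bool ok = steady_core(sys, tol, maxit, state, resid);
  return List::create(_["state"] = NumericVector(state, state + NS),
                      _["residual"] = resid, _["converged"] = ok);
}

// [[Rcpp::export]]
arma::mat mc_integrate_cpp(List spec, arma::vec free, bool deviant,
                           arma::vec init) {
  McSpec m = parse_spec(spec);
  System sys(m, free, deviant);
  arma::mat out(m.times.size(), NS);
  integrate_core(sys, init.memptr(), out);
  return out;
}

// [[Rcpp::export]]
arma::vec mc_predict_cpp(List spec, arma::vec free) {
  McSpec m = parse_spec(spec);
  return predict_core(m, free);
}

// Central-difference Jacobian of the concatenated (standard, deviant)
// prediction with respect to the free parameters.
// [[Rcpp::export]]
arma::mat mc_jacobian_cpp(List spec, arma::vec free, double step) {
  McSpec m = parse_spec(spec);
  const arma::uword p = free.n_elem;
  const arma::uword n = 2 * m.times.size();
  arma::mat J(n, p);
  arma::vec f(free);
  for (arma::uword j = 0; j < p; ++j) {
    const double x0 = f(j);
    f(j) = x0 + step;
    arma::vec yp = predict_core(m, f);
    f(j) = x0 - step;
    arma::vec ym = predict_core(m, f);
    f(j) = x0;
    J.col(j) = (yp - ym) / (2.0 * step);
  }
  return J;
}
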