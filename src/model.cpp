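#include <Rcpp.h>
using namespace Rcpp;

// Modified Morris-Lecar membrane model with low-threshold (Kv1-type, gate z)
// and inactivating A-type (gates a^4 b) potassium conductances.
//
// Parameter vector layout (shared with R/.param_vec):
//  0 C, 1 E_Na, 2 E_K, 3 E_leak, 4 gbar_Na, 5 gbar_Kdr, 6 gbar_leak,
//  7 gbar_Klt, 8 gbar_KA, 9 phi_w, 10 phi_z, 11 phi_a, 12 phi_b,
// 13 beta_m, 14 beta_w, 15 beta_z, 16 gamma_m, 17 gamma_w, 18 gamma_z

struct MLParams {
  double C, ENa, EK, Eleak, gNa, gKdr, gleak, gKlt, gKA;
  double phiw, phiz, phia, phib;
  double betam, betaw, betaz, gammam, gammaw, gammaz;
  explicit MLParams(const NumericVector& p) {
    C = p[0]; ENa = p[1]; EK = p[2]; Eleak = p[3];
    gNa = p[4]; gKdr = p[5]; gleak = p[6]; gKlt = p[7]; gKA = p[8];
    phiw = p[9]; phiz = p[10]; phia = p[11]; phib = p[12];
    betam = p[13]; betaw = p[14]; betaz = p[15];
    gammam = p[16]; gammaw = p[17]; gammaz = p[18];
  }
};

struct MLState { double V, w, z, a, b; };

static inline double minf(const MLParams& p, double V) {
  return 0.5 * (1.0 + tanh((V - p.betam) / p.gammam));
}
static inline double winf(const MLParams& p, double V) {
  return 0.5 * (1.0 + tanh((V - p.betaw) / p.gammaw));
}
static inline double zinf(const MLParams& p, double V) {
  return 0.5 * (1.0 + tanh((V - p.betaz) / p.gammaz));
}
static inline double ainf(double V) { return 1.0 / (1.0 + exp(-(V + 60.0) / 8.5)); }
static inline double binf(double V) { return 1.0 / (1.0 + exp((V + 78.0) / 6.0)); }
static inline double tauw(const MLParams& p, double V) {
  return 1.0 / cosh((V - p.betaw) / (2.0 * p.gammaw));
}
static inline double tauz(const MLParams& p, double V) {
  return 1.0 / cosh((V - p.betaz) / (2.0 * p.gammaz));
}
static inline double taua(double V) {
  return 1.0 / (exp((V + 35.82) / 19.69) + exp(-(V + 79.69) / 12.7)) + 0.37;
}
// V = -63 exactly takes the double-exponential branch
static inline double taub(double V) {
  if (V > -63.0) return 19.0;
  return 1.0 / (exp((V + 46.05) / 5.0) + exp(-(V + 238.4) / 37.45));
}

static inline MLState steady(const MLParams& p, double V) {
  MLState s;
  s.V = V;
  s.w = winf(p, V); s.z = zinf(p, V); s.a = ainf(V); s.b = binf(V);
  return s;
}

static inline void euler_step(const MLParams& p, MLState& s, double I, double dt) {
  const double V = s.V;
  const double dV = (I
    - p.gNa  * minf(p, V) * (V - p.ENa)
    - p.gKdr * s.w * (V - p.EK)
    - p.gKlt * s.z * (V - p.EK)
    - p.gKA  * s.a * s.a * s.a * s.a * s.b * (V - p.EK)
    - p.gleak * (V - p.Eleak)) / p.C;
  s.V += dt * dV;
  s.w += dt * p.phiw * (winf(p, V) - s.w) / tauw(p, V);
  s.z += dt * p.phiz * (zinf(p, V) - s.z) / tauz(p, V);
  s.a += dt * p.phia * (ainf(V) - s.a) / taua(V);
  s.b += dt * p.phib * (binf(V) - s.b) / taub(V);
}

// [[Rcpp::export(name = ".ml_gating_cpp")]]
NumericVector ml_gating_cpp(NumericVector pv, double V) {
  MLParams p(pv);
  return NumericVector::create(
    _["m_inf"] = minf(p, V), _["w_inf"] = winf(p, V), _["z_inf"] = zinf(p, V),
    _["a_inf"] = ainf(V), _["b_inf"] = binf(V),
    _["tau_w"] = tauw(p, V), _["tau_z"] = tauz(p, V),
    _["tau_a"] = taua(V), _["tau_b"] = taub(V));
}

// Full trace: forward Euler through settle (I = I_pre) then stimulus
// (I = I_pre + I_stim).  Times are reported relative to stimulus onset.
// [[Rcpp::export(name = ".ml_trace_cpp")]]
List ml_trace_cpp(NumericVector pv, double settle, double stim_dur,
                  double I_pre, double I_stim, double dt) {
  MLParams p(pv);
  const int n_settle = (int)std::lround(settle / dt);
  const int n_stim = (int)std::lround(stim_dur / dt);
  const int n = n_settle + n_stim + 1;
  NumericVector times(n), V(n), w(n), z(n), a(n), b(n);
  MLState s = steady(p, p.Eleak);
  for (int k = 0; k < n; ++k) {
    times[k] = (k - n_settle) * dt;
    V[k] = s.V; w[k] = s.w; z[k] = s.z; a[k] = s.a; b[k] = s.b;
    if (!R_finite(s.V))
      stop("non-finite membrane potential at step %d (t = %.2f ms)", k, times[k]);
    if (k < n) {
      double I = (k < n_settle) ? I_pre : I_pre + I_stim;
      euler_step(p, s, I, dt);
    }
  }
  return List::create(_["times"] = times, _["V"] = V, _["w"] = w,
                      _["z"] = z, _["a"] = a, _["b"] = b,
                      _["n_settle"] = n_settle);
}

// Spike times only (upward threshold crossings during the stimulus window,
// linearly interpolated).  Used by the grid sweep where traces are not kept.
static std::vector<double> run_spikes(const MLParams& p, double settle,
                                      double stim_dur, double I_pre,
                                      double I_stim, double dt,
                                      double threshold, bool* blew_up) {
  const int n_settle = (int)std::lround(settle / dt);
  const int n_stim = (int)std::lround(stim_dur / dt);
  std::vector<double> spikes;
  MLState s = steady(p, p.Eleak);
  *blew_up = false;
  for (int k = 0; k < n_settle; ++k) euler_step(p, s, I_pre, dt);
  if (!R_finite(s.V)) { *blew_up = true; return spikes; }
  double Vprev = s.V;
  for (int k = 0; k < n_stim; ++k) {
    euler_step(p, s, I_pre + I_stim, dt);
    if (!R_finite(s.V)) { *blew_up = true; return spikes; }
    if (Vprev < threshold && s.V >= threshold) {
      double frac = (threshold - Vprev) / (s.V - Vprev);
      spikes.push_back((k + frac) * dt);
    }
    Vprev = s.V;
  }
  return spikes;
}

// [[Rcpp::export(name = ".ml_spikes_cpp")]]
NumericVector ml_spikes_cpp(NumericVector pv, double settle, double stim_dur,
                            double I_pre, double I_stim, double dt,
                            double threshold) {
  MLParams p(pv);
  bool blew = false;
  std::vector<double> sp = run_spikes(p, settle, stim_dur, I_pre, I_stim, dt,
                                      threshold, &blew);
  if (blew) stop("non-finite membrane potential during simulation");
  return wrap(sp);
}

// Sweep all (g_Klt, g_KA) pairs; returns a list of spike-time vectors.
// [[Rcpp::export(name = ".ml_sweep_cpp")]]
List ml_sweep_cpp(NumericVector pv, NumericVector g_lt, NumericVector g_A,
                  double settle, double stim_dur, double I_pre, double I_stim,
                  double dt, double threshold) {
  const int np = g_lt.size();
  if (g_A.size() != np) stop("g_lt and g_A must have equal length");
  List out(np);
  NumericVector base(clone(pv));
  for (int i = 0; i < np; ++i) {
    base[7] = g_lt[i];
    base[8] = g_A[i];
    MLParams p(base);
    bool blew = false;
    std::vector<double> sp = run_spikes(p, settle, stim_dur, I_pre, I_stim,
                                        dt, threshold, &blew);
    if (blew)
      stop("simulation blow-up at g_Klt = %.3f, g_KA = %.3f", g_lt[i], g_A[i]);
    out[i] = wrap(sp);
    if (i % 2048 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
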