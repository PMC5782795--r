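// Fixed-tick dynamic-clamp engine and the fine-step joint integrator used
// as its accuracy oracle.  The channel algebra mirrors the R reference
// implementations (R/ik1-model.R, R/virtual-cell.R); parameter vectors are
// packed on the R side (R/engine.R) so every constant remains
// single-sourced in R.

#include <Rcpp.h>
using namespace Rcpp;

struct IK1 {
  double dens, EK, Ko, Mg, SPM, fm1, Cm_inj;
  // rate constants
  double mg_a, mg_as, mg_b, mg_bs, mg_sites;
  double kd0, kd_s;
  double a2, a2s, a2sat, b2, b2s, b2sat, mg_shift;
  double ko_ref, ko_exp;
  double scale;   // precomputed Ko conductance scale

  void unpack(const NumericVector& v) {
    dens = v[0]; EK = v[1]; Ko = v[2]; Mg = v[3]; SPM = v[4];
    fm1 = v[5]; Cm_inj = v[6];
    mg_a = v[7]; mg_as = v[8]; mg_b = v[9]; mg_bs = v[10]; mg_sites = v[11];
    kd0 = v[12]; kd_s = v[13];
    a2 = v[14]; a2s = v[15]; a2sat = v[16];
    b2 = v[17]; b2s = v[18]; b2sat = v[19]; mg_shift = v[20];
    ko_ref = v[21]; ko_exp = v[22];
    scale = std::pow(Ko / ko_ref, ko_exp);
  }

  // instantaneous block factors and slow-gate kinetics at V
  void gating(double V, double& p_mg, double& f1,
              double& y_inf, double& tau_y) const {
    double dv = V - EK;
    double a = mg_a * std::exp(mg_as * dv);
    double b = mg_b * Mg * std::exp(mg_bs * dv);
    p_mg = std::pow(a / (a + b), mg_sites);
    double kd = kd0 * std::exp(-dv * kd_s);
    f1 = kd / (kd + SPM * 1e-3);
    double u = dv + mg_shift * Mg;
    double ay = a2 * std::exp(-a2s * u) / (1 + 0.01 * std::exp(a2sat * u));
    double by = b2 * SPM * std::exp(b2s * u) / (1 + 0.01 * std::exp(b2sat * u));
    y_inf = ay / (ay + by);
    tau_y = 1 / (ay + by);
  }

  // current density (pA/pF) at V with slow gate y
  double density_current(double V, double y) const {
    double p_mg, f1, yi, ty;
    gating(V, p_mg, f1, yi, ty);
    return dens * 1e-3 * scale * (V - EK) * p_mg *
      (fm1 * f1 + (1 - fm1) * y);
  }
};

struct Cell {
  double Cm, g_leak, E_leak, g_Na, E_Na, Vhm, km, tau_m, Vhh, kh, tau_h;
  double g_CaL, E_Ca, Vhd, kd, tau_d, Vhf, kf, tau_f;
  double g_Kr, E_Kr, Vhxr, kxr, tau_xr, Vhr, kr;
  double g_K1_endo;

  void unpack(const NumericVector& v) {
    Cm = v[0]; g_leak = v[1]; E_leak = v[2];
    g_Na = v[3]; E_Na = v[4]; Vhm = v[5]; km = v[6]; tau_m = v[7];
    Vhh = v[8]; kh = v[9]; tau_h = v[10];
    g_CaL = v[11]; E_Ca = v[12]; Vhd = v[13]; kd = v[14]; tau_d = v[15];
    Vhf = v[16]; kf = v[17]; tau_f = v[18];
    g_Kr = v[19]; E_Kr = v[20]; Vhxr = v[21]; kxr = v[22]; tau_xr = v[23];
    Vhr = v[24]; kr = v[25];
    g_K1_endo = v[26];
  }

  void gate_inf(double V, double& mi, double& hi,
                double& di, double& fi, double& xri) const {
    mi = 1 / (1 + std::exp(-(V - Vhm) / km));
    hi = 1 / (1 + std::exp((V - Vhh) / kh));
    di = 1 / (1 + std::exp(-(V - Vhd) / kd));
    fi = 1 / (1 + std::exp((V - Vhf) / kf));
    xri = 1 / (1 + std::exp(-(V - Vhxr) / kxr));
  }

  double kr_rect(double V) const {
    return 1 / (1 + std::exp((V - Vhr) / kr));
  }
};

struct State {
  double V, m, h, d, f, xr, y_endo, y_ik1, V_prev;
  void unpack(const NumericVector& v) {
    V = v[0]; m = v[1]; h = v[2]; d = v[3]; f = v[4]; xr = v[5];
    y_endo = v[6]; y_ik1 = v[7]; V_prev = v[8];
  }
  NumericVector pack() const {
    return NumericVector::create(
      _["V"] = V, _["m"] = m, _["h"] = h, _["d"] = d, _["f"] = f,
      _["xr"] = xr, _["y_endo"] = y_endo, _["y_ik1"] = y_ik1,
      _["V_prev"] = V_prev);
  }
};

static inline double clamp01(double x) {
  return x < 0 ? 0 : (x > 1 ? 1 : x);
}

// one cell substep: exponential gate update, then explicit Euler on V
// (order mirrors cell_step() in R)
static void cell_substep(const Cell& c, const IK1& endo, State& s,
                         double inj_pA, double dt_ms) {
  double mi, hi, di, fi, xri;
  c.gate_inf(s.V, mi, hi, di, fi, xri);
  s.m = mi + (s.m - mi) * std::exp(-dt_ms / c.tau_m);
  s.h = hi + (s.h - hi) * std::exp(-dt_ms / c.tau_h);
  s.d = di + (s.d - di) * std::exp(-dt_ms / c.tau_d);
  s.f = fi + (s.f - fi) * std::exp(-dt_ms / c.tau_f);
  s.xr = xri + (s.xr - xri) * std::exp(-dt_ms / c.tau_xr);
  double I_endo = 0;
  if (c.g_K1_endo > 0) {
    double p_mg, f1, yi, ty;
    endo.gating(s.V, p_mg, f1, yi, ty);
    s.y_endo = clamp01(yi + (s.y_endo - yi) * std::exp(-dt_ms * 1e-3 / ty));
    I_endo = endo.density_current(s.V, s.y_endo) * c.Cm;
  }
  double I_total = c.g_leak * (s.V - c.E_leak)
    + c.g_Na * s.m * s.h * (s.V - c.E_Na)
    + c.g_CaL * s.d * s.f * (s.V - c.E_Ca)
    + c.g_Kr * s.xr * c.kr_rect(s.V) * (s.V - c.E_Kr)
    + I_endo;
  s.V += dt_ms * (-I_total + inj_pA) / c.Cm;
}

// The dynamic-clamp loop.  Per tick: the measured potential (one tick old
// when latency = 1) drives the slow I_K1 gate and the injected current,
// which is held constant (zero-order hold) while the cell integrates in
// `substeps` substeps.  Row t of the trace records the tick-start
// potential and the currents applied during tick t.
// [[Rcpp::export]]
List run_clamp_cpp(NumericVector cellv, NumericVector endov,
                   NumericVector ik1v, NumericVector statev,
                   NumericVector stim_pA, double dt_tick,
                   int substeps, int latency, bool record = true) {
  Cell c; c.unpack(cellv);
  IK1 endo; endo.unpack(endov);
  IK1 k1; k1.unpack(ik1v);
  State s; s.unpack(statev);
  int n = stim_pA.size();
  double dt_sub_ms = dt_tick * 1e3 / substeps;
  NumericMatrix tr(record ? n : 0, 3);
  for (int t = 0; t < n; ++t) {
    double V_meas = latency ? s.V_prev : s.V;
    double I_k1 = 0;
    if (k1.dens > 0) {
      double p_mg, f1, yi, ty;
      k1.gating(V_meas, p_mg, f1, yi, ty);
      s.y_ik1 = clamp01(yi + (s.y_ik1 - yi) * std::exp(-dt_tick / ty));
      I_k1 = k1.density_current(V_meas, s.y_ik1) * k1.Cm_inj;
    }
    if (record) {
      tr(t, 0) = s.V; tr(t, 1) = I_k1; tr(t, 2) = stim_pA[t];
    }
    double inj = stim_pA[t] - I_k1;
    s.V_prev = s.V;
    for (int ss = 0; ss < substeps; ++ss) {
      cell_substep(c, endo, s, inj, dt_sub_ms);
    }
  }
  return List::create(_["trace"] = tr, _["state"] = s.pack());
}

// Monolithic accuracy oracle: the cell and the I_K1 model integrated
// jointly by forward Euler at a fine step dt (every state variable,
// gates included), with no loop latency and no zero-order hold -- the
// continuous system the discrete loop approximates.  The stimulus vector
// is indexed at tick resolution.  V is recorded every `decim` steps.
// [[Rcpp::export]]
NumericVector run_joint_euler_cpp(NumericVector cellv, NumericVector endov,
                                  NumericVector ik1v, NumericVector statev,
                                  NumericVector stim_pA, double dt_tick,
                                  double dt, int decim) {
  Cell c; c.unpack(cellv);
  IK1 endo; endo.unpack(endov);
  IK1 k1; k1.unpack(ik1v);
  State s; s.unpack(statev);
  int n_ticks = stim_pA.size();
  long n_steps = std::lround(n_ticks * dt_tick / dt);
  double dt_ms = dt * 1e3;
  NumericVector out(n_steps / decim);
  long rec = 0;
  for (long i = 0; i < n_steps; ++i) {
    if (i % decim == 0 && rec < out.size()) out[rec++] = s.V;
    int tick = (int)(i * dt / dt_tick);
    if (tick >= n_ticks) tick = n_ticks - 1;
    double mi, hi, di, fi, xri;
    c.gate_inf(s.V, mi, hi, di, fi, xri);
    double I_endo = 0;
    if (c.g_K1_endo > 0) {
      double p_mg, f1, yi, ty;
      endo.gating(s.V, p_mg, f1, yi, ty);
      s.y_endo = clamp01(s.y_endo + dt * (yi - s.y_endo) / ty);
      I_endo = endo.density_current(s.V, s.y_endo) * c.Cm;
    }
    double I_k1 = 0;
    if (k1.dens > 0) {
      double p_mg, f1, yi, ty;
      k1.gating(s.V, p_mg, f1, yi, ty);
      s.y_ik1 = clamp01(s.y_ik1 + dt * (yi - s.y_ik1) / ty);
      I_k1 = k1.density_current(s.V, s.y_ik1) * k1.Cm_inj;
    }
    double I_total = c.g_leak * (s.V - c.E_leak)
      + c.g_Na * s.m * s.h * (s.V - c.E_Na)
      + c.g_CaL * s.d * s.f * (s.V - c.E_Ca)
      + c.g_Kr * s.xr * c.kr_rect(s.V) * (s.V - c.E_Kr)
      + I_endo;
    s.m += dt_ms * (mi - s.m) / c.tau_m;
    s.h += dt_ms * (hi - s.h) / c.tau_h;
    s.d += dt_ms * (di - s.d) / c.tau_d;
    s.f += dt_ms * (fi - s.f) / c.tau_f;
    s.xr += dt_ms * (xri - s.xr) / c.tau_xr;
    s.V += dt_ms * (-I_total + stim_pA[tick] - I_k1) / c.Cm;
  }
  return out;
}
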