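// Fixed-step RK4 integration of a single-compartment conductance-based neuron:
// leak + transient Na / delayed-rectifier K spike currents + a generic plastic
// X conductance, optional Poisson background synaptic drive, and an optional
// intrinsic-plasticity loop (high-threshold Ca current -> shell Ca dynamics ->
// kinase/phosphatase cycle -> phosphorylated fraction scaling gmax of X).
//
// Units project-wide: mV, ms, uA/cm^2, mS/cm^2, uF/cm^2, uM.
#include <Rcpp.h>
#include <cmath>
#include <random>
using namespace Rcpp;

static inline double boltz(double V, double Vh, double k) {
  // activation-sign Boltzmann; inactivation is encoded by negating k upstream
  return 1.0 / (1.0 + std::exp(-(V - Vh) / k));
}

static inline double ipow(double x, int p) {
  switch (p) {
    case 1: return x;
    case 2: return x * x;
    case 3: return x * x * x;
    case 4: { double x2 = x * x; return x2 * x2; }
    default: return std::pow(x, (double)p);
  }
}

// linear-interpolation lookup table for voltage-dependent gating functions
struct VTab {
  double vmin, vmax, inv_dv;
  std::vector<double> y;
  template <class F> void build(F f, double a = -130.0, double b = 70.0, double dv = 0.05) {
    vmin = a; vmax = b; inv_dv = 1.0 / dv;
    size_t n = (size_t)((b - a) * inv_dv) + 2;
    y.resize(n);
    for (size_t i = 0; i < n; ++i) y[i] = f(a + i * dv);
  }
  inline double operator()(double V) const {
    double u = (V - vmin) * inv_dv;
    if (u <= 0) return y.front();
    size_t i = (size_t)u;
    if (i >= y.size() - 1) return y.back();
    double w = u - i;
    return y[i] * (1.0 - w) + y[i + 1] * w;
  }
};

struct APModel {
  // Golomb-Amitai style regular-spiking neocortical spike currents:
  // I_Na = gNa * m_inf(V)^3 * h * (V - VNa), m instantaneous
  // I_Kdr = gK * n^4 * (V - VK)
  double gNa, thm, sgm, thh, sgh, gK, thn, sgn, VNa, VK;
  double tauh0, tauh1, thth, sgth; // tau_h = tauh0 + tauh1 * boltz(V, thth, sgth)
  double taun0, taun1, thtn, sgtn;
  inline double minf(double V) const { return boltz(V, thm, sgm); }
  inline double hinf(double V) const { return boltz(V, thh, sgh); }
  inline double ninf(double V) const { return boltz(V, thn, sgn); }
  inline double tauh(double V) const { return tauh0 + tauh1 * boltz(V, thth, sgth); }
  inline double taun(double V) const { return taun0 + taun1 * boltz(V, thtn, sgtn); }
};

struct XCond {
  double g, p, Vhx, kx, taux; bool inst;
  bool has_inact; double Vhy, ky, tauy;
  double EX;
  inline double xinf(double V) const { return boltz(V, Vhx, kx); }
  inline double yinf(double V) const { return boltz(V, Vhy, ky); }
};

struct LoopPars {
  bool on;
  double gCaL, VhCa, kCa, tauCaAct, ECa; // high-threshold Ca current, m^2 gating
  double caConv;                         // uM/ms per uA/cm^2 (shell factor / 2F)
  double Cab, tauCa;
  double vK, vP, KK, KP, nH, gsup;
  inline double minfCa(double V) const { return boltz(V, VhCa, kCa); }
  inline double RK(double Ca) const {
    double cn = std::pow(Ca, nH);
    return vK * cn / (cn + std::pow(KK, nH));
  }
  inline double RP(double Ca) const {
    double cn = std::pow(Ca, nH);
    return vP * cn / (cn + std::pow(KP, nH));
  }
};

struct State {
  double V, h, n, x, y, mca, Ca, fphi;
};

struct Deriv {
  double V, h, n, x, y, mca, Ca, fphi;
};

struct Tabs {
  VTab minf3, hinf, tauh_inv, ninf, taun_inv, xinf, yinf, minfCa;
};

static inline Deriv derivs(const State& s, double I, double ge, double gi,
                           double Ee, double Ei, double C, double gL, double EL,
                           const APModel& ap, const XCond& xc, const LoopPars& lp,
                           const Tabs& tb, int px) {
  Deriv d;
  double V = s.V;
  double INa = ap.gNa * tb.minf3(V) * s.h * (V - ap.VNa);
  double n2 = s.n * s.n;
  double IK  = ap.gK * n2 * n2 * (V - ap.VK);
  double IL  = gL * (V - EL);
  double xg  = xc.inst ? tb.xinf(V) : s.x;
  double gateprod = ipow(xg, px) * (xc.has_inact ? s.y : 1.0);
  double IX  = xc.g * gateprod * (V - xc.EX);
  double Isyn = ge * (V - Ee) + gi * (V - Ei);
  double ICa = 0.0;
  if (lp.on) ICa = lp.gCaL * s.mca * s.mca * (V - lp.ECa);
  d.V = (I - INa - IK - IL - IX - Isyn - ICa) / C;
  d.h = (tb.hinf(V) - s.h) * tb.tauh_inv(V);
  d.n = (tb.ninf(V) - s.n) * tb.taun_inv(V);
  d.x = xc.inst ? 0.0 : (tb.xinf(V) - s.x) / xc.taux;
  d.y = xc.has_inact ? (tb.yinf(V) - s.y) / xc.tauy : 0.0;
  if (lp.on) {
    d.mca = (tb.minfCa(V) - s.mca) / lp.tauCaAct;
    d.Ca = -lp.caConv * ICa - (s.Ca - lp.Cab) / lp.tauCa;
    d.fphi = lp.RK(s.Ca) * (1.0 - s.fphi) - lp.RP(s.Ca) * s.fphi;
  } else { d.mca = 0.0; d.Ca = 0.0; d.fphi = 0.0; }
  return d;
}

// [[Rcpp::export(name = ".hh_simulate_cpp")]]
List hh_simulate_cpp(List pars) {
  double dt = as<double>(pars["dt"]);
  double t_max = as<double>(pars["t_max"]);
  double settle = as<double>(pars["settle"]);
  int stop_spikes = as<int>(pars["stop_spikes"]); // counted after settle; 0 = run to t_max
  double I = as<double>(pars["I"]);
  double C = as<double>(pars["C"]);
  double gL = as<double>(pars["gL"]);
  double EL = as<double>(pars["EL"]);

  List apL = pars["ap"];
  APModel ap;
  ap.gNa = as<double>(apL["gNa"]); ap.thm = as<double>(apL["thm"]); ap.sgm = as<double>(apL["sgm"]);
  ap.thh = as<double>(apL["thh"]); ap.sgh = as<double>(apL["sgh"]);
  ap.gK = as<double>(apL["gK"]); ap.thn = as<double>(apL["thn"]); ap.sgn = as<double>(apL["sgn"]);
  ap.VNa = as<double>(apL["VNa"]); ap.VK = as<double>(apL["VK"]);
  ap.tauh0 = as<double>(apL["tauh0"]); ap.tauh1 = as<double>(apL["tauh1"]);
  ap.thth = as<double>(apL["thth"]); ap.sgth = as<double>(apL["sgth"]);
  ap.taun0 = as<double>(apL["taun0"]); ap.taun1 = as<double>(apL["taun1"]);
  ap.thtn = as<double>(apL["thtn"]); ap.sgtn = as<double>(apL["sgtn"]);

  List xL = pars["x"];
  XCond xc;
  xc.g = as<double>(xL["gmax"]); xc.p = as<double>(xL["p"]);
  xc.Vhx = as<double>(xL["Vhx"]); xc.kx = as<double>(xL["kx"]);
  xc.inst = as<bool>(xL["inst"]); xc.taux = as<double>(xL["taux"]);
  xc.has_inact = as<bool>(xL["has_inact"]);
  xc.Vhy = as<double>(xL["Vhy"]); xc.ky = as<double>(xL["ky"]); xc.tauy = as<double>(xL["tauy"]);
  xc.EX = as<double>(xL["EX"]);

  bool use_noise = as<bool>(pars["use_noise"]);
  double rateE = 0, jumpE = 0, tauE = 1, Ee = 0, rateI = 0, jumpI = 0, tauI = 1, Ei = -80;
  uint64_t seed = 1;
  if (use_noise) {
    List nz = pars["noise"];
    rateE = as<double>(nz["rateE"]); jumpE = as<double>(nz["jumpE"]);
    tauE = as<double>(nz["tauE"]); Ee = as<double>(nz["Ee"]);
    rateI = as<double>(nz["rateI"]); jumpI = as<double>(nz["jumpI"]);
    tauI = as<double>(nz["tauI"]); Ei = as<double>(nz["Ei"]);
    seed = (uint64_t) as<double>(nz["seed"]);
  }

  LoopPars lp; lp.on = as<bool>(pars["use_loop"]);
  double fphi0 = 0.0, Ca0 = 0.0;
  if (lp.on) {
    List ll = pars["loop"];
    lp.gCaL = as<double>(ll["gCaL"]); lp.VhCa = as<double>(ll["VhCa"]);
    lp.kCa = as<double>(ll["kCa"]); lp.tauCaAct = as<double>(ll["tauCaAct"]);
    lp.ECa = as<double>(ll["ECa"]); lp.caConv = as<double>(ll["caConv"]);
    lp.Cab = as<double>(ll["Cab"]); lp.tauCa = as<double>(ll["tauCa"]);
    lp.vK = as<double>(ll["vK"]); lp.vP = as<double>(ll["vP"]);
    lp.KK = as<double>(ll["KK"]); lp.KP = as<double>(ll["KP"]);
    lp.nH = as<double>(ll["nH"]); lp.gsup = as<double>(ll["gsup"]);
    fphi0 = as<double>(ll["fphi0"]); Ca0 = as<double>(ll["Ca0"]);
  }

  int record_every = as<int>(pars["record_every"]); // 0 = no trace
  double V0 = as<double>(pars["V0"]);

  Tabs tb;
  tb.minf3.build([&](double V){ double m = ap.minf(V); return m * m * m; });
  tb.hinf.build([&](double V){ return ap.hinf(V); });
  tb.tauh_inv.build([&](double V){ return 1.0 / ap.tauh(V); });
  tb.ninf.build([&](double V){ return ap.ninf(V); });
  tb.taun_inv.build([&](double V){ return 1.0 / ap.taun(V); });
  tb.xinf.build([&](double V){ return xc.xinf(V); });
  if (xc.has_inact) tb.yinf.build([&](double V){ return xc.yinf(V); });
  if (lp.on) tb.minfCa.build([&](double V){ return lp.minfCa(V); });
  int px = (int)xc.p;

  State s;
  s.V = V0;
  s.h = ap.hinf(V0); s.n = ap.ninf(V0);
  s.x = xc.xinf(V0); s.y = xc.has_inact ? xc.yinf(V0) : 1.0;
  s.mca = lp.on ? lp.minfCa(V0) : 0.0;
  s.Ca = lp.on ? Ca0 : 0.0; s.fphi = fphi0;

  std::mt19937_64 rng(seed);
  std::exponential_distribution<double> expdist(1.0);
  double ge = 0.0, gi = 0.0;
  double nextE = use_noise && rateE > 0 ? expdist(rng) / rateE : R_PosInf;
  double nextI = use_noise && rateI > 0 ? expdist(rng) / rateI : R_PosInf;
  const double decEh = std::exp(-0.5 * dt / tauE), decIh = std::exp(-0.5 * dt / tauI);
  const double decE1 = std::exp(-dt / tauE), decI1 = std::exp(-dt / tauI);

  long n_steps = (long) std::ceil(t_max / dt);
  std::vector<double> rec_t, rec_V, rec_x, rec_h, rec_n, rec_ge, rec_gi, rec_Ca, rec_f, rec_g, rec_y;
  std::vector<double> spikes, apdur;
  if (record_every > 0) {
    long cap = n_steps / record_every + 2;
    rec_t.reserve(cap); rec_V.reserve(cap);
  }

  const double V_DETECT = 0.0, V_DUR = -20.0, REFRAC = 2.0;
  double last_spike = -1e18, dur_up = NA_REAL;
  bool above_dur = false;
  double Vprev = s.V;
  bool blown = false; double blow_t = NA_REAL;
  long spike_count_meas = 0;

  double t = 0.0;
  for (long i = 0; i <= n_steps; ++i) {
    if (record_every > 0 && (i % record_every == 0)) {
      rec_t.push_back(t); rec_V.push_back(s.V); rec_x.push_back(xc.inst ? xc.xinf(s.V) : s.x);
      rec_h.push_back(s.h); rec_n.push_back(s.n);
      if (use_noise) { rec_ge.push_back(ge); rec_gi.push_back(gi); }
      if (xc.has_inact) rec_y.push_back(s.y);
      if (lp.on) { rec_Ca.push_back(s.Ca); rec_f.push_back(s.fphi); rec_g.push_back(lp.gsup * s.fphi); }
    }
    if (i == n_steps) break;

    // deliver Poisson events due in [t, t+dt)
    if (use_noise) {
      while (nextE < t + dt) { ge += jumpE; nextE += expdist(rng) / rateE; }
      while (nextI < t + dt) { gi += jumpI; nextI += expdist(rng) / rateI; }
    }

    if (lp.on) xc.g = lp.gsup * s.fphi;

    // RK4 with synaptic conductances decaying exponentially within the step
    double geh = ge * decEh, gih = gi * decIh;
    double ge1 = ge * decE1, gi1 = gi * decI1;
    Deriv k1 = derivs(s, I, ge, gi, Ee, Ei, C, gL, EL, ap, xc, lp, tb, px);
    State s2 = s;
    s2.V = s.V + 0.5 * dt * k1.V; s2.h = s.h + 0.5 * dt * k1.h; s2.n = s.n + 0.5 * dt * k1.n;
    s2.x = s.x + 0.5 * dt * k1.x; s2.y = s.y + 0.5 * dt * k1.y;
    s2.mca = s.mca + 0.5 * dt * k1.mca; s2.Ca = s.Ca + 0.5 * dt * k1.Ca; s2.fphi = s.fphi + 0.5 * dt * k1.fphi;
    Deriv k2 = derivs(s2, I, geh, gih, Ee, Ei, C, gL, EL, ap, xc, lp, tb, px);
    State s3 = s;
    s3.V = s.V + 0.5 * dt * k2.V; s3.h = s.h + 0.5 * dt * k2.h; s3.n = s.n + 0.5 * dt * k2.n;
    s3.x = s.x + 0.5 * dt * k2.x; s3.y = s.y + 0.5 * dt * k2.y;
    s3.mca = s.mca + 0.5 * dt * k2.mca; s3.Ca = s.Ca + 0.5 * dt * k2.Ca; s3.fphi = s.fphi + 0.5 * dt * k2.fphi;
    Deriv k3 = derivs(s3, I, geh, gih, Ee, Ei, C, gL, EL, ap, xc, lp, tb, px);
    State s4 = s;
    s4.V = s.V + dt * k3.V; s4.h = s.h + dt * k3.h; s4.n = s.n + dt * k3.n;
    s4.x = s.x + dt * k3.x; s4.y = s.y + dt * k3.y;
    s4.mca = s.mca + dt * k3.mca; s4.Ca = s.Ca + dt * k3.Ca; s4.fphi = s.fphi + dt * k3.fphi;
    Deriv k4 = derivs(s4, I, ge1, gi1, Ee, Ei, C, gL, EL, ap, xc, lp, tb, px);

    Vprev = s.V;
    s.V += dt / 6.0 * (k1.V + 2 * k2.V + 2 * k3.V + k4.V);
    s.h += dt / 6.0 * (k1.h + 2 * k2.h + 2 * k3.h + k4.h);
    s.n += dt / 6.0 * (k1.n + 2 * k2.n + 2 * k3.n + k4.n);
    s.x += dt / 6.0 * (k1.x + 2 * k2.x + 2 * k3.x + k4.x);
    s.y += dt / 6.0 * (k1.y + 2 * k2.y + 2 * k3.y + k4.y);
    s.mca += dt / 6.0 * (k1.mca + 2 * k2.mca + 2 * k3.mca + k4.mca);
    s.Ca += dt / 6.0 * (k1.Ca + 2 * k2.Ca + 2 * k3.Ca + k4.Ca);
    s.fphi += dt / 6.0 * (k1.fphi + 2 * k2.fphi + 2 * k3.fphi + k4.fphi);
    // enzymatic-cycle conservation and non-negative calcium
    if (s.fphi < 0) s.fphi = 0; else if (s.fphi > 1) s.fphi = 1;
    if (lp.on && s.Ca < 0) s.Ca = 0;
    ge = ge1; gi = gi1;
    t += dt;

    if (!std::isfinite(s.V)) { blown = true; blow_t = t; break; }

    // spike detection: upward crossing of 0 mV with refractory guard
    if (Vprev < V_DETECT && s.V >= V_DETECT && (t - last_spike) > REFRAC) {
      last_spike = t;
      spikes.push_back(t);
      if (t > settle) {
        ++spike_count_meas;
      }
    }
    // AP duration at the -20 mV level
    if (!above_dur && Vprev < V_DUR && s.V >= V_DUR) { above_dur = true; dur_up = t; }
    else if (above_dur && Vprev >= V_DUR && s.V < V_DUR) {
      above_dur = false;
      if (!spikes.empty() && dur_up <= last_spike && last_spike <= t) apdur.push_back(t - dur_up);
    }
    if (stop_spikes > 0 && spike_count_meas >= stop_spikes) break;
  }

  List out = List::create(
    _["spike_times"] = spikes, _["ap_durations"] = apdur,
    _["t_end"] = t, _["V_end"] = s.V, _["blown_up"] = blown, _["blow_time"] = blow_t);
  if (record_every > 0) {
    out["t"] = rec_t; out["V"] = rec_V; out["x"] = rec_x; out["h"] = rec_h; out["n"] = rec_n;
    if (use_noise) { out["ge"] = rec_ge; out["gi"] = rec_gi; }
    if (xc.has_inact) out["y"] = rec_y;
    if (lp.on) { out["Ca"] = rec_Ca; out["fphi"] = rec_f; out["gmax_eff"] = rec_g; }
  }
  return out;
}

// Reduced integrate-and-fire membrane over one inter-spike interval under an
// activation hypothesis. mode: 0 = quasi-steady x = xinf(V) (instantaneous
// activation; threshold theory trajectories), 1 = prescribed exponential
// relaxation from x0 toward x_rest (post-spike theory), 2 = first-order gate
// dx/dt = (xinf(V) - x)/tau from x0 (pre-spike theory with x0 = xinf(Vr);
// pre/post-spike theory with x0 = end-of-spike activation). Returns the ISI
// duration (ms), the end of the initial relaxation period (first time
// x <= xinf(V), mode 2), and optionally the trajectory.
// [[Rcpp::export(name = ".iaf_isi_cpp")]]
List iaf_isi_cpp(double I, double g, double p, double Vhx, double kx, double EX,
                 double taux, double C, double gL, double EL,
                 double Vr, double Vs, double x0, double x_rest,
                 int mode, double dt, double t_max, bool record) {
  double V = Vr, t = 0.0;
  std::vector<double> rt, rV, rx;
  double x = (mode == 0) ? boltz(Vr, Vhx, kx) : x0;
  double t_switch = NA_REAL;
  bool switched = (mode != 2) || (x0 <= boltz(Vr, Vhx, kx));
  if (switched && mode == 2) t_switch = 0.0;
  int pw = (int)p;
  auto dv = [&](double V_, double x_) {
    return (I - gL * (V_ - EL) - g * ipow(x_, pw) * (V_ - EX)) / C;
  };
  const double dec_h = std::exp(-0.5 * dt / taux), dec_1 = std::exp(-dt / taux);
  long nmax = (long)(t_max / dt) + 1;
  for (long i = 0; i < nmax; ++i) {
    if (record) { rt.push_back(t); rV.push_back(V); rx.push_back(mode == 0 ? boltz(V, Vhx, kx) : x); }
    double Vn, xn = x;
    if (mode == 0) {
      double xc_ = boltz(V, Vhx, kx);
      double k1 = dv(V, xc_);
      double V2 = V + 0.5 * dt * k1;
      double k2 = dv(V2, boltz(V2, Vhx, kx));
      double V3 = V + 0.5 * dt * k2;
      double k3 = dv(V3, boltz(V3, Vhx, kx));
      double V4 = V + dt * k3;
      double k4 = dv(V4, boltz(V4, Vhx, kx));
      Vn = V + dt / 6.0 * (k1 + 2 * k2 + 2 * k3 + k4);
    } else if (mode == 1) {
      double xh_ = x_rest + (x - x_rest) * dec_h;
      double x1_ = x_rest + (x - x_rest) * dec_1;
      double k1 = dv(V, x);
      double k2 = dv(V + 0.5 * dt * k1, xh_);
      double k3 = dv(V + 0.5 * dt * k2, xh_);
      double k4 = dv(V + dt * k3, x1_);
      Vn = V + dt / 6.0 * (k1 + 2 * k2 + 2 * k3 + k4);
      xn = x1_;
    } else {
      // coupled first-order gate
      double kv1 = dv(V, x);
      double kx1 = (boltz(V, Vhx, kx) - x) / taux;
      double V2 = V + 0.5 * dt * kv1, x2 = x + 0.5 * dt * kx1;
      double kv2 = dv(V2, x2);
      double kx2 = (boltz(V2, Vhx, kx) - x2) / taux;
      double V3 = V + 0.5 * dt * kv2, x3 = x + 0.5 * dt * kx2;
      double kv3 = dv(V3, x3);
      double kx3 = (boltz(V3, Vhx, kx) - x3) / taux;
      double V4 = V + dt * kv3, x4 = x + dt * kx3;
      double kv4 = dv(V4, x4);
      double kx4 = (boltz(V4, Vhx, kx) - x4) / taux;
      Vn = V + dt / 6.0 * (kv1 + 2 * kv2 + 2 * kv3 + kv4);
      xn = x + dt / 6.0 * (kx1 + 2 * kx2 + 2 * kx3 + kx4);
    }
    t += dt;
    if (mode == 2 && !switched && xn <= boltz(Vn, Vhx, kx)) {
      switched = true; t_switch = t;
    }
    if (Vn >= Vs) {
      double frac = (Vs - V) / (Vn - V); // linear interpolation of crossing
      t = t - dt + frac * dt;
      return List::create(_["T"] = t, _["reached"] = true, _["t_switch"] = t_switch,
                          _["t"] = rt, _["V"] = rV, _["x"] = rx);
    }
    V = Vn; x = xn;
  }
  return List::create(_["T"] = NA_REAL, _["reached"] = false, _["t_switch"] = t_switch,
                      _["t"] = rt, _["V"] = rV, _["x"] = rx);
}
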