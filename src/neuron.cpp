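// Fixed-step integrator for a single-compartment pacemaking dopamine neuron.
//
// Conventions (package-wide): mV, ms, pA, nS, pF, uM.  Every membrane current
// is written I = g * gates * (E - V), i.e. positive values depolarize, and
// dV/dt = (sum(I) + I_inj) / C.  Gates relax first-order toward their
// voltage-dependent steady state (exponential Euler); V is advanced by a
// forward update at fixed dt.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Boltz {
  double vhalf, vslope;
  double ss(double v) const { return 1.0 / (1.0 + std::exp((vhalf - v) / vslope)); }
};

struct TauSig {
  double vhalf, vslope, tmin, tmax;
  double tau(double v) const {
    return tmin + (tmax - tmin) / (1.0 + std::exp((vhalf - v) / vslope));
  }
};

struct Gate {
  Boltz ss;
  TauSig tau;
};

static Gate gate_from(List g) {
  Gate out;
  out.ss.vhalf = as<double>(g["vhalf"]);
  out.ss.vslope = as<double>(g["vslope"]);
  out.tau.vhalf = as<double>(g["tau_vhalf"]);
  out.tau.vslope = as<double>(g["tau_vslope"]);
  out.tau.tmin = as<double>(g["tau_min"]);
  out.tau.tmax = as<double>(g["tau_max"]);
  return out;
}

// exponential Euler update
static inline double relax(double x, double xinf, double tau, double dt) {
  return xinf + (x - xinf) * std::exp(-dt / tau);
}

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// Biexponential conductance (difference of exponentials), peak-normalized so
// that a unit-weight event reaches a maximum conductance of exactly 1 nS.
struct BiExp {
  double tau_rise, tau_decay, norm;
  double a = 0.0, b = 0.0; // g = a - b
  double fa, fb;
  void init(double tr, double td, double dt) {
    tau_rise = tr;
    tau_decay = td;
    double tp = std::log(td / tr) * tr * td / (td - tr);
    norm = 1.0 / (std::exp(-tp / td) - std::exp(-tp / tr));
    fa = std::exp(-dt / td);
    fb = std::exp(-dt / tr);
  }
  void step() { a *= fa; b *= fb; }
  void event(double w) { a += w * norm; b += w * norm; }
  double g() const { return a - b; }
};

// [[Rcpp::export]]
List sim_neuron_cpp(List pars, double duration, double dt,
                    NumericVector init_state,
                    NumericMatrix step_currents, // columns: t_on, t_off, amp (pA)
                    List synapses, double spike_threshold,
                    bool record_trace, int record_stride) {
  if (dt <= 0 || duration < dt) stop("invalid duration/dt");

  const double cm = as<double>(pars["cm"]);
  const double g_leak = as<double>(pars["g_leak"]), e_leak = as<double>(pars["e_leak"]);
  const double g_na = as<double>(pars["g_na"]), e_na = as<double>(pars["e_na"]);
  const double g_kdr = as<double>(pars["g_kdr"]), e_k = as<double>(pars["e_k"]);
  const double g_cal = as<double>(pars["g_cal"]), e_ca = as<double>(pars["e_ca"]);
  const double g_sk = as<double>(pars["g_sk"]), ks_sk = as<double>(pars["ks_sk"]);
  const double g_hcn = as<double>(pars["g_hcn"]), e_hcn = as<double>(pars["e_hcn"]);
  const double ca_rest = as<double>(pars["ca_rest"]);
  const double ca_tau = as<double>(pars["ca_tau"]);
  const double ca_in = as<double>(pars["ca_in"]); // uM per pA*ms of L-type current

  Gate gm = gate_from(pars["na_m"]);
  Gate gh = gate_from(pars["na_h"]);
  Gate gn = gate_from(pars["kdr_n"]);
  Gate ga = gate_from(pars["cal_a"]);
  Gate ghc = gate_from(pars["hcn_h"]);

  // Kv4.3: I = g_max p^3 (f_s q_s + (1 - f_s) q_f) (E_K - V)
  List kv4 = pars["kv4"];
  const double g_kv4 = as<double>(kv4["g_max"]);
  const double f_s = as<double>(kv4["f_s"]);
  const double e_k_kv4 = as<double>(kv4["e_k"]);
  Boltz kv4_act, kv4_inact;
  kv4_act.vhalf = as<double>(as<List>(kv4["activation"])["vhalf"]);
  kv4_act.vslope = as<double>(as<List>(kv4["activation"])["vslope"]);
  kv4_inact.vhalf = as<double>(as<List>(kv4["inactivation"])["vhalf"]);
  kv4_inact.vslope = as<double>(as<List>(kv4["inactivation"])["vslope"]);
  TauSig tau_s, tau_f, tau_p;
  List ts = kv4["tau_slow"], tf = kv4["tau_fast"], tp = kv4["activation_tau"];
  tau_s.vhalf = as<double>(ts["vhalf"]); tau_s.vslope = as<double>(ts["vslope"]);
  tau_s.tmin = as<double>(ts["tau_min"]); tau_s.tmax = as<double>(ts["tau_max"]);
  tau_f.vhalf = as<double>(tf["vhalf"]); tau_f.vslope = as<double>(tf["vslope"]);
  tau_f.tmin = as<double>(tf["tau_min"]); tau_f.tmax = as<double>(tf["tau_max"]);
  tau_p.vhalf = as<double>(tp["vhalf"]); tau_p.vslope = as<double>(tp["vslope"]);
  tau_p.tmin = as<double>(tp["tau_min"]); tau_p.tmax = as<double>(tp["tau_max"]);

  // state: V, m, h, n, a, hc, p, qs, qf, Ca
  if (init_state.size() != 10) stop("init_state must have 10 elements");
  double V = init_state[0], m = init_state[1], h = init_state[2], n = init_state[3],
         a = init_state[4], hc = init_state[5], p = init_state[6], qs = init_state[7],
         qf = init_state[8], Ca = init_state[9];

  const int nstep = (int)std::floor(duration / dt + 0.5);

  // synaptic event streams (times sorted ascending, weights in nS peak)
  List syn_ampa = synapses["ampa"], syn_nmda = synapses["nmda"], syn_gaba = synapses["gaba"];
  NumericVector t_ampa = syn_ampa["t"], w_ampa = syn_ampa["w"];
  NumericVector t_nmda = syn_nmda["t"], w_nmda = syn_nmda["w"];
  NumericVector t_gaba = syn_gaba["t"], w_gaba = syn_gaba["w"];
  List kin = pars["syn_kinetics"];
  BiExp ampa, nmda, gaba;
  ampa.init(as<double>(kin["ampa_rise"]), as<double>(kin["ampa_decay"]), dt);
  nmda.init(as<double>(kin["nmda_rise"]), as<double>(kin["nmda_decay"]), dt);
  gaba.init(as<double>(kin["gaba_rise"]), as<double>(kin["gaba_decay"]), dt);
  const double e_glut = as<double>(kin["e_glut"]);
  const double e_gaba = as<double>(kin["e_gaba"]);
  const double mg = as<double>(kin["mg_mM"]);
  int i_ampa = 0, i_nmda = 0, i_gaba = 0;

  const int nrec = record_trace ? (nstep / record_stride + 1) : 0;
  NumericVector out_t(nrec), out_v(nrec), out_i(nrec);
  std::vector<double> spikes;
  double v_min = V;
  int irec = 0;
  bool above = V > spike_threshold;

  const int nsc = step_currents.nrow();

  for (int k = 0; k < nstep; ++k) {
    double t = k * dt;

    // injected current
    double i_inj = 0.0;
    for (int s = 0; s < nsc; ++s) {
      if (t >= step_currents(s, 0) && t < step_currents(s, 1)) i_inj += step_currents(s, 2);
    }

    // synaptic events due within [t, t+dt)
    while (i_ampa < t_ampa.size() && t_ampa[i_ampa] < t + dt) ampa.event(w_ampa[i_ampa++]);
    while (i_nmda < t_nmda.size() && t_nmda[i_nmda] < t + dt) nmda.event(w_nmda[i_nmda++]);
    while (i_gaba < t_gaba.size() && t_gaba[i_gaba] < t + dt) gaba.event(w_gaba[i_gaba++]);

    if (record_trace && (k % record_stride == 0)) {
      out_t[irec] = t; out_v[irec] = V; out_i[irec] = i_inj; ++irec;
    }

    // currents at current state
    double i_leak = g_leak * (e_leak - V);
    double i_na = g_na * m * m * m * h * (e_na - V);
    double i_kdr = g_kdr * n * n * n * n * (e_k - V);
    double i_cal = g_cal * a * a * (e_ca - V);
    double ca2 = Ca * Ca, ks2 = ks_sk * ks_sk;
    double zca = ca2 * ca2 / (ca2 * ca2 + ks2 * ks2); // Hill coefficient 4
    double i_sk = g_sk * zca * (e_k - V);
    double i_hcn = g_hcn * hc * (e_hcn - V);
    double mix = f_s * qs + (1.0 - f_s) * qf;
    double i_kv4 = g_kv4 * p * p * p * mix * (e_k_kv4 - V);
    double mgblock = 1.0 / (1.0 + (mg / 3.57) * std::exp(-0.062 * V));
    double i_syn = ampa.g() * (e_glut - V) + nmda.g() * mgblock * (e_glut - V) +
                   gaba.g() * (e_gaba - V);

    double dv = (i_leak + i_na + i_kdr + i_cal + i_sk + i_hcn + i_kv4 + i_syn + i_inj) / cm;
    double V_new = V + dt * dv;

    // gates relax against the pre-step voltage
    m = relax(m, gm.ss.ss(V), gm.tau.tau(V), dt);
    h = relax(h, gh.ss.ss(V), gh.tau.tau(V), dt);
    n = relax(n, gn.ss.ss(V), gn.tau.tau(V), dt);
    a = relax(a, ga.ss.ss(V), ga.tau.tau(V), dt);
    hc = relax(hc, ghc.ss.ss(V), ghc.tau.tau(V), dt);
    p = clamp01(relax(p, kv4_act.ss(V), tau_p.tau(V), dt));
    qs = clamp01(relax(qs, kv4_inact.ss(V), tau_s.tau(V), dt));
    qf = clamp01(relax(qf, kv4_inact.ss(V), tau_f.tau(V), dt));
    Ca += dt * (ca_in * std::max(i_cal, 0.0) - (Ca - ca_rest) / ca_tau);
    if (Ca < 0.0) Ca = 0.0;

    ampa.step(); nmda.step(); gaba.step();

    if (!R_finite(V_new) || std::fabs(V_new) > 200.0) {
      stop("integration failure at t = %f ms (V = %f)", t, V_new);
    }

    // strict upward crossing of the spike threshold
    if (!above && V_new > spike_threshold && V <= spike_threshold) {
      double frac = (spike_threshold - V) / (V_new - V);
      spikes.push_back(t + frac * dt);
    }
    above = V_new > spike_threshold;
    if (V_new < v_min) v_min = V_new;
    V = V_new;
  }

  NumericVector final_state = NumericVector::create(V, m, h, n, a, hc, p, qs, qf, Ca);
  final_state.names() = CharacterVector::create("v", "m", "h", "n", "a", "hc",
                                                "p", "qs", "qf", "ca");
  List out = List::create(
    _["spikes"] = wrap(spikes),
    _["v_min"] = v_min,
    _["final_state"] = final_state,
    _["duration"] = nstep * dt);
  if (record_trace) {
    out["time"] = out_t[Range(0, irec - 1)];
    out["v"] = out_v[Range(0, irec - 1)];
    out["i_inj"] = out_i[Range(0, irec - 1)];
  }
  return out;
}
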