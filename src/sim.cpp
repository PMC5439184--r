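// Simulation core: leaky integrate-and-fire reservoir with NMDAR
// calcium-controlled plasticity, plus a single-synapse engine used by the
// tetanus / pairing / calcium-response protocols.
//
// Units: time s (waveform constants converted from ms on the R side),
// membrane potential mV, currents A (weights are peak synaptic currents,
// CSIM convention), calcium uM.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Plast {
  double epsp_scale;              // mV per A of synaptic weight
  double bpap_max;                // mV
  double tfb, ifb, tsb, isb;      // BPAP fast/slow
  double tfe, ife, tse, ise;      // EPSP fast/slow
  double gain;                    // NMDA gain, uM/s per (trace*H)
  double nif, nis, ntf, nts;      // NMDA current fractions / time constants
  double p_w, w_ref;              // conductance-weight coupling exponent
  double mg, v_rev, v_shift;      // Mg block / Ca reversal (mV)
  bool   h_product;               // literal product reading of the block term
  double tau_ca;
  double a1, a2, b1, b2, orate;   // Omega
  double kappa;                   // Omega -> weight scale
  double e1, e2, e3, e4;          // eta(Ca) = esc/(e1/(e2+Ca^e3)+e4)
  double esc;                     // global eta scale (learning timescale)
  double ncap;                    // saturation of the summed NMDA activation
  double bu, btau;                // BPAP attenuation: per-spike use fraction,
                                  // recovery time constant (s)
  double w_min, w_max;
  int    trace_mode;              // 0 restart, 1 summation
  bool   no_bpap;
  // pair-based STDP variant
  double A_plus, A_minus, tau_plus, tau_minus;
};

Plast read_plast(const List& p) {
  Plast q;
  q.epsp_scale = as<double>(p["epsp_scale"]);
  q.bpap_max = as<double>(p["bpap_max"]);
  q.tfb = as<double>(p["tau_f_bpap"]); q.ifb = as<double>(p["i_f_bpap"]);
  q.tsb = as<double>(p["tau_s_bpap"]); q.isb = as<double>(p["i_s_bpap"]);
  q.tfe = as<double>(p["tau_f_epsp"]); q.ife = as<double>(p["i_f_epsp"]);
  q.tse = as<double>(p["tau_s_epsp"]); q.ise = as<double>(p["i_s_epsp"]);
  q.gain = as<double>(p["nmda_gain"]);
  q.nif = as<double>(p["nmda_i_f"]); q.nis = as<double>(p["nmda_i_s"]);
  q.ntf = as<double>(p["nmda_tau_f"]); q.nts = as<double>(p["nmda_tau_s"]);
  q.p_w = as<double>(p["p_w"]); q.w_ref = as<double>(p["w_ref"]);
  q.mg = as<double>(p["mg"]); q.v_rev = as<double>(p["v_reversal_ca"]);
  q.v_shift = as<double>(p["v_shift"]);
  q.h_product = as<bool>(p["h_product"]);
  q.tau_ca = as<double>(p["tau_ca"]);
  q.a1 = as<double>(p["alpha1"]); q.a2 = as<double>(p["alpha2"]);
  q.b1 = as<double>(p["beta1"]); q.b2 = as<double>(p["beta2"]);
  q.orate = as<double>(p["omega_rate"]);
  q.kappa = as<double>(p["omega_to_weight_scale"]);
  q.e1 = as<double>(p["eta_p1"]); q.e2 = as<double>(p["eta_p2"]);
  q.e3 = as<double>(p["eta_p3"]); q.e4 = as<double>(p["eta_p4"]);
  q.esc = as<double>(p["eta_scale"]);
  q.ncap = as<double>(p["nmda_trace_cap"]);
  q.bu = as<double>(p["bpap_u"]); q.btau = as<double>(p["bpap_tau_rec"]);
  q.w_min = as<double>(p["weight_min"]); q.w_max = as<double>(p["weight_max"]);
  q.trace_mode = as<int>(p["trace_mode"]);
  q.no_bpap = as<bool>(p["no_bpap"]);
  q.A_plus = as<double>(p["stdp_a_plus"]); q.A_minus = as<double>(p["stdp_a_minus"]);
  q.tau_plus = as<double>(p["stdp_tau_plus"]); q.tau_minus = as<double>(p["stdp_tau_minus"]);
  return q;
}

inline double sig(double x) { return 1.0 / (1.0 + std::exp(-x)); }

inline double h_of_v(double v, const Plast& q) {
  double num = -0.42 * (v - q.v_rev);
  double blk = 1.0 + 0.6 * std::exp(-0.09 * (v - q.v_shift)) * q.mg / 3.57;
  return q.h_product ? num * blk : num / blk;
}

inline double omega_of_ca(double ca, const Plast& q) {
  return sig((ca - q.a2) * q.b2) - q.orate * sig((ca - q.a1) * q.b1);
}

inline double eta_of_ca(double ca, const Plast& q) {
  return q.esc / (q.e1 / (q.e2 + std::pow(ca, q.e3)) + q.e4);
}

// Lookup tables (built per simulation; linear interpolation).
struct Tables {
  std::vector<double> h;   double v0, dv; int nh;
  std::vector<double> om;  // omega over ca grid
  std::vector<double> et;  // eta over ca grid
  double c0, dc; int nc;
  std::vector<double> gw;  // (w/w_ref)^p_w over weight grid
  double w0, dw; int nw;

  void build(const Plast& q) {
    v0 = -300.0; dv = 0.1; nh = 7001;          // -300 .. 400 mV
    h.resize(nh);
    for (int i = 0; i < nh; ++i) h[i] = h_of_v(v0 + i * dv, q);
    c0 = 0.0; dc = 0.001; nc = 6001;           // 0 .. 6 uM
    om.resize(nc); et.resize(nc);
    for (int i = 0; i < nc; ++i) {
      double ca = c0 + i * dc;
      om[i] = omega_of_ca(ca, q);
      et[i] = eta_of_ca(ca, q);
    }
    w0 = 0.0; dw = 1e-10; nw = 1001;           // 0 .. 1e-7 A
    gw.resize(nw);
    for (int i = 0; i < nw; ++i)
      gw[i] = (q.p_w == 0.0) ? 1.0 : std::pow((w0 + i * dw) / q.w_ref, q.p_w);
  }
  inline double H(double v) const {
    double x = (v - v0) / dv;
    if (x <= 0) return h[0];
    if (x >= nh - 1) return h[nh - 1];
    int i = (int)x; double f = x - i;
    return h[i] + f * (h[i + 1] - h[i]);
  }
  inline double OM(double ca) const {
    double x = (ca - c0) / dc;
    if (x <= 0) return om[0];
    if (x >= nc - 1) return om[nc - 1];
    int i = (int)x; double f = x - i;
    return om[i] + f * (om[i + 1] - om[i]);
  }
  inline double ET(double ca) const {
    double x = (ca - c0) / dc;
    if (x <= 0) return et[0];
    if (x >= nc - 1) return et[nc - 1];
    int i = (int)x; double f = x - i;
    return et[i] + f * (et[i + 1] - et[i]);
  }
  inline double GW(double w) const {
    double x = (w - w0) / dw;
    if (x <= 0) return gw[0];
    if (x >= nw - 1) return gw[nw - 1];
    int i = (int)x; double f = x - i;
    return gw[i] + f * (gw[i + 1] - gw[i]);
  }
};

} // namespace

// Exact H / Omega / eta evaluators exposed for the R-level operations.
// [[Rcpp::export]]
NumericVector cpp_driving_force(NumericVector v, double mg, double v_rev,
                                double v_shift, bool h_product) {
  Plast q; q.mg = mg; q.v_rev = v_rev; q.v_shift = v_shift; q.h_product = h_product;
  NumericVector out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = h_of_v(v[i], q);
  return out;
}

// Distance-dependent Bernoulli sampling of directed reservoir connections.
// cbase is c(EE, EI, IE, II) read as (pre type, post type).
// [[Rcpp::export]]
List cpp_sample_connections(NumericMatrix pos, LogicalVector is_exc,
                            double lambda, double cscale, NumericVector cbase) {
  int n = pos.nrow();
  std::vector<int> pre, post;
  bool inf_lambda = !R_finite(lambda);
  double il2 = inf_lambda ? 0.0 : 1.0 / (lambda * lambda);
  // beyond this squared distance P < ~1e-13: skip without consuming RNG
  double d2max = inf_lambda ? R_PosInf : 30.0 * lambda * lambda;
  for (int a = 0; a < n; ++a) {
    double ax = pos(a, 0), ay = pos(a, 1), az = pos(a, 2);
    bool ea = is_exc[a];
    for (int b = 0; b < n; ++b) {
      if (a == b) continue;
      double dx = ax - pos(b, 0), dy = ay - pos(b, 1), dz = az - pos(b, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > d2max) continue;
      bool eb = is_exc[b];
      double c = ea ? (eb ? cbase[0] : cbase[1]) : (eb ? cbase[2] : cbase[3]);
      double p = c * cscale * (inf_lambda ? 1.0 : std::exp(-d2 * il2));
      if (p > 0 && unif_rand() < p) { pre.push_back(a + 1); post.push_back(b + 1); }
    }
  }
  return List::create(_["pre"] = wrap(pre), _["post"] = wrap(post));
}

// Expected directed degree per neuron (sum of connection probabilities),
// used for Bernoulli-expectation checks without sampling.
// [[Rcpp::export]]
List cpp_expected_degree(NumericMatrix pos, LogicalVector is_exc,
                         double lambda, double cscale, NumericVector cbase) {
  int n = pos.nrow();
  NumericVector outdeg(n);
  double tot = 0.0, var = 0.0;
  bool inf_lambda = !R_finite(lambda);
  double il2 = inf_lambda ? 0.0 : 1.0 / (lambda * lambda);
  for (int a = 0; a < n; ++a) {
    bool ea = is_exc[a];
    double s = 0.0;
    for (int b = 0; b < n; ++b) {
      if (a == b) continue;
      double dx = pos(a,0)-pos(b,0), dy = pos(a,1)-pos(b,1), dz = pos(a,2)-pos(b,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      bool eb = is_exc[b];
      double c = ea ? (eb ? cbase[0] : cbase[1]) : (eb ? cbase[2] : cbase[3]);
      double p = c * cscale * (inf_lambda ? 1.0 : std::exp(-d2 * il2));
      if (p > 1) p = 1;
      s += p; var += p * (1 - p);
    }
    outdeg[a] = s; tot += s;
  }
  return List::create(_["expected_outdegree"] = outdeg,
                      _["expected_total"] = tot,
                      _["sd_total"] = std::sqrt(var));
}

// Full reservoir simulation.
//
// syn_*: reservoir synapse table (pre/post 1-based). in_*: input projection
// (channel/post 1-based). ev_*: input spike events sorted by time.
// Plasticity variants: 0 off, 1 full NMDAR, 2 NMDAR without BPAPs,
// 3 pair-based STDP.
// Spike transmission is delayed by one timestep; membrane update is
// exponential-Euler with the synaptic current held constant over the step.
// [[Rcpp::export]]
List cpp_simulate_network(IntegerVector syn_pre, IntegerVector syn_post,
                          NumericVector syn_w0, LogicalVector syn_plastic,
                          LogicalVector is_exc,
                          IntegerVector in_ch, IntegerVector in_post,
                          NumericVector in_w, int n_channels,
                          NumericVector ev_time, IntegerVector ev_ch,
                          double duration, double dt,
                          int variant, double noise_sd_nA,
                          List neuron, List plast,
                          NumericVector ca0) {
  const int N = is_exc.size();
  const int M = syn_pre.size();
  const int Mi = in_ch.size();
  const Plast q = read_plast(plast);
  Tables tab; tab.build(q);

  const double tau_m = as<double>(neuron["tau_m"]);
  const double v_rest = as<double>(neuron["v_resting"]);
  const double r_m = as<double>(neuron["r_m"]);            // MOhm
  const double i_inject = as<double>(neuron["i_inject"]);  // nA
  const double v_thresh = as<double>(neuron["v_thresh"]);
  const double refr_e = as<double>(neuron["refractory_e"]);
  const double refr_i = as<double>(neuron["refractory_i"]);
  const double tau_syn = as<double>(neuron["tau_syn"]);
  const double tau_syn_i = as<double>(neuron["tau_syn_i"]);

  const int S = (int)std::round(duration / dt);
  const double dsyn = std::exp(-dt / tau_syn);
  const double dsyn_i = std::exp(-dt / tau_syn_i);
  const double em = std::exp(-dt / tau_m);
  const double dfe = std::exp(-dt / q.tfe), dse = std::exp(-dt / q.tse);
  const double dfb = std::exp(-dt / q.tfb), dsb = std::exp(-dt / q.tsb);
  const double dfn = std::exp(-dt / q.ntf), dsn = std::exp(-dt / q.nts);
  const double dca1 = std::exp(-dt / q.tau_ca);
  const int refr_steps_e = (int)std::round(refr_e / dt);
  const int refr_steps_i = (int)std::round(refr_i / dt);
  const double ca_gate = 0.02;
  const int act_steps = (int)std::round(8.0 * q.nts / dt);

  // CSR of reservoir synapses by presynaptic neuron
  std::vector<int> deg(N, 0);
  for (int m = 0; m < M; ++m) deg[syn_pre[m] - 1]++;
  std::vector<int> start(N + 1, 0);
  for (int i = 0; i < N; ++i) start[i + 1] = start[i] + deg[i];
  std::vector<int> order(M);
  { std::vector<int> fill(start.begin(), start.end() - 1);
    for (int m = 0; m < M; ++m) order[fill[syn_pre[m] - 1]++] = m; }
  // CSC by postsynaptic neuron (pair-based STDP needs in-synapses)
  std::vector<int> cstart, corder;
  if (variant == 3) {
    std::vector<int> ideg(N, 0);
    for (int m = 0; m < M; ++m) ideg[syn_post[m] - 1]++;
    cstart.assign(N + 1, 0);
    for (int i = 0; i < N; ++i) cstart[i + 1] = cstart[i] + ideg[i];
    corder.resize(M);
    std::vector<int> fill(cstart.begin(), cstart.end() - 1);
    for (int m = 0; m < M; ++m) corder[fill[syn_post[m] - 1]++] = m;
  }
  // CSR of input synapses by channel
  std::vector<int> istart(n_channels + 1, 0), iorder(Mi);
  { std::vector<int> ideg(n_channels, 0);
    for (int m = 0; m < Mi; ++m) ideg[in_ch[m] - 1]++;
    for (int c = 0; c < n_channels; ++c) istart[c + 1] = istart[c] + ideg[c];
    std::vector<int> fill(istart.begin(), istart.end() - 1);
    for (int m = 0; m < Mi; ++m) iorder[fill[in_ch[m] - 1]++] = m; }

  std::vector<double> w(syn_w0.begin(), syn_w0.end());
  std::vector<double> ca(M, 0.0);
  if (ca0.size() == M) for (int m = 0; m < M; ++m) ca[m] = ca0[m];

  std::vector<double> V(N), isyn(N, 0.0), pend(N, 0.0);
  std::vector<double> isyn_i(N, 0.0), pend_i(N, 0.0);   // inhibitory currents
  std::vector<int> refr(N, 0);
  std::vector<double> epsp_f(N, 0.0), epsp_s(N, 0.0);
  std::vector<double> nmda_f(N, 0.0), nmda_s(N, 0.0);
  std::vector<double> bpap_f(N, 0.0), bpap_s(N, 0.0);
  std::vector<double> bpap_eff(N, 1.0);   // attenuation of repetitive BPAPs
  std::vector<double> last_spike(N, -1e9);
  std::vector<int> last_pre_step(N, -1000000000);
  std::vector<int> last_proc(N, -1);
  std::vector<double> group_camax(N, 0.0);
  for (int i = 0; i < N; ++i) V[i] = v_rest + (unif_rand() * 2.0 - 1.0);

  std::vector<int> spk_id; std::vector<double> spk_t;
  std::vector<int> spiked; spiked.reserve(256);

  const bool plast_on = variant == 1 || variant == 2;
  const bool stdp_on = variant == 3;
  const bool use_bpap = (variant == 1) && !q.no_bpap;
  const double dt_ms_conv = 1.0; // calcium ODE kept in seconds throughout

  int ev = 0; const int nev = ev_time.size();

  double* p_isyn = isyn.data(); double* p_isyn_i = isyn_i.data();
  double* p_pend = pend.data(); double* p_pend_i = pend_i.data();
  double* p_V = V.data(); int* p_refr = refr.data();
  const double brec = 1.0 - std::exp(-dt / q.btau);
  const double base_nA = i_inject;

  for (int s = 0; s < S; ++s) {
    double t = s * dt;
    // decay plasticity traces; BPAP efficacy recovers toward 1
    if (plast_on) {
      for (int i = 0; i < N; ++i) {
        epsp_f[i] *= dfe; epsp_s[i] *= dse;
        nmda_f[i] *= dfn; nmda_s[i] *= dsn;
        bpap_f[i] *= dfb; bpap_s[i] *= dsb;
        bpap_eff[i] += (1.0 - bpap_eff[i]) * brec;
      }
    }
    // fused pass: synaptic-current decay + arrivals scheduled last step,
    // exponential-Euler membrane update, threshold detection
    spiked.clear();
    for (int i = 0; i < N; ++i) {
      double ie = p_isyn[i] * dsyn + p_pend[i]; p_pend[i] = 0.0;
      double ii = p_isyn_i[i] * dsyn_i + p_pend_i[i]; p_pend_i[i] = 0.0;
      p_isyn[i] = ie; p_isyn_i[i] = ii;
      if (p_refr[i] > 0) { --p_refr[i]; continue; }
      double inoise = (noise_sd_nA > 0) ? norm_rand() * noise_sd_nA : 0.0;
      double vinf = v_rest + r_m * ((ie + ii) * 1e9 + base_nA + inoise);
      double v = vinf + (p_V[i] - vinf) * em;
      if (v >= v_thresh) {
        spk_id.push_back(i + 1); spk_t.push_back(t + dt);
        v = v_rest + (unif_rand() * 2.0 - 1.0);
        p_refr[i] = is_exc[i] ? refr_steps_e : refr_steps_i;
        spiked.push_back(i);
      }
      p_V[i] = v;
    }
    // input events in [t, t+dt) take effect next step
    while (ev < nev && ev_time[ev] < t + dt) {
      int c = ev_ch[ev] - 1;
      for (int k = istart[c]; k < istart[c + 1]; ++k) {
        int m = iorder[k];
        p_pend[in_post[m] - 1] += in_w[m];
      }
      ++ev;
    }
    // 4. spike effects: schedule currents, restart traces, STDP pair updates
    for (size_t k = 0; k < spiked.size(); ++k) {
      int j = spiked[k];
      bool inh = !is_exc[j];
      for (int m0 = start[j]; m0 < start[j + 1]; ++m0) {
        int m = order[m0];
        if (inh) pend_i[syn_post[m] - 1] += w[m];
        else pend[syn_post[m] - 1] += w[m];
        if (stdp_on && syn_plastic[m]) {
          // pre fires: depress by time since last post spike
          double dtp = (t + dt) - last_spike[syn_post[m] - 1];
          if (dtp < 1e8) {
            w[m] -= q.A_minus * std::exp(-dtp / q.tau_minus);
            if (w[m] < q.w_min) w[m] = q.w_min;
          }
        }
      }
      if (stdp_on) {
        // post fires: potentiate in-synapses by time since last pre spike
        for (int m0 = cstart[j]; m0 < cstart[j + 1]; ++m0) {
          int m = corder[m0];
          if (!syn_plastic[m]) continue;
          double dtp = (t + dt) - last_spike[syn_pre[m] - 1];
          if (dtp < 1e8) {
            w[m] += q.A_plus * std::exp(-dtp / q.tau_plus);
            if (w[m] > q.w_max) w[m] = q.w_max;
          }
        }
        last_spike[j] = t + dt;
      }
      if (plast_on) {
        if (is_exc[j]) {
          if (q.trace_mode == 1) {
            epsp_f[j] += q.ife; epsp_s[j] += q.ise;
            nmda_f[j] += q.nif; nmda_s[j] += q.nis;
          } else {
            epsp_f[j] = q.ife; epsp_s[j] = q.ise;
            nmda_f[j] = q.nif; nmda_s[j] = q.nis;
          }
          last_pre_step[j] = s;
        }
        // BPAP restarts on every somatic spike, attenuated by recent firing
        bpap_f[j] = q.ifb * bpap_eff[j]; bpap_s[j] = q.isb * bpap_eff[j];
        bpap_eff[j] *= (1.0 - q.bu);
      }
    }
    // 5. calcium + weight updates for active presynaptic groups
    if (plast_on) {
      for (int j = 0; j < N; ++j) {
        if (!is_exc[j]) continue;
        if (start[j + 1] == start[j]) continue;
        bool active = (s - last_pre_step[j] <= act_steps) || (group_camax[j] > ca_gate);
        if (!active) continue;
        int gap = s - last_proc[j];
        double catchup = (gap > 1) ? std::pow(dca1, gap - 1) : 1.0;
        last_proc[j] = s;
        double ntr = nmda_f[j] + nmda_s[j];
        if (ntr > q.ncap) ntr = q.ncap;
        double etr = (epsp_f[j] + epsp_s[j]) * q.epsp_scale;
        double cmax = 0.0;
        for (int m0 = start[j]; m0 < start[j + 1]; ++m0) {
          int m = order[m0];
          if (!syn_plastic[m]) continue;
          double c = ca[m] * catchup;
          int post = syn_post[m] - 1;
          double vsyn = w[m] * etr +
            (use_bpap ? q.bpap_max * (bpap_f[post] + bpap_s[post]) : 0.0);
          double inmda = q.gain * tab.GW(w[m]) * ntr * tab.H(vsyn);
          c += dt * (inmda * dt_ms_conv - c / q.tau_ca);
          if (c < 0) c = 0;
          ca[m] = c;
          if (c > cmax) cmax = c;
          double wn = w[m] + dt * tab.ET(c) * (q.kappa * tab.OM(c) - w[m]);
          if (wn < q.w_min) wn = q.w_min;
          if (wn > q.w_max) wn = q.w_max;
          w[m] = wn;
        }
        group_camax[j] = cmax;
      }
    }
    if ((s & 16383) == 0) Rcpp::checkUserInterrupt();
  }
  // settle calcium decay for groups skipped near the end
  if (plast_on) {
    for (int j = 0; j < N; ++j) {
      if (!is_exc[j] || last_proc[j] < 0) continue;
      int gap = (S - 1) - last_proc[j];
      if (gap > 0) {
        double f = std::pow(dca1, gap);
        for (int m0 = start[j]; m0 < start[j + 1]; ++m0) {
          int m = order[m0];
          if (syn_plastic[m]) ca[m] *= f;
        }
      }
    }
  }
  return List::create(_["spike_neuron"] = wrap(spk_id),
                      _["spike_time"] = wrap(spk_t),
                      _["weights"] = wrap(w),
                      _["calcium"] = wrap(ca));
}

// Single NMDAR synapse between a driven presynaptic terminal and a
// postsynaptic neuron whose firing is controlled externally (dual-patch /
// tetanus setting). Presynaptic spikes at pre_t; postsynaptic action
// potentials (BPAPs) forced at post_t. The postsynaptic membrane is
// integrated without a firing threshold so EPSP amplitudes can be probed.
// variant: 0 plasticity off, 1 full, 2 no BPAP, 3 pair-based STDP.
// [[Rcpp::export]]
List cpp_simulate_synapse(NumericVector pre_t, NumericVector post_t,
                          double w0, double duration, double dt,
                          int variant, List neuron, List plast,
                          int record_every) {
  const Plast q = read_plast(plast);
  Tables tab; tab.build(q);
  const double tau_m = as<double>(neuron["tau_m"]);
  const double v_rest = as<double>(neuron["v_resting"]);
  const double r_m = as<double>(neuron["r_m"]);
  const double tau_syn = as<double>(neuron["tau_syn"]);

  const int S = (int)std::round(duration / dt);
  const double dsyn = std::exp(-dt / tau_syn);
  const double em = std::exp(-dt / tau_m);
  const double dfe = std::exp(-dt / q.tfe), dse = std::exp(-dt / q.tse);
  const double dfb = std::exp(-dt / q.tfb), dsb = std::exp(-dt / q.tsb);
  const double dfn = std::exp(-dt / q.ntf), dsn = std::exp(-dt / q.nts);

  double w = w0, ca = 0.0;
  double epsp_f = 0, epsp_s = 0, nmda_f = 0, nmda_s = 0, bpap_f = 0, bpap_s = 0;
  double bpap_eff = 1.0;
  double V = v_rest, isyn = 0.0, pend = 0.0;
  double last_pre = -1e9, last_post = -1e9;
  // variant 0 keeps the calcium machinery running but freezes the weight
  // (the readout convention for calcium-response measurements)
  const bool use_bpap = (variant != 2) && !q.no_bpap;
  const bool ca_on = variant <= 2;
  const bool plast_on = variant == 1 || variant == 2;
  const bool stdp_on = variant == 3;

  int np = pre_t.size(), nq = post_t.size();
  int ip = 0, iq = 0;
  int nrec = S / record_every + 1;
  NumericVector rt(nrec), rca(nrec), rw(nrec), rv(nrec);
  int ir = 0;

  for (int s = 0; s < S; ++s) {
    double t = s * dt;
    isyn = isyn * dsyn + pend; pend = 0.0;
    epsp_f *= dfe; epsp_s *= dse;
    nmda_f *= dfn; nmda_s *= dsn;
    bpap_f *= dfb; bpap_s *= dsb;
    bpap_eff += (1.0 - bpap_eff) * (1.0 - std::exp(-dt / q.btau));
    // presynaptic spikes in [t, t+dt)
    while (ip < np && pre_t[ip] < t + dt) {
      pend += w;
      if (q.trace_mode == 1) {
        epsp_f += q.ife; epsp_s += q.ise; nmda_f += q.nif; nmda_s += q.nis;
      } else {
        epsp_f = q.ife; epsp_s = q.ise; nmda_f = q.nif; nmda_s = q.nis;
      }
      if (stdp_on && last_post > -1e8) {
        w -= q.A_minus * std::exp(-((t + dt) - last_post) / q.tau_minus);
        if (w < q.w_min) w = q.w_min;
      }
      last_pre = t + dt;
      ++ip;
    }
    while (iq < nq && post_t[iq] < t + dt) {
      bpap_f = q.ifb * bpap_eff; bpap_s = q.isb * bpap_eff;
      bpap_eff *= (1.0 - q.bu);
      if (stdp_on && last_pre > -1e8) {
        w += q.A_plus * std::exp(-((t + dt) - last_pre) / q.tau_plus);
        if (w > q.w_max) w = q.w_max;
      }
      last_post = t + dt;
      ++iq;
    }
    double vinf = v_rest + r_m * (isyn * 1e9);
    V = vinf + (V - vinf) * em;
    if (ca_on) {
      double vsyn = w * q.epsp_scale * (epsp_f + epsp_s) +
        (use_bpap ? q.bpap_max * (bpap_f + bpap_s) : 0.0);
      double ntr = nmda_f + nmda_s;
      if (ntr > q.ncap) ntr = q.ncap;
      double inmda = q.gain * tab.GW(w) * ntr * tab.H(vsyn);
      ca += dt * (inmda - ca / q.tau_ca);
      if (ca < 0) ca = 0;
      if (plast_on) {
        double wn = w + dt * tab.ET(ca) * (q.kappa * tab.OM(ca) - w);
        if (wn < q.w_min) wn = q.w_min;
        if (wn > q.w_max) wn = q.w_max;
        w = wn;
      }
    }
    if (s % record_every == 0) {
      rt[ir] = t; rca[ir] = ca; rw[ir] = w; rv[ir] = V; ++ir;
    }
  }
  return List::create(_["time"] = rt[Range(0, ir - 1)],
                      _["calcium"] = rca[Range(0, ir - 1)],
                      _["weight"] = rw[Range(0, ir - 1)],
                      _["v_post"] = rv[Range(0, ir - 1)]);
}
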