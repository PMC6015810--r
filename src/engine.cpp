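// Forward-Euler engine for conductance-based LIF networks with delayed
// spike delivery and trace STDP.
//
// Per-step ordering (mirrored by the pure-R reference stepper):
//   1. input-layer emissions due this step are scheduled on the delay line
//   2. pending arrivals due this step are delivered: conductance jump of
//      g_scale * weight, then (plastic, STDP on) LTD using the current
//      postsynaptic trace D, then the presynaptic trace C is driven
//   3. each non-refractory neuron takes one Euler step of the membrane
//      equation; refractory neurons are clamped at V_H while their
//      countdown decrements
//   4. neurons crossing threshold emit a spike stamped at the end of the
//      step; LTP over plastic afferents using current C, then D is
//      driven; efferent deliveries are enqueued at emission + delay
//   5. conductances decay by exp(-dt / tau_g)
//
// Conductances are aggregated per (neuron, synapse class): decay is linear
// and tau_g / reversal are shared within a class, so the aggregate equals
// the sum of per-synapse conductances exactly. STDP traces decay lazily
// (exact exponential between the events that touch them).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List run_trial_engine(IntegerVector syn_pre, IntegerVector syn_post,
                      IntegerVector syn_class, LogicalVector syn_plastic,
                      NumericVector syn_weight_in, NumericVector syn_delay,
                      IntegerVector neuron_class, NumericMatrix neuron_par,
                      NumericMatrix syn_class_par,
                      IntegerVector in_spike_neuron,
                      NumericVector in_spike_time, double duration, double dt,
                      bool stdp_on, double alpha_c, double alpha_d,
                      double tau_c, double tau_d, double rho,
                      NumericVector trace_c_in, NumericVector trace_d_in) {
  const int n_syn = syn_pre.size();
  const int n_neu = neuron_class.size();
  const int n_cls = syn_class_par.nrow();
  const int nsteps = (int)std::floor(duration / dt + 1e-9);
  if (dt <= 0) stop("dt must be positive");

  NumericVector w = clone(syn_weight_in);

  // compact index over simulated (non-input) neurons
  std::vector<int> simmap(n_neu, -1), sim_ids;
  for (int i = 0; i < n_neu; ++i)
    if (neuron_class[i] > 0) { simmap[i] = (int)sim_ids.size(); sim_ids.push_back(i); }
  const int n_sim = (int)sim_ids.size();

  // per-synapse arrival offsets in steps (>= 1 so delivery is causal)
  std::vector<int> off(n_syn);
  int max_off = 1;
  for (int s = 0; s < n_syn; ++s) {
    int o = (int)std::lround(syn_delay[s] / dt);
    if (o < 1) o = 1;
    off[s] = o;
    if (o > max_off) max_off = o;
  }

  // efferent CSR over all neurons
  std::vector<int> eff_cnt(n_neu + 1, 0);
  for (int s = 0; s < n_syn; ++s) eff_cnt[syn_pre[s] - 1 + 1]++;
  for (int i = 0; i < n_neu; ++i) eff_cnt[i + 1] += eff_cnt[i];
  std::vector<int> eff(n_syn);
  {
    std::vector<int> fill(eff_cnt.begin(), eff_cnt.end() - 1);
    for (int s = 0; s < n_syn; ++s) eff[fill[syn_pre[s] - 1]++] = s;
  }
  // plastic afferent CSR over simulated neurons
  std::vector<int> aff_cnt(n_sim + 1, 0);
  for (int s = 0; s < n_syn; ++s)
    if (syn_plastic[s]) {
      int p = simmap[syn_post[s] - 1];
      if (p >= 0) aff_cnt[p + 1]++;
    }
  for (int i = 0; i < n_sim; ++i) aff_cnt[i + 1] += aff_cnt[i];
  std::vector<int> aff(aff_cnt[n_sim]);
  {
    std::vector<int> fill(aff_cnt.begin(), aff_cnt.end() - 1);
    for (int s = 0; s < n_syn; ++s)
      if (syn_plastic[s]) {
        int p = simmap[syn_post[s] - 1];
        if (p >= 0) aff[fill[p]++] = s;
      }
  }

  // state
  std::vector<double> V(n_sim);
  std::vector<double> Cm(n_sim), g0(n_sim), V0(n_sim), theta(n_sim),
      VH(n_sim), tauR(n_sim);
  for (int p = 0; p < n_sim; ++p) {
    int cls = neuron_class[sim_ids[p]] - 1;
    Cm[p] = neuron_par(cls, 0); g0[p] = neuron_par(cls, 1);
    V0[p] = neuron_par(cls, 2); theta[p] = neuron_par(cls, 3);
    VH[p] = neuron_par(cls, 4); tauR[p] = neuron_par(cls, 5);
    V[p] = V0[p];
  }
  std::vector<double> G((size_t)n_sim * n_cls, 0.0);
  std::vector<double> decay_g(n_cls), vrev(n_cls), gscale(n_cls);
  for (int c = 0; c < n_cls; ++c) {
    decay_g[c] = std::exp(-dt / syn_class_par(c, 0));
    vrev[c] = syn_class_par(c, 1);
    gscale[c] = syn_class_par(c, 2);
  }

  // STDP traces, lazily decayed
  std::vector<double> trC(n_syn, 0.0), trD(n_sim, 0.0);
  std::vector<int> lastC(n_syn, 0), lastD(n_sim, 0);
  if (trace_c_in.size() == n_syn)
    for (int s = 0; s < n_syn; ++s) trC[s] = trace_c_in[s];
  if (trace_d_in.size() == n_neu)
    for (int p = 0; p < n_sim; ++p) trD[p] = trace_d_in[sim_ids[p]];

  // delay line ring buffer
  const int L = max_off + 2;
  std::vector<std::vector<int>> ring(L);

  // input emissions grouped by step
  const int n_in_sp = in_spike_neuron.size();
  std::vector<int> in_step(n_in_sp);
  std::vector<int> in_order(n_in_sp);
  for (int e = 0; e < n_in_sp; ++e) {
    in_step[e] = (int)std::floor(in_spike_time[e] / dt + 1e-9);
    in_order[e] = e;
  }
  std::stable_sort(in_order.begin(), in_order.end(),
                   [&](int a, int b) { return in_step[a] < in_step[b]; });
  int in_ptr = 0;

  std::vector<int> out_neuron;
  std::vector<double> out_time;
  std::vector<int> refr_cnt(n_sim, 0);

  for (int k = 0; k < nsteps; ++k) {
    // 1. schedule input emissions due this step
    while (in_ptr < n_in_sp && in_step[in_order[in_ptr]] <= k) {
      int e = in_order[in_ptr++];
      int nid = in_spike_neuron[e] - 1;
      for (int q = eff_cnt[nid]; q < eff_cnt[nid + 1]; ++q) {
        int s = eff[q];
        int at = k + off[s];
        if (at < nsteps + max_off) ring[at % L].push_back(s);
      }
    }
    // 2. arrivals
    std::vector<int> &slot = ring[k % L];
    for (size_t a = 0; a < slot.size(); ++a) {
      int s = slot[a];
      int p = simmap[syn_post[s] - 1];
      if (p < 0) continue;
      int c = syn_class[s] - 1;
      G[(size_t)c * n_sim + p] += gscale[c] * w[s];
      if (stdp_on && syn_plastic[s]) {
        trD[p] *= std::exp(-(k - lastD[p]) * dt / tau_d);
        lastD[p] = k;
        w[s] -= rho * trD[p] * w[s];
        trC[s] *= std::exp(-(k - lastC[s]) * dt / tau_c);
        lastC[s] = k;
        trC[s] += alpha_c * (1.0 - trC[s]);
      }
    }
    slot.clear();
    // 3-4. integrate, detect, schedule
    for (int p = 0; p < n_sim; ++p) {
      if (refr_cnt[p] > 0) {
        V[p] = VH[p];
        refr_cnt[p]--;
        continue;
      }
      double I = 0.0;
      for (int c = 0; c < n_cls; ++c)
        I += G[(size_t)c * n_sim + p] * (vrev[c] - V[p]);
      double tau_m = Cm[p] / g0[p];
      V[p] += dt / tau_m * ((V0[p] - V[p]) + I / g0[p]);
      if (!std::isfinite(V[p]))
        stop("membrane potential diverged at t = %f ms (neuron %d); dt too large?",
             (k + 1) * dt, sim_ids[p] + 1);
      if (V[p] >= theta[p]) {
        int nid = sim_ids[p];
        out_neuron.push_back(nid + 1);
        out_time.push_back((k + 1) * dt);
        V[p] = VH[p];
        refr_cnt[p] = (int)std::lround(tauR[p] / dt);
        if (stdp_on) {
          for (int q = aff_cnt[p]; q < aff_cnt[p + 1]; ++q) {
            int s = aff[q];
            trC[s] *= std::exp(-(k - lastC[s]) * dt / tau_c);
            lastC[s] = k;
            w[s] += rho * trC[s] * (1.0 - w[s]);
          }
          trD[p] *= std::exp(-(k - lastD[p]) * dt / tau_d);
          lastD[p] = k;
          trD[p] += alpha_d * (1.0 - trD[p]);
        }
        for (int q = eff_cnt[nid]; q < eff_cnt[nid + 1]; ++q) {
          int s = eff[q];
          int at = k + off[s];
          if (at < nsteps + max_off) ring[at % L].push_back(s);
        }
      }
    }
    // 5. conductance decay
    for (int c = 0; c < n_cls; ++c) {
      double f = decay_g[c];
      double *col = &G[(size_t)c * n_sim];
      for (int p = 0; p < n_sim; ++p) col[p] *= f;
    }
  }

  // final trace values at the end of the trial
  for (int s = 0; s < n_syn; ++s)
    trC[s] *= std::exp(-(nsteps - lastC[s]) * dt / tau_c);
  NumericVector Dout(n_neu, 0.0), Vout(n_neu, NA_REAL);
  for (int p = 0; p < n_sim; ++p) {
    Dout[sim_ids[p]] = trD[p] * std::exp(-(nsteps - lastD[p]) * dt / tau_d);
    Vout[sim_ids[p]] = V[p];
  }

  return List::create(
      _["spike_neuron"] = wrap(out_neuron), _["spike_time"] = wrap(out_time),
      _["weights"] = w, _["trace_c"] = wrap(trC), _["trace_d"] = Dout,
      _["V"] = Vout);
}
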