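// Time-driven simulator for asynchronous stochastic binary-neuron networks.
//
// Each neuron's update times form a Poisson process with rate 1/tau, realized
// on a regular grid of step dt (at most one update per neuron per step; update
// intervals are exponential draws rounded to >= 1 step). At an update a local
// neuron becomes active iff its summed synaptic input, delayed by `delay`
// grid steps, exceeds its threshold (Heaviside gain, H(0) = 0). External
// sources become active with constant probability m_x, independent of
// everything else. State flips are propagated to the input accumulators of
// all targets through per-source outgoing adjacency, entering the
// accumulators `delay` steps after the flip.
//
// Statistics (per-neuron activity sums, population-summed activity,
// per-pair coincidence counts for a caller-supplied pair list) are
// accumulated on the measurement grid so that large networks never require
// materializing the full state matrix. Uses R's RNG so results are
// reproducible via set.seed().

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline int draw_interval_steps(double tau_steps) {
  // exponential inter-update interval in grid steps, at least one step
  double u = R::exp_rand() * tau_steps;
  int k = (int)(u + 0.5);
  return k < 1 ? 1 : k;
}

// [[Rcpp::export(name = ".simulate_binary_network")]]
List simulate_binary_network(
    int n_e, int n_i, int n_x,
    IntegerVector in_ptr,     // length n_local + 1, 0-based offsets
    IntegerVector in_src,     // global 0-based source index per in-edge
    NumericVector in_w,       // weight per in-edge
    NumericVector theta,      // length n_local
    NumericVector dc_offset,  // length n_local, constant input term
    double m_x,
    double tau_steps,         // tau expressed in grid steps (tau / dt)
    int n_steps, int transient_steps, int meas_every, int delay_steps,
    NumericVector p_init,     // length n_tot, initial activation probability
    IntegerMatrix pairs,      // n_pairs x 2 global 0-based indices (or 0 x 2)
    bool record_states) {

  const int n_local = n_e + n_i;
  const int n_tot = n_local + n_x;
  if (delay_steps < 1) stop("delay must be at least one grid step");
  if (transient_steps >= n_steps) stop("duration must exceed the transient");

  // --- outgoing adjacency (CSR) built from the incoming lists -------------
  const int n_edges = in_src.size();
  std::vector<int> out_cnt(n_tot, 0);
  for (int e = 0; e < n_edges; ++e) out_cnt[in_src[e]]++;
  std::vector<int> out_ptr(n_tot + 1, 0);
  for (int v = 0; v < n_tot; ++v) out_ptr[v + 1] = out_ptr[v] + out_cnt[v];
  std::vector<int> out_tgt(n_edges);
  std::vector<double> out_w(n_edges);
  {
    std::vector<int> fill(out_ptr.begin(), out_ptr.end() - 1);
    for (int tgt = 0; tgt < n_local; ++tgt) {
      for (int e = in_ptr[tgt]; e < in_ptr[tgt + 1]; ++e) {
        if (!R_finite(in_w[e])) stop("non-finite synaptic weight");
        int s = in_src[e];
        out_tgt[fill[s]] = tgt;
        out_w[fill[s]] = in_w[e];
        fill[s]++;
      }
    }
  }

  // --- state, input accumulators, schedules -------------------------------
  std::vector<uint8_t> state(n_tot);
  std::vector<double> h(n_local, 0.0);
  for (int v = 0; v < n_tot; ++v) state[v] = (unif_rand() < p_init[v]) ? 1 : 0;
  for (int tgt = 0; tgt < n_local; ++tgt)
    for (int e = in_ptr[tgt]; e < in_ptr[tgt + 1]; ++e)
      if (state[in_src[e]]) h[tgt] += in_w[e];

  std::vector< std::vector<int> > update_at(n_steps);
  std::vector< std::vector<int> > flip_at(n_steps);  // +-(neuron+1)
  for (int v = 0; v < n_tot; ++v) {
    int t0 = draw_interval_steps(tau_steps) - 1;  // first update may be at step 0
    if (t0 < n_steps) update_at[t0].push_back(v);
  }

  // --- measurement accumulators -------------------------------------------
  const int n_bins = (n_steps - transient_steps + meas_every - 1) / meas_every;
  std::vector<double> neuron_sum(n_tot, 0.0);
  NumericMatrix pop_sums(n_bins, 3);
  const int n_pairs = pairs.nrow();
  std::vector<double> pair_prod(n_pairs, 0.0);
  IntegerMatrix states_rec(record_states ? n_bins : 0,
                           record_states ? n_tot : 0);
  int bin = 0;

  // --- main loop -----------------------------------------------------------
  for (int t = 0; t < n_steps; ++t) {
    { // deliver flips scheduled for this step
      std::vector<int> &fl = flip_at[t];
      for (size_t q = 0; q < fl.size(); ++q) {
        int code = fl[q];
        int v = (code > 0 ? code : -code) - 1;
        double sgn = code > 0 ? 1.0 : -1.0;
        for (int e = out_ptr[v]; e < out_ptr[v + 1]; ++e)
          h[out_tgt[e]] += sgn * out_w[e];
      }
      std::vector<int>().swap(fl);
    }
    { // neuron updates
      std::vector<int> &up = update_at[t];
      for (size_t q = 0; q < up.size(); ++q) {
        int v = up[q];
        uint8_t ns;
        if (v < n_local) {
          ns = (h[v] + dc_offset[v] > theta[v]) ? 1 : 0;
        } else {
          ns = (unif_rand() < m_x) ? 1 : 0;
        }
        if (ns != state[v]) {
          state[v] = ns;
          int td = t + delay_steps;
          if (td < n_steps) flip_at[td].push_back(ns ? (v + 1) : -(v + 1));
        }
        int tn = t + draw_interval_steps(tau_steps);
        if (tn < n_steps) update_at[tn].push_back(v);
      }
      std::vector<int>().swap(up);
    }
    // measurement
    if (t >= transient_steps && (t - transient_steps) % meas_every == 0) {
      double se = 0, si = 0, sx = 0;
      for (int v = 0; v < n_e; ++v) se += state[v];
      for (int v = n_e; v < n_local; ++v) si += state[v];
      for (int v = n_local; v < n_tot; ++v) sx += state[v];
      pop_sums(bin, 0) = se; pop_sums(bin, 1) = si; pop_sums(bin, 2) = sx;
      for (int v = 0; v < n_tot; ++v) neuron_sum[v] += state[v];
      for (int pp = 0; pp < n_pairs; ++pp)
        if (state[pairs(pp, 0)] && state[pairs(pp, 1)]) pair_prod[pp] += 1.0;
      if (record_states)
        for (int v = 0; v < n_tot; ++v) states_rec(bin, v) = state[v];
      ++bin;
    }
  }

  List out = List::create(
    _["n_bins"] = bin,
    _["neuron_sum"] = NumericVector(neuron_sum.begin(), neuron_sum.end()),
    _["pop_sums"] = pop_sums,
    _["pair_prod"] = NumericVector(pair_prod.begin(), pair_prod.end()));
  if (record_states) out["states"] = states_rec;
  return out;
}
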