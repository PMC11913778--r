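#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Self-contained counter-free PRNG (xoshiro256+ seeded by splitmix64) so
// simulations are bit-reproducible across platforms independently of R's
// RNG state.
struct Rng {
  uint64_t s[4];
  double spare;
  bool has_spare;

  explicit Rng(uint64_t seed) : spare(0.0), has_spare(false) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(const uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double runif() {
    // 53-bit mantissa uniform in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double rnorm() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, ss;
    do {
      u = 2.0 * runif() - 1.0;
      v = 2.0 * runif() - 1.0;
      ss = u * u + v * v;
    } while (ss >= 1.0 || ss == 0.0);
    double m = std::sqrt(-2.0 * std::log(ss) / ss);
    spare = v * m;
    has_spare = true;
    return u * m;
  }
};

// Conductance-based leaky integrate-and-fire network with exponential
// synaptic decay, cyclic pulse + pause external input with log-normal
// amplitudes, per-neuron refreshed log-normal noise current, and optional
// homeostatic inhibitory spike-timing-dependent plasticity
// (symmetric rule: pre spike -> w += eta * (x_post - alpha);
//  post spike -> w += eta * x_pre; traces decay with tau_stdp).
//
// Units: mV, ms, nS, pF, pA. dV/dt in mV/ms = pA/pF.
// [[Rcpp::export(name = ".lif_simulate_cpp")]]
List lif_simulate_cpp(int n_exc, int n_inh,
                      IntegerVector exc_src, IntegerVector exc_tgt, double w_exc,
                      IntegerVector inh_src, IntegerVector inh_tgt, NumericVector w_inh,
                      List params,
                      NumericMatrix patterns,       // n_total x n_patterns, pA
                      IntegerVector pattern_seq,    // 1-based pattern id per cycle
                      double pulse_ms, double pause_ms,
                      double noise_M, double noise_mu, double noise_sigma,
                      double noise_refresh_ms,
                      bool plasticity, double eta, double alpha, double tau_stdp,
                      double w_max,
                      double seed,
                      bool record_spikes,
                      bool poisson_drive, double poisson_rate_per_ms,
                      double stim_M, double stim_mu, double stim_sigma,
                      int record_v_neuron = 0) {
  const int n = n_exc + n_inh;
  const double e_leak   = as<double>(params["e_leak"]);
  const double e_glut   = as<double>(params["e_glut"]);
  const double egaba_e  = as<double>(params["egaba_exc"]);
  const double egaba_i  = as<double>(params["egaba_inh"]);
  const double tau_e    = as<double>(params["tau_exc_syn"]);
  const double tau_i    = as<double>(params["tau_inh_syn"]);
  const double c_m      = as<double>(params["c_m"]);
  const double tau_m    = as<double>(params["tau_m"]);
  const double v_th     = as<double>(params["v_threshold"]);
  const double v_reset  = as<double>(params["v_reset"]);
  const double t_ref    = as<double>(params["t_refractory"]);
  const double dt       = as<double>(params["dt"]);
  const double delay_ms = as<double>(params["syn_delay"]);
  const double g_leak   = c_m / tau_m;  // nS

  const int n_cycles = pattern_seq.size();
  const double cycle_ms = pulse_ms + pause_ms;
  const int steps_per_cycle = (int)std::llround(cycle_ms / dt);
  const int pulse_steps = (int)std::llround(pulse_ms / dt);
  const int refresh_steps = std::max(1, (int)std::llround(noise_refresh_ms / dt));
  const int ref_steps = (int)std::llround(t_ref / dt);
  // synaptic transmission delay: conductance increments are queued in a
  // ring buffer and released delay_steps later
  const int delay_steps = std::max(1, (int)std::llround(delay_ms / dt));
  std::vector<std::vector<double>> buf_e(delay_steps),
      buf_i(delay_steps);
  for (int d = 0; d < delay_steps; ++d) {
    buf_e[d].assign(n_exc + n_inh, 0.0);
    buf_i[d].assign(n_exc + n_inh, 0.0);
  }

  // outgoing adjacency (CSR by source)
  std::vector<std::vector<int>> out_e(n), out_i(n);
  std::vector<std::vector<int>> out_i_syn(n);   // synapse index for inh edges
  for (int k = 0; k < exc_src.size(); ++k) out_e[exc_src[k]].push_back(exc_tgt[k]);
  std::vector<double> w(w_inh.begin(), w_inh.end());
  for (int k = 0; k < inh_src.size(); ++k) {
    out_i[inh_src[k]].push_back(inh_tgt[k]);
    out_i_syn[inh_src[k]].push_back(k);
  }
  // incoming inhibitory synapses per target (for plasticity on post spikes)
  std::vector<std::vector<int>> in_i_syn(n);
  if (plasticity) {
    for (int k = 0; k < inh_src.size(); ++k) in_i_syn[inh_tgt[k]].push_back(k);
  }

  std::vector<double> V(n, e_leak), g_e(n, 0.0), g_i(n, 0.0),
      I_noise(n, 0.0), trace(n, 0.0), pulse_amp(n, 0.0);
  std::vector<int> refrac(n, 0), pulse_left(n, 0);
  const double dec_e = std::exp(-dt / tau_e);
  const double dec_i = std::exp(-dt / tau_i);
  const double dec_x = std::exp(-dt / tau_stdp);

  Rng rng((uint64_t)seed);

  std::vector<int> spk_n;
  std::vector<double> spk_t;
  std::vector<double> v_trace;
  if (record_v_neuron > 0)
    v_trace.reserve((size_t)n_cycles * steps_per_cycle);
  std::vector<int> spiked; spiked.reserve(64);

  // mean excitatory-population rate per simulated second
  const int total_steps = n_cycles * steps_per_cycle;
  const int steps_per_sec = (int)std::llround(1000.0 / dt);
  std::vector<double> rate_traj;
  long exc_spikes_this_sec = 0;

  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    const int pat = pattern_seq[cyc] - 1;
    for (int st = 0; st < steps_per_cycle; ++st) {
      const long gstep = (long)cyc * steps_per_cycle + st;
      // spikes are stamped at the midpoint of the step in which the
      // threshold crossing occurred, so a crossing during the final step
      // of an input pulse stays inside the pulse's histogram bin
      const double t_now = (gstep + 0.5) * dt;

      if (gstep % refresh_steps == 0) {
        for (int i = 0; i < n; ++i)
          I_noise[i] = noise_M * std::exp(noise_mu + noise_sigma * rng.rnorm());
      }

      spiked.clear();
      const bool in_pulse = st < pulse_steps;
      std::vector<double>& rel_e = buf_e[gstep % delay_steps];
      std::vector<double>& rel_i = buf_i[gstep % delay_steps];
      for (int i = 0; i < n; ++i) {
        g_e[i] = g_e[i] * dec_e + rel_e[i];
        g_i[i] = g_i[i] * dec_i + rel_i[i];
        rel_e[i] = 0.0;
        rel_i[i] = 0.0;
        if (plasticity) trace[i] *= dec_x;
        if (refrac[i] > 0) { --refrac[i]; V[i] = v_reset; continue; }
        const double e_gaba = (i < n_exc) ? egaba_e : egaba_i;
        double I_ext = I_noise[i];
        if (poisson_drive) {
          // independent per-neuron pulse trains with log-normal amplitudes
          if (pulse_left[i] == 0 && rng.runif() < poisson_rate_per_ms * dt) {
            pulse_left[i] = pulse_steps;
            pulse_amp[i] =
                stim_M * std::exp(stim_mu + stim_sigma * rng.rnorm());
          }
          if (pulse_left[i] > 0) { I_ext += pulse_amp[i]; --pulse_left[i]; }
        } else if (in_pulse) {
          I_ext += patterns(i, pat);
        }
        const double G = g_leak + g_e[i] + g_i[i];
        const double v_inf =
            (g_leak * e_leak + g_e[i] * e_glut + g_i[i] * e_gaba + I_ext) / G;
        V[i] = v_inf + (V[i] - v_inf) * std::exp(-G * dt / c_m);
        if (V[i] >= v_th) {
          V[i] = v_reset;
          refrac[i] = ref_steps;
          spiked.push_back(i);
          if (i < n_exc) ++exc_spikes_this_sec;
          if (record_spikes) { spk_n.push_back(i + 1); spk_t.push_back(t_now); }
        }
        if (V[i] > 200.0 || V[i] < -200.0)
          stop("numerical instability: |V| > 200 mV at t = %f ms", t_now);
      }

      // propagate spikes (into the delay buffer) and apply plasticity
      // the slot read (and cleared) this step comes around again exactly
      // delay_steps later
      std::vector<double>& enq_e = buf_e[gstep % delay_steps];
      std::vector<double>& enq_i = buf_i[gstep % delay_steps];
      for (size_t si = 0; si < spiked.size(); ++si) {
        const int s = spiked[si];
        if (s < n_exc) {
          const std::vector<int>& tg = out_e[s];
          for (size_t k = 0; k < tg.size(); ++k) enq_e[tg[k]] += w_exc;
        } else {
          const std::vector<int>& tg = out_i[s];
          const std::vector<int>& sy = out_i_syn[s];
          for (size_t k = 0; k < tg.size(); ++k) {
            if (plasticity) {
              double nw = w[sy[k]] + eta * (trace[tg[k]] - alpha);
              w[sy[k]] = nw < 0.0 ? 0.0 : (nw > w_max ? w_max : nw);
            }
            enq_i[tg[k]] += w[sy[k]];
          }
        }
        if (plasticity) {
          // post-spike update on incoming inhibitory synapses
          const std::vector<int>& in_sy = in_i_syn[s];
          for (size_t k = 0; k < in_sy.size(); ++k) {
            double nw = w[in_sy[k]] + eta * trace[inh_src[in_sy[k]]];
            w[in_sy[k]] = nw < 0.0 ? 0.0 : (nw > w_max ? w_max : nw);
          }
          trace[s] += 1.0;
        }
      }

      if (record_v_neuron > 0) v_trace.push_back(V[record_v_neuron - 1]);

      if ((gstep + 1) % steps_per_sec == 0 || gstep + 1 == total_steps) {
        const double span_s =
            ((gstep % steps_per_sec) + 1) * dt / 1000.0;
        rate_traj.push_back(exc_spikes_this_sec / (double)n_exc / span_s);
        exc_spikes_this_sec = 0;
      }
    }
  }

  return List::create(
      _["spike_neuron"] = wrap(spk_n),
      _["spike_t_ms"] = wrap(spk_t),
      _["w_inh"] = wrap(w),
      _["rate_traj_hz"] = wrap(rate_traj),
      _["v_trace"] = wrap(v_trace),
      _["cycle_ms"] = cycle_ms,
      _["n_cycles"] = n_cycles);
}
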