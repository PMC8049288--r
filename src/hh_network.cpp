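#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Hodgkin-Huxley gating rate functions (ms^-1).  The alpha_n and alpha_m
// expressions have removable singularities at v = -55 and v = -40 mV; within
// |x| < 1e-7 of the singular voltage they are evaluated by their limits
// (0.1 and 1.0 ms^-1).
static inline double rate_an(double v) {
  double x = v + 55.0;
  if (std::fabs(x) < 1e-7) return 0.1;
  return 0.01 * x / (1.0 - std::exp(-0.1 * x));
}
static inline double rate_bn(double v) { return 0.125 * std::exp(-0.0125 * (v + 65.0)); }
static inline double rate_am(double v) {
  double x = v + 40.0;
  if (std::fabs(x) < 1e-7) return 1.0;
  return 0.1 * x / (1.0 - std::exp(-0.1 * x));
}
static inline double rate_bm(double v) { return 4.0 * std::exp(-0.0556 * (v + 65.0)); }
static inline double rate_ah(double v) { return 0.07 * std::exp(-0.05 * (v + 65.0)); }
static inline double rate_bh(double v) { return 1.0 / (1.0 + std::exp(-0.1 * (v + 35.0))); }

// [[Rcpp::export]]
NumericMatrix gating_rates_cpp(NumericVector v) {
  int n = v.size();
  NumericMatrix out(n, 6);
  for (int i = 0; i < n; ++i) {
    double vi = v[i];
    out(i, 0) = rate_an(vi); out(i, 1) = rate_bn(vi);
    out(i, 2) = rate_am(vi); out(i, 3) = rate_bm(vi);
    out(i, 4) = rate_ah(vi); out(i, 5) = rate_bh(vi);
  }
  colnames(out) = CharacterVector::create("an", "bn", "am", "bm", "ah", "bh");
  return out;
}

struct Arrival { int post; double w; int cls; }; // cls 0 = excitatory, 1 = inhibitory

// Simulate a network of HH neurons with conductance-based double-exponential
// synapses and per-edge axonal delays (delay-line ring buffer at dt
// resolution).  Additive Gaussian white noise (sigma * sqrt(dt) per step)
// enters only the voltage equation; for additive noise the Milstein
// correction vanishes, so the scheme coincides with Euler-Maruyama.  Noise is
// drawn from R's RNG, one draw per neuron per step (no draws when sigma = 0),
// so trajectories are fully reproducible from set.seed().
//
// edges_*: parallel vectors (0-based pre/post, weight in muS/cm^2, delay in
// integer steps >= 1, class of the presynaptic neuron).
// signal: per-step injected current (muA/cm^2) added to neurons flagged in
// signal_target; length 0 disables it.
// [[Rcpp::export]]
List hh_network_cpp(int n_neurons,
                    IntegerVector edges_pre, IntegerVector edges_post,
                    NumericVector edges_w, IntegerVector edges_delay,
                    IntegerVector edges_cls,
                    NumericVector I0, NumericVector noise_sigma,
                    NumericVector signal, LogicalVector signal_target,
                    double duration, double dt,
                    NumericVector v0, NumericVector n0,
                    NumericVector m0, NumericVector h0,
                    IntegerVector record_idx,
                    double tau_r, double tau_d,
                    double E_exc, double E_inh,
                    NumericVector params,
                    double spike_threshold, double refractory) {
  const double C    = params[0], gK = params[1], gNa = params[2], gL = params[3];
  const double EK   = params[4], ENa = params[5], EL = params[6];
  const int n_steps = (int) std::lround(duration / dt);
  const int n_edges = edges_pre.size();

  // peak-normalisation constant of the double-exponential kernel
  const double t_pk = tau_r * tau_d / (tau_d - tau_r) * std::log(tau_d / tau_r);
  const double A_pk = std::exp(-t_pk / tau_d) - std::exp(-t_pk / tau_r);
  const double fd = std::exp(-dt / tau_d), fr = std::exp(-dt / tau_r);

  // CSR outgoing adjacency
  std::vector<int> deg(n_neurons, 0);
  for (int e = 0; e < n_edges; ++e) deg[edges_pre[e]]++;
  std::vector<int> off(n_neurons + 1, 0);
  for (int i = 0; i < n_neurons; ++i) off[i + 1] = off[i] + deg[i];
  std::vector<int> adj(n_edges), fill(off.begin(), off.end() - 1);
  for (int e = 0; e < n_edges; ++e) adj[fill[edges_pre[e]]++] = e;

  int max_delay = 1;
  for (int e = 0; e < n_edges; ++e) if (edges_delay[e] > max_delay) max_delay = edges_delay[e];
  const int ring_len = max_delay + 1;
  std::vector< std::vector<Arrival> > ring(ring_len);

  std::vector<double> v(v0.begin(), v0.end()), gn(n0.begin(), n0.end());
  std::vector<double> gm(m0.begin(), m0.end()), gh(h0.begin(), h0.end());
  std::vector<double> geD(n_neurons, 0.0), geR(n_neurons, 0.0);
  std::vector<double> giD(n_neurons, 0.0), giR(n_neurons, 0.0);
  std::vector<double> last_spike(n_neurons, -1e9);

  std::vector<double> spike_t; std::vector<int> spike_id;
  spike_t.reserve(n_neurons * (size_t)(duration / 10.0 + 16));
  spike_id.reserve(spike_t.capacity());

  const int n_rec = record_idx.size();
  NumericMatrix v_rec(n_rec > 0 ? n_steps + 1 : 0, n_rec);
  if (n_rec > 0) for (int j = 0; j < n_rec; ++j) v_rec(0, j) = v[record_idx[j]];

  const bool has_signal = signal.size() > 0;
  long clip_count = 0;
  bool any_noise = false;
  for (int i = 0; i < n_neurons; ++i) if (noise_sigma[i] > 0) any_noise = true;
  if (any_noise) GetRNGstate();

  for (int s = 0; s < n_steps; ++s) {
    // deliver spikes scheduled for this step
    std::vector<Arrival> &slot = ring[s % ring_len];
    for (size_t a = 0; a < slot.size(); ++a) {
      const Arrival &ar = slot[a];
      if (ar.cls == 0) { geD[ar.post] += ar.w; geR[ar.post] += ar.w; }
      else             { giD[ar.post] += ar.w; giR[ar.post] += ar.w; }
    }
    slot.clear();

    const double sig = has_signal ? signal[s] : 0.0;
    const double t_next = (s + 1) * dt;

    for (int i = 0; i < n_neurons; ++i) {
      double vi = v[i];
      double ge = geD[i] - geR[i], gi = giD[i] - giR[i];
      double Isyn = ge * (E_exc - vi) + gi * (E_inh - vi);
      double Iin = I0[i] + (signal_target[i] ? sig : 0.0);
      double dv = (Iin + Isyn
                   - gK * gn[i]*gn[i]*gn[i]*gn[i] * (vi - EK)
                   - gNa * gm[i]*gm[i]*gm[i] * gh[i] * (vi - ENa)
                   - gL * (vi - EL)) / C;
      double vnew = vi + dt * dv;
      if (noise_sigma[i] > 0.0)
        vnew += noise_sigma[i] * std::sqrt(dt) / C * norm_rand();

      double an = rate_an(vi), bn = rate_bn(vi);
      double am = rate_am(vi), bm = rate_bm(vi);
      double ah = rate_ah(vi), bh = rate_bh(vi);
      double nn = gn[i] + dt * (an * (1.0 - gn[i]) - bn * gn[i]);
      double mn = gm[i] + dt * (am * (1.0 - gm[i]) - bm * gm[i]);
      double hn = gh[i] + dt * (ah * (1.0 - gh[i]) - bh * gh[i]);
      if (nn < 0.0) { nn = 0.0; ++clip_count; } else if (nn > 1.0) { nn = 1.0; ++clip_count; }
      if (mn < 0.0) { mn = 0.0; ++clip_count; } else if (mn > 1.0) { mn = 1.0; ++clip_count; }
      if (hn < 0.0) { hn = 0.0; ++clip_count; } else if (hn > 1.0) { hn = 1.0; ++clip_count; }

      // spike: upward crossing of the threshold with refractory lockout
      if (vi < spike_threshold && vnew >= spike_threshold &&
          t_next - last_spike[i] >= refractory) {
        last_spike[i] = t_next;
        spike_t.push_back(t_next);
        spike_id.push_back(i);
        for (int k = off[i]; k < off[i + 1]; ++k) {
          int e = adj[k];
          Arrival ar;
          ar.post = edges_post[e];
          ar.w = edges_w[e] * 1e-3 / A_pk;  // muS -> mS, unit-peak kernel
          ar.cls = edges_cls[e];
          ring[(s + edges_delay[e]) % ring_len].push_back(ar);
        }
      }
      v[i] = vnew; gn[i] = nn; gm[i] = mn; gh[i] = hn;
    }

    for (int i = 0; i < n_neurons; ++i) {
      geD[i] *= fd; geR[i] *= fr; giD[i] *= fd; giR[i] *= fr;
    }
    if (n_rec > 0) for (int j = 0; j < n_rec; ++j) v_rec(s + 1, j) = v[record_idx[j]];
  }
  if (any_noise) PutRNGstate();

  return List::create(_["spike_t"] = wrap(spike_t),
                      _["spike_id"] = wrap(spike_id),
                      _["v"] = v_rec,
                      _["state"] = DataFrame::create(_["v"] = wrap(v), _["n"] = wrap(gn),
                                                     _["m"] = wrap(gm), _["h"] = wrap(gh)),
                      _["clip_count"] = (double) clip_count);
}
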