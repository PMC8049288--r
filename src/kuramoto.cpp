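#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama integration of two delay-coupled phase oscillators
//   dtheta1 = 2*pi*(w1 + s1(t)) dt + 2*pi*K*sin(theta2 - theta1 - delta) dt + 2*pi*sigma*sqrt(dt) xi1
//   dtheta2 = 2*pi*(w2 + s2(t)) dt + 2*pi*K*sin(theta1 - theta2 - delta) dt + 2*pi*sigma*sqrt(dt) xi2
// Frequencies, coupling, signals and noise are all expressed in Hz; delta is
// the interaction phase lag in radians.  Noise uses R's RNG (two draws per
// step) so trajectories are reproducible from set.seed(); no draws when
// sigma = 0.
// `thin` records every thin-th step (plus the initial state), which keeps
// long runs cheap on the R side; phase increments across recorded samples
// are exact sums of the step increments.
// [[Rcpp::export]]
List kuramoto_pair_cpp(double w1, double w2, double K, double delta,
                       double sigma, NumericVector signal1, NumericVector signal2,
                       double duration, double dt,
                       double theta1_0, double theta2_0, int thin) {
  const int n_steps = (int) std::lround(duration / dt);
  const double twopi = 2.0 * M_PI;
  const int n_rec = n_steps / thin;
  NumericVector th1(n_rec + 1), th2(n_rec + 1);
  th1[0] = theta1_0; th2[0] = theta2_0;
  const bool s1 = signal1.size() > 0, s2 = signal2.size() > 0;
  const double sq = sigma * std::sqrt(dt) * twopi;
  if (sigma > 0) GetRNGstate();
  double a = theta1_0, b = theta2_0;
  for (int s = 0; s < n_steps; ++s) {
    double da = twopi * (w1 + (s1 ? signal1[s] : 0.0) + K * std::sin(b - a - delta)) * dt;
    double db = twopi * (w2 + (s2 ? signal2[s] : 0.0) + K * std::sin(a - b - delta)) * dt;
    if (sigma > 0) { da += sq * norm_rand(); db += sq * norm_rand(); }
    a += da; b += db;
    if ((s + 1) % thin == 0) { th1[(s + 1) / thin] = a; th2[(s + 1) / thin] = b; }
  }
  if (sigma > 0) PutRNGstate();
  return List::create(_["theta1"] = th1, _["theta2"] = th2);
}
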