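#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Synchronous update u_{t+1} = tanh(W u_t + r * eta), eta ~ N(0,1) per
// neuron per step. Noise draws come from R's RNG so set.seed() controls
// reproducibility. When r == 0 no draws are consumed, so noise-free runs
// are bit-identical regardless of the RNG state.
// Returns the steps x n matrix of post-update continuous states.
// [[Rcpp::export]]
NumericMatrix simulate_tanh_cpp(NumericMatrix w, int steps, double r,
                                NumericVector u0) {
  const int n = w.nrow();
  if (w.ncol() != n) stop("weight matrix must be square");
  if (u0.size() != n) stop("initial state length does not match network size");
  if (steps < 1) stop("steps must be >= 1");

  NumericMatrix out(steps, n);
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> v(n);

  for (int t = 0; t < steps; ++t) {
    for (int i = 0; i < n; ++i) {
      double a = 0.0;
      for (int j = 0; j < n; ++j) a += w(i, j) * u[j];
      if (r > 0.0) a += r * norm_rand();
      v[i] = std::tanh(a);
    }
    for (int i = 0; i < n; ++i) {
      u[i] = v[i];
      out(t, i) = u[i];
    }
  }
  return out;
}
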