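// Monte-Carlo kernels for the asynchronous binary-network dynamics.
// Both samplers draw from R's RNG stream so that set.seed() in R makes
// trajectories reproducible.

#include <Rcpp.h>
using namespace Rcpp;

// Simulate the tabular network: per-neuron spike probabilities are given as
// a flattened [2^n, nx, n] array (column-major, matching an R array), the
// input chain as a matrix of cumulative row probabilities.  States are
// 0-based integer bit codes.
// [[Rcpp::export]]
List cpp_simulate_network(NumericVector q, int n, int ns, int nx,
                          NumericMatrix px_cum, int n_steps, int burn_in,
                          int s0, int x0) {
  IntegerVector states(n_steps), inputs(n_steps);
  int s = s0, x = x0;
  long total = (long)burn_in + n_steps;
  for (long t = 0; t < total; ++t) {
    int i = (int)(unif_rand() * n);
    if (i >= n) i = n - 1;
    double p_spike = q[s + (long)ns * x + (long)ns * nx * i];
    int bit = 1 << i;
    if (unif_rand() < p_spike) s |= bit; else s &= ~bit;
    if (nx > 1) {
      double u = unif_rand();
      int x2 = 0;
      while (x2 < nx - 1 && u > px_cum(x, x2)) ++x2;
      x = x2;
    }
    if (t >= burn_in) {
      states[t - burn_in] = s;
      inputs[t - burn_in] = x;
    }
  }
  return List::create(_["states"] = states, _["inputs"] = inputs);
}

// Simulate Glauber-style dynamics under a quadratic (Ising) value function:
// neuron i spikes with probability logistic(sum_j J4[i][j] sigma_j + b[i]),
// where J4 = 4 J / (n lambda) and b = 2 h / (n lambda) + logit(rate) are
// precomputed by the caller.  Pinned neurons stay at +1 and are never
// updated.  Returns the visited 0-based state codes.  With probability
// `explore` the selected neuron is resampled from a fair coin instead of
// the policy (training-time exploration; 0 = on-policy).
// [[Rcpp::export]]
IntegerVector cpp_simulate_ising(NumericMatrix J4, NumericVector b,
                                 int n_steps, int burn_in, int s0,
                                 LogicalVector pinned, double explore) {
  int n = b.size();
  std::vector<double> sigma(n);
  for (int i = 0; i < n; ++i) {
    sigma[i] = ((s0 >> i) & 1) ? 1.0 : -1.0;
    if (pinned[i]) sigma[i] = 1.0;
  }
  std::vector<double> field(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      field[i] += J4(i, j) * sigma[j];
  IntegerVector states(n_steps);
  int code = 0;
  for (int i = 0; i < n; ++i) if (sigma[i] > 0) code |= (1 << i);
  long total = (long)burn_in + n_steps;
  for (long t = 0; t < total; ++t) {
    int i = (int)(unif_rand() * n);
    if (i >= n) i = n - 1;
    if (!pinned[i]) {
      double p;
      if (explore > 0.0 && unif_rand() < explore) {
        p = 0.5;
      } else {
        double eta = field[i] + b[i];
        p = 1.0 / (1.0 + std::exp(-eta));
      }
      double nv = (unif_rand() < p) ? 1.0 : -1.0;
      if (nv != sigma[i]) {
        double d = nv - sigma[i];
        for (int j = 0; j < n; ++j) field[j] += J4(j, i) * d;
        sigma[i] = nv;
        if (nv > 0) code |= (1 << i); else code &= ~(1 << i);
      }
    }
    if (t >= burn_in) states[t - burn_in] = code;
  }
  return states;
}
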