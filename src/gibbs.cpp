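#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for a {0,1} Ising model.
// Full conditional: P(x_j = 1 | rest) = logistic(tau_j + sum_k w_jk x_k).
// Fixed ascending scan; uses R's RNG so set.seed() on the R side governs
// reproducibility. Initial state drawn from the independent logistic(tau).
// [[Rcpp::export]]
IntegerMatrix gibbs_sample_cpp(NumericVector tau, NumericMatrix w,
                               int n, int burn_in, int thin) {
  const int p = tau.size();
  IntegerMatrix out(n, p);
  std::vector<int> x(p);
  for (int j = 0; j < p; ++j) {
    double pr = 1.0 / (1.0 + std::exp(-tau[j]));
    x[j] = (unif_rand() < pr) ? 1 : 0;
  }
  const int total = burn_in + (n > 0 ? n * thin : 0);
  int kept = 0;
  for (int sweep = 0; sweep < total; ++sweep) {
    for (int j = 0; j < p; ++j) {
      double eta = tau[j];
      for (int k = 0; k < p; ++k) {
        if (x[k]) eta += w(j, k);
      }
      double pr = 1.0 / (1.0 + std::exp(-eta));
      x[j] = (unif_rand() < pr) ? 1 : 0;
    }
    if (sweep >= burn_in && ((sweep - burn_in + 1) % thin == 0) && kept < n) {
      for (int j = 0; j < p; ++j) out(kept, j) = x[j];
      ++kept;
    }
  }
  return out;
}
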