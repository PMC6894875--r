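#include <Rcpp.h>
using namespace Rcpp;

// Online SOM training for a small node grid. X is samples x features,
// init is nodes x features, order holds 1-based sample indices for every
// update step (generated from R's RNG so runs are reproducible). The
// learning rate decays linearly from alpha_from to alpha_to; with two
// nodes the neighborhood collapses to winner-only updates.
// [[Rcpp::export]]
List som_train_cpp(NumericMatrix X, NumericMatrix init, IntegerVector order,
                   double alpha_from, double alpha_to) {
  const int n = X.nrow(), d = X.ncol(), m = init.nrow();
  NumericMatrix W = clone(init);
  const int steps = order.size();
  for (int s = 0; s < steps; ++s) {
    const int i = order[s] - 1;
    const double alpha =
        alpha_from + (alpha_to - alpha_from) * ((double)s / steps);
    int best = 0;
    double bestd = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double acc = 0.0;
      for (int t = 0; t < d; ++t) {
        const double diff = X(i, t) - W(j, t);
        acc += diff * diff;
      }
      if (acc < bestd) { bestd = acc; best = j; }
    }
    for (int t = 0; t < d; ++t) W(best, t) += alpha * (X(i, t) - W(best, t));
  }
  IntegerVector assignment(n);
  double objective = 0.0;
  for (int i = 0; i < n; ++i) {
    int best = 0;
    double bestd = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double acc = 0.0;
      for (int t = 0; t < d; ++t) {
        const double diff = X(i, t) - W(j, t);
        acc += diff * diff;
      }
      if (acc < bestd) { bestd = acc; best = j; }
    }
    assignment[i] = best + 1;
    objective += bestd;
  }
  return List::create(_["codebook"] = W, _["assignment"] = assignment,
                      _["objective"] = objective);
}
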