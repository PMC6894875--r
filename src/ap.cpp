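#include <Rcpp.h>
using namespace Rcpp;

// Affinity-propagation message passing. S is the full similarity matrix
// with the shared preference already placed on the diagonal. Messages are
// damped with factor lam; iteration stops when the exemplar set has been
// stable for convits iterations or after maxits iterations. Deterministic
// (no noise is added to S).
// [[Rcpp::export]]
List ap_messages_cpp(NumericMatrix S, double lam, int maxits, int convits) {
  const int n = S.nrow();
  NumericMatrix R(n, n), A(n, n);
  std::vector<int> last(n, -1);
  int stable = 0, it = 0;
  bool converged = false;
  for (it = 0; it < maxits; ++it) {
    // responsibilities: r(i,k) = s(i,k) - max_{k' != k} (a(i,k') + s(i,k'))
    for (int i = 0; i < n; ++i) {
      double m1 = R_NegInf, m2 = R_NegInf;
      int k1 = -1;
      for (int k = 0; k < n; ++k) {
        const double v = A(i, k) + S(i, k);
        if (v > m1) { m2 = m1; m1 = v; k1 = k; }
        else if (v > m2) { m2 = v; }
      }
      for (int k = 0; k < n; ++k) {
        const double rnew = S(i, k) - (k == k1 ? m2 : m1);
        R(i, k) = lam * R(i, k) + (1.0 - lam) * rnew;
      }
    }
    // availabilities: a(i,k) = min(0, r(k,k) + sum_{i' not in {i,k}} r(i',k)+)
    for (int k = 0; k < n; ++k) {
      double spos = 0.0;
      for (int i = 0; i < n; ++i)
        if (i != k) spos += std::max(0.0, R(i, k));
      for (int i = 0; i < n; ++i) {
        double anew;
        if (i == k) anew = spos;
        else anew = std::min(0.0, R(k, k) + spos - std::max(0.0, R(i, k)));
        A(i, k) = lam * A(i, k) + (1.0 - lam) * anew;
      }
    }
    bool same = true;
    int count = 0;
    for (int k = 0; k < n; ++k) {
      const int e = (A(k, k) + R(k, k)) > 0 ? 1 : 0;
      if (e != last[k]) same = false;
      last[k] = e;
      count += e;
    }
    if (same && count > 0) {
      if (++stable >= convits) { converged = true; ++it; break; }
    } else {
      stable = 0;
    }
  }
  std::vector<int> ex;
  for (int k = 0; k < n; ++k)
    if (last[k] == 1) ex.push_back(k + 1);
  return List::create(_["exemplars"] = wrap(ex), _["iterations"] = it,
                      _["converged"] = converged);
}
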