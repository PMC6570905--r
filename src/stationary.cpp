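#include <Rcpp.h>
using namespace Rcpp;

// Stationary distribution of a CTMC by uniformized power iteration:
// x <- x P with P = I + Q / Lambda, Lambda slightly above the fastest
// exit rate, starting from the uniform distribution. P has strictly
// positive diagonal entries, so the iteration converges for any
// irreducible truncated generator. Off-diagonal rates are passed as
// triplets; diag holds the (negative) diagonal of Q.
// [[Rcpp::export]]
List cpp_power_stationary(IntegerVector from, IntegerVector to,
                          NumericVector rate, NumericVector diag,
                          double lambda, int max_iter, double tol,
                          int check_every) {
  const int ns = diag.size();
  const int ne = rate.size();
  std::vector<double> x(ns, 1.0 / ns), xn(ns);
  double delta = R_PosInf;
  int it = 0;
  while (it < max_iter) {
    for (int sweep = 0; sweep < check_every && it < max_iter;
         ++sweep, ++it) {
      for (int j = 0; j < ns; ++j)
        xn[j] = x[j] * (1.0 + diag[j] / lambda);
      for (int e = 0; e < ne; ++e)
        xn[to[e]] += x[from[e]] * rate[e] / lambda;
      std::swap(x, xn);
    }
    delta = 0.0;
    for (int j = 0; j < ns; ++j) delta += std::fabs(x[j] - xn[j]);
    if (delta < tol) break;
  }
  double s = 0.0;
  for (int j = 0; j < ns; ++j) s += x[j];
  NumericVector out(ns);
  for (int j = 0; j < ns; ++j) out[j] = x[j] / s;
  return List::create(_["p"] = out, _["iterations"] = it,
                      _["delta"] = delta);
}
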