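#include <Rcpp.h>
using namespace Rcpp;

// EM for a two-component 1-D Gaussian mixture. Overlapping components
// make the likelihood surface shallow in the weight direction, so EM can
// need very many iterations; this kernel keeps each iteration cheap and
// stops on an absolute log-likelihood increment below tol.
// [[Rcpp::export]]
List cpp_gmm_em(NumericVector x, NumericVector w0, NumericVector mu0,
                NumericVector v0, int max_iter, double tol) {
  const int n = x.size();
  double w1 = w0[0], m1 = mu0[0], m2 = mu0[1], v1 = v0[0], v2 = v0[1];
  double ll = R_NegInf, prev = R_NegInf;
  int it = 0;
  std::vector<double> r1(n);
  for (it = 1; it <= max_iter; ++it) {
    double c1 = std::log(w1) - 0.5 * std::log(2.0 * M_PI * v1);
    double c2 = std::log(1.0 - w1) - 0.5 * std::log(2.0 * M_PI * v2);
    double s1 = 0.0, sx1 = 0.0, sxx1 = 0.0, sx2 = 0.0, sxx2 = 0.0;
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double d1 = x[i] - m1, d2 = x[i] - m2;
      double l1 = c1 - 0.5 * d1 * d1 / v1;
      double l2 = c2 - 0.5 * d2 * d2 / v2;
      double mx = std::max(l1, l2);
      double e1 = std::exp(l1 - mx), e2 = std::exp(l2 - mx);
      double s = e1 + e2;
      ll += mx + std::log(s);
      double g = e1 / s;
      r1[i] = g;
      s1 += g;
      sx1 += g * x[i];
      sxx1 += g * x[i] * x[i];
      sx2 += (1.0 - g) * x[i];
      sxx2 += (1.0 - g) * x[i] * x[i];
    }
    double s2 = n - s1;
    w1 = s1 / n;
    m1 = sx1 / s1; m2 = sx2 / s2;
    v1 = std::max(sxx1 / s1 - m1 * m1, 1e-10);
    v2 = std::max(sxx2 / s2 - m2 * m2, 1e-10);
    if (it > 10 && (ll - prev) < tol) break;
    prev = ll;
  }
  return List::create(_["w"] = NumericVector::create(w1, 1.0 - w1),
                      _["mu"] = NumericVector::create(m1, m2),
                      _["v"] = NumericVector::create(v1, v2),
                      _["loglik"] = ll, _["n_iter"] = it);
}
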