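#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a K-state Gaussian-emission HMM over a set
// of independent trajectories sharing parameters. Returns the total
// log-likelihood plus the Baum-Welch sufficient statistics:
//   gamma1[k]  : sum over trajectories of P(state_1 = k | y)
//   xi[j,k]    : expected transition counts j -> k
//   occ[k]     : sum_t gamma_t(k)
//   sy[k]      : sum_t gamma_t(k) * y_t
//   syy[k]     : sum_t gamma_t(k) * y_t^2
//
// y is the pooled emission vector; lengths gives the frames per trajectory.

static inline double dnorm_(double y, double mu, double var) {
  double d = y - mu;
  return std::exp(-0.5 * d * d / var) / std::sqrt(2.0 * M_PI * var);
}

// [[Rcpp::export]]
List cpp_hmm_estep(NumericVector y, IntegerVector lengths, NumericMatrix T,
                   NumericVector mu, NumericVector var, NumericVector pi) {
  const int K = mu.size();
  double loglik = 0.0;
  NumericVector gamma1(K), occ(K), sy(K), syy(K);
  NumericMatrix xi(K, K);
  int off = 0;
  std::vector<double> alpha, beta, scale, b;
  for (int tr = 0; tr < lengths.size(); ++tr) {
    const int n = lengths[tr];
    alpha.assign((size_t)n * K, 0.0);
    beta.assign((size_t)n * K, 0.0);
    scale.assign(n, 0.0);
    b.assign((size_t)n * K, 0.0);
    for (int t = 0; t < n; ++t)
      for (int k = 0; k < K; ++k)
        b[t * K + k] = dnorm_(y[off + t], mu[k], var[k]);
    // forward
    double c0 = 0.0;
    for (int k = 0; k < K; ++k) {
      alpha[k] = pi[k] * b[k];
      c0 += alpha[k];
    }
    if (c0 <= 0.0) stop("zero forward mass (degenerate emission model)");
    scale[0] = c0;
    for (int k = 0; k < K; ++k) alpha[k] /= c0;
    for (int t = 1; t < n; ++t) {
      double ct = 0.0;
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < K; ++j) s += alpha[(t - 1) * K + j] * T(j, k);
        double v = s * b[t * K + k];
        alpha[t * K + k] = v;
        ct += v;
      }
      if (ct <= 0.0) stop("zero forward mass (degenerate emission model)");
      scale[t] = ct;
      for (int k = 0; k < K; ++k) alpha[t * K + k] /= ct;
    }
    // backward
    for (int k = 0; k < K; ++k) beta[(n - 1) * K + k] = 1.0;
    for (int t = n - 2; t >= 0; --t)
      for (int j = 0; j < K; ++j) {
        double s = 0.0;
        for (int k = 0; k < K; ++k)
          s += T(j, k) * b[(t + 1) * K + k] * beta[(t + 1) * K + k];
        beta[t * K + j] = s / scale[t + 1];
      }
    // accumulate
    for (int t = 0; t < n; ++t) {
      double norm = 0.0;
      for (int k = 0; k < K; ++k) norm += alpha[t * K + k] * beta[t * K + k];
      for (int k = 0; k < K; ++k) {
        double g = alpha[t * K + k] * beta[t * K + k] / norm;
        if (t == 0) gamma1[k] += g;
        occ[k] += g;
        sy[k] += g * y[off + t];
        syy[k] += g * y[off + t] * y[off + t];
      }
    }
    for (int t = 0; t < n - 1; ++t) {
      double norm = 0.0;
      std::vector<double> tmp((size_t)K * K);
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k) {
          double v = alpha[t * K + j] * T(j, k) * b[(t + 1) * K + k] *
                     beta[(t + 1) * K + k];
          tmp[j * K + k] = v;
          norm += v;
        }
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k) xi(j, k) += tmp[j * K + k] / norm;
    }
    for (int t = 0; t < n; ++t) loglik += std::log(scale[t]);
    off += n;
  }
  return List::create(_["loglik"] = loglik, _["gamma1"] = gamma1,
                      _["xi"] = xi, _["occ"] = occ, _["sy"] = sy,
                      _["syy"] = syy);
}

// Viterbi most-likely path (log domain); returns 0-based state indices.
// [[Rcpp::export]]
IntegerVector cpp_viterbi(NumericVector y, NumericMatrix T, NumericVector mu,
                          NumericVector var, NumericVector pi) {
  const int K = mu.size(), n = y.size();
  std::vector<double> delta((size_t)n * K);
  std::vector<int> psi((size_t)n * K);
  NumericMatrix lT(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k) lT(j, k) = std::log(T(j, k));
  auto ldnorm = [&](double yv, int k) {
    double d = yv - mu[k];
    return -0.5 * (std::log(2.0 * M_PI * var[k]) + d * d / var[k]);
  };
  for (int k = 0; k < K; ++k) delta[k] = std::log(pi[k]) + ldnorm(y[0], k);
  for (int t = 1; t < n; ++t)
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta[(t - 1) * K + j] + lT(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta[t * K + k] = best + ldnorm(y[t], k);
      psi[t * K + k] = arg;
    }
  IntegerVector path(n);
  int arg = 0;
  double best = R_NegInf;
  for (int k = 0; k < K; ++k)
    if (delta[(n - 1) * K + k] > best) { best = delta[(n - 1) * K + k]; arg = k; }
  path[n - 1] = arg;
  for (int t = n - 2; t >= 0; --t) path[t] = psi[(t + 1) * K + path[t + 1]];
  return path;
}
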