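#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward (Rabiner-style per-position normalizers) on a
// precomputed T x K emission-likelihood matrix B.  Returns the posterior
// state probabilities gamma (T x K), the expected transition counts xi
// summed over positions (K x K), and the sequence log-likelihood (the sum
// of the log scaling constants).  Scaling, not log-space recursion, so the
// normalizers give the log-likelihood directly and 1e5-position sequences
// cannot underflow.
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericVector init, NumericMatrix trans, NumericMatrix B) {
  const int T = B.nrow();
  const int K = B.ncol();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K), xi(K, K);
  NumericVector c(T);

  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = init[k] * B(0, k);
    s += alpha(0, k);
  }
  if (s <= 0.0 || !R_finite(s))
    stop("observation sequence has zero probability under the model");
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * trans(i, j);
      a *= B(t, j);
      alpha(t, j) = a;
      s += a;
    }
    if (s <= 0.0 || !R_finite(s))
      stop("observation sequence has zero probability under the model");
    c[t] = s;
    for (int j = 0; j < K; ++j) alpha(t, j) /= s;
  }

  // backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double b = 0.0;
      for (int j = 0; j < K; ++j)
        b += trans(i, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, i) = b / c[t + 1];
    }
  }

  // posteriors and expected transition counts
  double loglik = 0.0;
  for (int t = 0; t < T; ++t) {
    loglik += std::log(c[t]);
    double g = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      g += gamma(t, k);
    }
    // guard against rounding drift; g is 1 up to machine precision
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }
  for (int t = 0; t + 1 < T; ++t) {
    for (int i = 0; i < K; ++i) {
      const double ai = alpha(t, i);
      for (int j = 0; j < K; ++j)
        xi(i, j) += ai * trans(i, j) * B(t + 1, j) * beta(t + 1, j) / c[t + 1];
    }
  }

  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = loglik);
}
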