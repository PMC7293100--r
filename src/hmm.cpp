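#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a homogeneous discrete-state HMM.
// emis: n x K matrix of emission probabilities (linear scale),
// trans: K x K row-stochastic transition matrix, init: length-K start
// distribution. Returns posterior state probabilities, the log-likelihood
// and the expected transition-count matrix (for Baum-Welch).
// [[Rcpp::export(name = ".fb_hmm")]]
List fb_hmm(NumericMatrix emis, NumericMatrix trans, NumericVector init) {
  const int n = emis.nrow(), K = emis.ncol();
  NumericMatrix alpha(n, K), beta(n, K), gamma(n, K);
  NumericVector scale(n);
  const double tiny = 1e-300;

  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = init[k] * emis(0, k);
    s += alpha(0, k);
  }
  if (s < tiny) s = tiny;
  scale[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int i = 1; i < n; ++i) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(i - 1, j) * trans(j, k);
      a *= emis(i, k);
      alpha(i, k) = a;
      s += a;
    }
    if (s < tiny) s = tiny;
    scale[i] = s;
    for (int k = 0; k < K; ++k) alpha(i, k) /= s;
  }

  // backward
  for (int k = 0; k < K; ++k) beta(n - 1, k) = 1.0;
  for (int i = n - 2; i >= 0; --i) {
    for (int j = 0; j < K; ++j) {
      double b = 0.0;
      for (int k = 0; k < K; ++k)
        b += trans(j, k) * emis(i + 1, k) * beta(i + 1, k);
      beta(i, j) = b / scale[i + 1];
    }
  }

  // posteriors and expected transition counts
  NumericMatrix xi(K, K);
  for (int i = 0; i < n; ++i) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(i, k) = alpha(i, k) * beta(i, k);
      g += gamma(i, k);
    }
    if (g < tiny) g = tiny;
    for (int k = 0; k < K; ++k) gamma(i, k) /= g;
  }
  for (int i = 0; i < n - 1; ++i) {
    for (int j = 0; j < K; ++j) {
      double aij = alpha(i, j);
      for (int k = 0; k < K; ++k)
        xi(j, k) += aij * trans(j, k) * emis(i + 1, k) * beta(i + 1, k) /
                    scale[i + 1];
    }
  }

  double loglik = 0.0;
  for (int i = 0; i < n; ++i) loglik += std::log(scale[i]);

  return List::create(_["gamma"] = gamma, _["loglik"] = loglik,
                      _["xi"] = xi);
}

// Scaled forward-backward for the haplotype-copying (Li & Stephens type)
// HMM. States are the panel haplotypes; between adjacent sites the chain
// either stays on the current haplotype or switches with probability
// rho[i] (length n-1) to a haplotype drawn from the prior pi (also the
// start distribution). emis: n x K copying emission probabilities.
// [[Rcpp::export(name = ".fb_copying")]]
List fb_copying(NumericMatrix emis, NumericVector rho, NumericVector pi) {
  const int n = emis.nrow(), K = emis.ncol();
  NumericMatrix alpha(n, K), beta(n, K), gamma(n, K);
  NumericVector scale(n);
  const double tiny = 1e-300;

  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = emis(0, k) * pi[k];
    s += alpha(0, k);
  }
  if (s < tiny) s = tiny;
  scale[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;

  for (int i = 1; i < n; ++i) {
    const double r = rho[i - 1];
    // alpha at i-1 sums to 1 after scaling
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = ((1.0 - r) * alpha(i - 1, k) + r * pi[k]) * emis(i, k);
      alpha(i, k) = a;
      s += a;
    }
    if (s < tiny) s = tiny;
    scale[i] = s;
    for (int k = 0; k < K; ++k) alpha(i, k) /= s;
  }

  for (int k = 0; k < K; ++k) beta(n - 1, k) = 1.0;
  for (int i = n - 2; i >= 0; --i) {
    const double r = rho[i];
    double tot = 0.0;
    for (int k = 0; k < K; ++k)
      tot += pi[k] * emis(i + 1, k) * beta(i + 1, k);
    for (int j = 0; j < K; ++j) {
      double b = (1.0 - r) * emis(i + 1, j) * beta(i + 1, j) + r * tot;
      beta(i, j) = b / scale[i + 1];
    }
  }

  for (int i = 0; i < n; ++i) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(i, k) = alpha(i, k) * beta(i, k);
      g += gamma(i, k);
    }
    if (g < tiny) g = tiny;
    for (int k = 0; k < K; ++k) gamma(i, k) /= g;
  }

  double loglik = 0.0;
  for (int i = 0; i < n; ++i) loglik += std::log(scale[i]);

  return List::create(_["gamma"] = gamma, _["loglik"] = loglik);
}
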