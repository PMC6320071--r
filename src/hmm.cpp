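#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scaled forward-backward pass for a two-state Gaussian-emission HMM.
// Returns the log-likelihood, the per-sample posterior of state 2, and the
// expected transition counts needed for the EM M-step.
// [[Rcpp::export(name = ".hmm_forward_backward")]]
List hmm_forward_backward(NumericVector x, NumericVector mu, NumericVector sigma,
                          NumericVector init, NumericMatrix trans) {
  const int n = x.size();
  NumericMatrix b(n, 2);
  for (int t = 0; t < n; ++t) {
    for (int s = 0; s < 2; ++s) {
      double z = (x[t] - mu[s]) / sigma[s];
      b(t, s) = std::exp(-0.5 * z * z) / sigma[s];
      if (b(t, s) < 1e-300) b(t, s) = 1e-300;
    }
  }
  NumericMatrix alpha(n, 2), beta(n, 2);
  NumericVector c(n);
  // forward
  for (int s = 0; s < 2; ++s) alpha(0, s) = init[s] * b(0, s);
  c[0] = alpha(0, 0) + alpha(0, 1);
  alpha(0, 0) /= c[0]; alpha(0, 1) /= c[0];
  for (int t = 1; t < n; ++t) {
    for (int s = 0; s < 2; ++s) {
      alpha(t, s) = (alpha(t - 1, 0) * trans(0, s) +
                     alpha(t - 1, 1) * trans(1, s)) * b(t, s);
    }
    c[t] = alpha(t, 0) + alpha(t, 1);
    alpha(t, 0) /= c[t]; alpha(t, 1) /= c[t];
  }
  // backward
  beta(n - 1, 0) = 1.0; beta(n - 1, 1) = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    for (int s = 0; s < 2; ++s) {
      beta(t, s) = (trans(s, 0) * b(t + 1, 0) * beta(t + 1, 0) +
                    trans(s, 1) * b(t + 1, 1) * beta(t + 1, 1)) / c[t + 1];
    }
  }
  double loglik = 0.0;
  for (int t = 0; t < n; ++t) loglik += std::log(c[t]);
  loglik -= n * 0.5 * std::log(2.0 * M_PI);

  NumericMatrix gamma(n, 2);
  for (int t = 0; t < n; ++t) {
    double g0 = alpha(t, 0) * beta(t, 0);
    double g1 = alpha(t, 1) * beta(t, 1);
    double s = g0 + g1;
    gamma(t, 0) = g0 / s; gamma(t, 1) = g1 / s;
  }
  NumericMatrix xi(2, 2);
  for (int t = 0; t < n - 1; ++t) {
    double denom = 0.0;
    double v[2][2];
    for (int i = 0; i < 2; ++i) {
      for (int j = 0; j < 2; ++j) {
        v[i][j] = alpha(t, i) * trans(i, j) * b(t + 1, j) * beta(t + 1, j);
        denom += v[i][j];
      }
    }
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j)
        xi(i, j) += v[i][j] / denom;
  }
  return List::create(_["loglik"] = loglik, _["gamma"] = gamma, _["xi"] = xi);
}

// Viterbi decoding of the most probable state path (1-based states).
// [[Rcpp::export(name = ".hmm_viterbi")]]
IntegerVector hmm_viterbi(NumericVector x, NumericVector mu, NumericVector sigma,
                          NumericVector init, NumericMatrix trans) {
  const int n = x.size();
  NumericMatrix logb(n, 2);
  for (int t = 0; t < n; ++t) {
    for (int s = 0; s < 2; ++s) {
      double z = (x[t] - mu[s]) / sigma[s];
      logb(t, s) = -0.5 * z * z - std::log(sigma[s]);
    }
  }
  double la[2][2];
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j)
      la[i][j] = std::log(std::max(trans(i, j), 1e-300));
  NumericMatrix delta(n, 2);
  IntegerMatrix psi(n, 2);
  for (int s = 0; s < 2; ++s)
    delta(0, s) = std::log(std::max(init[s], 1e-300)) + logb(0, s);
  for (int t = 1; t < n; ++t) {
    for (int s = 0; s < 2; ++s) {
      double v0 = delta(t - 1, 0) + la[0][s];
      double v1 = delta(t - 1, 1) + la[1][s];
      if (v0 >= v1) { delta(t, s) = v0 + logb(t, s); psi(t, s) = 0; }
      else          { delta(t, s) = v1 + logb(t, s); psi(t, s) = 1; }
    }
  }
  IntegerVector path(n);
  int last = delta(n - 1, 0) >= delta(n - 1, 1) ? 0 : 1;
  path[n - 1] = last + 1;
  for (int t = n - 2; t >= 0; --t) {
    last = psi(t + 1, last);
    path[t] = last + 1;
  }
  return path;
}
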