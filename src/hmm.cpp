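#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian-emission HMM utilities for a small number of states (K = 2 in
// practice). Scaled forward-backward Baum-Welch and Viterbi decoding.

static inline double gauss_pdf(double x, double mu, double sigma) {
  const double z = (x - mu) / sigma;
  return std::exp(-0.5 * z * z) / (sigma * 2.5066282746310002);
}

// [[Rcpp::export]]
List hmm_em_cpp(NumericVector y, NumericVector mu0, NumericVector sigma0,
                NumericMatrix A0, NumericVector pi0,
                int max_iter, double tol, double sigma_floor,
                double sigma_cap_frac) {
  const int T = y.size();
  const int K = mu0.size();
  if (K > 4) stop("at most 4 states supported");
  NumericVector mu = clone(mu0), sigma = clone(sigma0), pi = clone(pi0);
  NumericMatrix A = clone(A0);

  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K), B(T, K);
  NumericVector c(T);
  double loglik = R_NegInf, prev_ll = R_NegInf;
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    // emission densities
    for (int t = 0; t < T; ++t)
      for (int k = 0; k < K; ++k)
        B(t, k) = gauss_pdf(y[t], mu[k], sigma[k]);

    // scaled forward
    double s = 0.0;
    for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * B(0, k); s += alpha(0, k); }
    if (s <= 0.0 || !std::isfinite(s)) return List::create(_["ok"] = false);
    c[0] = s;
    for (int k = 0; k < K; ++k) alpha(0, k) /= s;
    for (int t = 1; t < T; ++t) {
      s = 0.0;
      for (int k = 0; k < K; ++k) {
        double a = 0.0;
        for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
        alpha(t, k) = a * B(t, k);
        s += alpha(t, k);
      }
      if (s <= 0.0 || !std::isfinite(s)) return List::create(_["ok"] = false);
      c[t] = s;
      for (int k = 0; k < K; ++k) alpha(t, k) /= s;
    }
    loglik = 0.0;
    for (int t = 0; t < T; ++t) loglik += std::log(c[t]);

    // scaled backward
    for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      for (int k = 0; k < K; ++k) {
        double b = 0.0;
        for (int j = 0; j < K; ++j) b += A(k, j) * B(t + 1, j) * beta(t + 1, j);
        beta(t, k) = b / c[t + 1];
      }
    }

    // posteriors
    for (int t = 0; t < T; ++t) {
      double g = 0.0;
      for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
      if (g <= 0.0) return List::create(_["ok"] = false);
      for (int k = 0; k < K; ++k) gamma(t, k) /= g;
    }

    // transition expectations
    NumericMatrix xi_sum(K, K);
    for (int t = 0; t < T - 1; ++t) {
      double denom = 0.0;
      double tmp[4 * 4];
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k) {
          double v = alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k);
          tmp[j * K + k] = v;
          denom += v;
        }
      if (denom <= 0.0) return List::create(_["ok"] = false);
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k)
          xi_sum(j, k) += tmp[j * K + k] / denom;
    }

    // M step
    for (int k = 0; k < K; ++k) {
      pi[k] = gamma(0, k);
      double w = 0.0, m = 0.0;
      for (int t = 0; t < T; ++t) { w += gamma(t, k); m += gamma(t, k) * y[t]; }
      if (w <= 0.0) return List::create(_["ok"] = false);
      mu[k] = m / w;
      double v = 0.0;
      for (int t = 0; t < T; ++t) {
        double d = y[t] - mu[k];
        v += gamma(t, k) * d * d;
      }
      sigma[k] = std::sqrt(v / w);
      if (sigma[k] < sigma_floor) sigma[k] = sigma_floor;
      double row = 0.0;
      for (int j = 0; j < K; ++j) row += xi_sum(k, j);
      if (row > 0.0)
        for (int j = 0; j < K; ++j) A(k, j) = xi_sum(k, j) / row;
    }

    // optional cap on emission widths relative to the level separation:
    // guards against one component swallowing the between-level ramp mass
    // produced by low-pass filtering (two-state case only)
    if (sigma_cap_frac > 0.0 && K == 2) {
      double cap = sigma_cap_frac * std::fabs(mu[1] - mu[0]);
      if (cap >= sigma_floor)
        for (int k = 0; k < K; ++k)
          if (sigma[k] > cap) sigma[k] = cap;
    }

    if (iter > 0) {
      double rel = std::fabs(loglik - prev_ll) /
                   (std::fabs(prev_ll) + 1e-300);
      if (rel < tol) { converged = true; ++iter; break; }
    }
    prev_ll = loglik;
  }

  return List::create(_["ok"] = true, _["mu"] = mu, _["sigma"] = sigma,
                      _["A"] = A, _["pi"] = pi, _["loglik"] = loglik,
                      _["iterations"] = iter, _["converged"] = converged);
}

// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericVector y, NumericVector mu,
                              NumericVector sigma, NumericMatrix A,
                              NumericVector pi) {
  const int T = y.size();
  const int K = mu.size();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  const double NEG = -1e300;

  NumericMatrix logA(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      logA(j, k) = A(j, k) > 0 ? std::log(A(j, k)) : NEG;

  for (int k = 0; k < K; ++k) {
    double e = gauss_pdf(y[0], mu[k], sigma[k]);
    delta(0, k) = (pi[k] > 0 && e > 0) ? std::log(pi[k]) + std::log(e) : NEG;
  }
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = NEG;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      double e = gauss_pdf(y[t], mu[k], sigma[k]);
      delta(t, k) = best + (e > 0 ? std::log(e) : NEG);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  int arg = 0;
  double best = NEG;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path;
}
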