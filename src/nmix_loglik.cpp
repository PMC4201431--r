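// Likelihood kernels for open-population (dynamic) N-mixture models.
// Latent abundance N_it lives on 0..K; the per-site likelihood is a
// forward pass over seasons:
//   f_1(N)   = mix(N; lambda_i, psi) * prod_j Binom(n_i1j | N, p_i1j)
//   f_t(N')  = [ sum_N f_{t-1}(N) P(N' | N; omega, gamma_i) ]
//              * prod_j Binom(n_itj | N', p_itj)
// with P(N'|N) = sum_s Binom(s | N, omega) Pois(N'-s | gamma).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// survival kernel: row n (0..K), col s (0..K): Binom(s | n, omega)
static arma::mat surv_matrix(double omega, int K) {
  arma::mat B(K + 1, K + 1, arma::fill::zeros);
  for (int n = 0; n <= K; ++n)
    for (int s = 0; s <= n; ++s)
      B(n, s) = R::dbinom(s, n, omega, 0);
  return B;
}

// recruitment kernel: row s, col n2 (n2 >= s): Pois(n2 - s | gamma)
static arma::mat recr_matrix(double gamma, int K) {
  arma::vec pois(K + 1);
  for (int k = 0; k <= K; ++k) pois(k) = R::dpois(k, gamma, 0);
  arma::mat G(K + 1, K + 1, arma::fill::zeros);
  for (int s = 0; s <= K; ++s)
    for (int n2 = s; n2 <= K; ++n2)
      G(s, n2) = pois(n2 - s);
  return G;
}

// [[Rcpp::export]]
arma::mat cpp_transition_matrix(double omega, double gamma, int K) {
  return surv_matrix(omega, K) * recr_matrix(gamma, K);
}

// multiply g(N), N = 0..K, by Binom(n | N, p) using the recursion
// Binom(n | N+1, p) = Binom(n | N, p) * (1-p) * (N+1) / (N+1-n),
// which avoids K density evaluations per observation
static inline void mult_binom_obs(arma::rowvec& g, int n, double p, int K) {
  for (int N = 0; N < n && N <= K; ++N) g(N) = 0.0;
  if (n > K) return;
  double val = std::pow(p, n);
  g(n) *= val;
  const double q = 1.0 - p;
  for (int N = n + 1; N <= K; ++N) {
    val *= q * (double)N / (double)(N - n);
    g(N) *= val;
  }
}

// counts, p: n_sites x (T*J), columns season-major (s1v1, s1v2, s2v1, ...)
// gamma: n_sites x (T-1); omega: length T-1; lambda: length n_sites
// mixture: 0 = Poisson, 1 = zero-inflated Poisson with weight psi on N=0
// [[Rcpp::export]]
double cpp_dyn_loglik(const arma::imat& counts, const arma::vec& lambda,
                      double psi, const arma::mat& gamma,
                      const arma::vec& omega, const arma::mat& p,
                      int K, int T, int J, int mixture) {
  const int n_sites = counts.n_rows;
  // refuse truncation below the data's support
  if (K < (int)counts.max()) return R_NegInf;

  // transition matrices: survival kernels depend only on omega_t;
  // recruitment depends on gamma_it. Cache per season when gamma is
  // constant across sites (the common candidate-set case).
  std::vector<arma::mat> B(T - 1);
  std::vector<bool> gamma_const(T - 1, false);
  std::vector<arma::mat> P_cached(T - 1);
  for (int t = 0; t < T - 1; ++t) {
    B[t] = surv_matrix(omega(t), K);
    gamma_const[t] =
        (n_sites == 0) ||
        (arma::abs(gamma.col(t) - gamma(0, t)).max() < 1e-300);
    if (gamma_const[t])
      P_cached[t] = B[t] * recr_matrix(gamma(0, t), K);
  }

  double ll = 0.0;
  arma::rowvec f(K + 1);
  for (int i = 0; i < n_sites; ++i) {
    // initial state times first-season detection
    for (int N = 0; N <= K; ++N) {
      double mix = R::dpois(N, lambda(i), 0);
      if (mixture == 1) mix = (N == 0 ? psi : 0.0) + (1.0 - psi) * mix;
      f(N) = mix;
    }
    for (int j = 0; j < J; ++j)
      mult_binom_obs(f, counts(i, j), p(i, j), K);
    for (int t = 1; t < T; ++t) {
      if (gamma_const[t - 1]) {
        f = f * P_cached[t - 1];
      } else {
        f = (f * B[t - 1]) * recr_matrix(gamma(i, t - 1), K);
      }
      for (int j = 0; j < J; ++j)
        mult_binom_obs(f, counts(i, t * J + j), p(i, t * J + j), K);
    }
    double Li = arma::accu(f);
    if (!(Li > 0.0)) return R_NegInf;
    ll += std::log(Li);
  }
  return ll;
}

// single-season likelihood: sum over N of mix(N) * prod_j Binom(n_j|N,p_j)
// counts, p: n_sites x J
// [[Rcpp::export]]
double cpp_single_loglik(const arma::imat& counts, const arma::vec& lambda,
                         double psi, const arma::mat& p, int K,
                         int mixture) {
  const int n_sites = counts.n_rows;
  const int J = counts.n_cols;
  if (K < (int)counts.max()) return R_NegInf;
  double ll = 0.0;
  arma::rowvec f(K + 1);
  for (int i = 0; i < n_sites; ++i) {
    for (int N = 0; N <= K; ++N) {
      double mix = R::dpois(N, lambda(i), 0);
      if (mixture == 1) mix = (N == 0 ? psi : 0.0) + (1.0 - psi) * mix;
      f(N) = mix;
    }
    for (int j = 0; j < J; ++j)
      mult_binom_obs(f, counts(i, j), p(i, j), K);
    double Li = arma::accu(f);
    if (!(Li > 0.0)) return R_NegInf;
    ll += std::log(Li);
  }
  return ll;
}
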