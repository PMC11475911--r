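// Marginalized Poisson log-likelihood of the base deconvolution model.
//
// For spot i and gene j, Y_ij ~ Poisson(N_i exp(alpha_i + eps) s_ij) with
// s_ij = sum_k theta_ik mu_kj and eps marginalized over a fixed quadrature
// grid (nodes, log-weights). Computes the total negative log-likelihood and,
// optionally, its gradient with respect to theta and alpha. This is the hot
// path of every fitting stage, hence compiled.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List glrm_negloglik_cpp(const arma::mat& theta, const arma::vec& alpha,
                              const arma::mat& Y, const arma::vec& N,
                              const arma::mat& mu, const arma::vec& nodes,
                              const arma::vec& logw, bool grad) {
  const uword I = Y.n_rows, G = Y.n_cols, M = nodes.n_elem;
  mat s = theta * mu;                       // I x G
  if (s.min() <= 0 || !s.is_finite()) {
    return Rcpp::List::create(
        Rcpp::Named("value") = R_PosInf,
        Rcpp::Named("dtheta") = mat(I, theta.n_cols, fill::zeros),
        Rcpp::Named("dalpha") = vec(I, fill::zeros));
  }
  mat base_lograte = log(s);
  base_lograte.each_col() += log(N) + alpha;      // I x G
  mat lgamY = Y;                                   // lgamma(Y + 1)
  lgamY.transform([](double y) { return std::lgamma(y + 1.0); });
  mat rate_base = exp(base_lograte);               // rate at eps = 0

  // log p_ijm = Y (base + node_m) - rate_base e^{node_m} - lgamma(Y+1) + logw_m
  mat fixed = Y % base_lograte - lgamY;            // node-independent part
  mat lse(I, G, fill::value(-datum::inf));
  cube terms(I, G, M);
  for (uword m = 0; m < M; ++m) {
    terms.slice(m) = fixed + nodes(m) * Y - std::exp(nodes(m)) * rate_base +
      logw(m);
    lse = max(lse, terms.slice(m));
  }
  mat acc(I, G, fill::zeros);
  for (uword m = 0; m < M; ++m) acc += exp(terms.slice(m) - lse);
  mat logmarg = lse + log(acc);
  double value = -accu(logmarg);

  if (!grad) {
    return Rcpp::List::create(Rcpp::Named("value") = value);
  }
  // d(-log marg)/d lograte = -E_posterior[Y - rate]
  mat dlograte(I, G, fill::zeros);
  for (uword m = 0; m < M; ++m) {
    mat post = exp(terms.slice(m) - logmarg);
    dlograte -= post % (Y - std::exp(nodes(m)) * rate_base);
  }
  mat ds = dlograte / s;
  mat dtheta = ds * mu.t();
  vec dalpha = sum(dlograte, 1);
  return Rcpp::List::create(Rcpp::Named("value") = value,
                            Rcpp::Named("dtheta") = dtheta,
                            Rcpp::Named("dalpha") = dalpha);
}
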