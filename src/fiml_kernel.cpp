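// Casewise (FIML) multivariate-normal log-likelihood over twin pairs.
// For each pair: subset the implied mean/covariance to the observed
// entries, add sex shifts to the mean, and accumulate the Gaussian
// log-density via a Cholesky solve.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Returns c(loglik, failIndex): failIndex is the 0-based index of the
// first pair whose pattern covariance has no Cholesky factor (loglik is
// then NA), or -1 on success.
// [[Rcpp::export]]
NumericVector fiml_kernel(const arma::vec& mu0,
                          const arma::vec& sexAddA,
                          const arma::vec& sexAddB,
                          const arma::mat& Sigma,
                          const List& obsIdx,
                          const List& obsVal,
                          const IntegerVector& sexA,
                          const IntegerVector& sexB) {
  const double log2pi = std::log(2.0 * M_PI);
  double ll = 0.0;
  const int n = obsIdx.size();
  for (int i = 0; i < n; ++i) {
    IntegerVector idxR = obsIdx[i];
    const int m = idxR.size();
    if (m == 0) continue;  // all-missing pair contributes 0
    arma::uvec idx(m);
    for (int j = 0; j < m; ++j) idx[j] = (arma::uword)idxR[j];
    arma::vec y = as<arma::vec>(obsVal[i]);
    arma::vec mu = mu0.elem(idx);
    if (sexA[i] == 1) mu += sexAddA.elem(idx);
    if (sexB[i] == 1) mu += sexAddB.elem(idx);
    arma::mat S = Sigma.submat(idx, idx);
    arma::mat Lc;
    if (!arma::chol(Lc, S, "lower"))
      return NumericVector::create(NA_REAL, (double)i);
    // reject numerically singular factors (near-zero pivot)
    if (Lc.diag().min() < 1e-12 * (1.0 + Lc.diag().max()))
      return NumericVector::create(NA_REAL, (double)i);
    arma::vec z;
    if (!arma::solve(z, arma::trimatl(Lc), y - mu,
                     arma::solve_opts::no_approx))
      return NumericVector::create(NA_REAL, (double)i);
    const double ldet = 2.0 * arma::accu(arma::log(Lc.diag()));
    ll += -0.5 * (m * log2pi + ldet + arma::dot(z, z));
  }
  return NumericVector::create(ll, -1.0);
}
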