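// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Full-covariance Gaussian-mixture EM for a fixed number of components,
// run from a given initial responsibility matrix to convergence
// (|delta log-likelihood| < tol) or max_iter. Collapsing covariances get a
// ridge (ridge_scale on the diagonal) and are flagged. Returns the
// per-iteration log-likelihood trace so monotonicity can be audited.
// The R wrapper owns restarts and initial responsibilities (seeded there).
// [[Rcpp::export(name = ".cpp_gmm_em")]]
List cpp_gmm_em(const arma::mat &x, arma::mat resp, double tol, int max_iter,
                double ridge_scale) {
  const int n = x.n_rows, d = x.n_cols, k = resp.n_cols;
  arma::mat means(k, d);
  arma::cube covs(d, d, k);
  arma::rowvec weights(k);
  bool regularized = false;
  std::vector<double> trace;
  double loglik = -arma::datum::inf, prev = -arma::datum::inf;
  arma::mat logdens(n, k);

  for (int it = 0; it < max_iter; ++it) {
    // M step
    for (int j = 0; j < k; ++j) {
      arma::vec w = resp.col(j);
      double sw = arma::accu(w);
      weights[j] = sw / n;
      arma::rowvec mu = (w.t() * x) / sw;
      arma::mat xc = x.each_row() - mu;
      arma::mat sig = (xc.each_col() % w).t() * xc / sw;
      arma::mat ch;
      if (!arma::chol(ch, sig) || sig.diag().min() < 1e-300) {
        sig.diag() += ridge_scale;
        regularized = true;
      }
      means.row(j) = mu;
      covs.slice(j) = sig;
    }
    // E step (log densities via Cholesky)
    for (int j = 0; j < k; ++j) {
      arma::mat ch;
      if (!arma::chol(ch, covs.slice(j))) {
        covs.slice(j).diag() += ridge_scale;
        regularized = true;
        arma::chol(ch, covs.slice(j));
      }
      arma::mat z = arma::solve(arma::trimatl(ch.t()),
                                (x.each_row() - means.row(j)).t());
      double logdet = arma::accu(arma::log(ch.diag()));
      logdens.col(j) = (-0.5 * arma::sum(arma::square(z), 0)).t() -
                       logdet - 0.5 * d * std::log(2.0 * arma::datum::pi) +
                       std::log(weights[j]);
    }
    arma::vec m = arma::max(logdens, 1);
    arma::vec lse = m + arma::log(arma::sum(arma::exp(logdens.each_col() - m), 1));
    loglik = arma::accu(lse);
    trace.push_back(loglik);
    resp = arma::exp(logdens.each_col() - lse);
    if (std::isfinite(prev) && std::fabs(loglik - prev) < tol) break;
    prev = loglik;
  }
  return List::create(_["weights"] = weights, _["means"] = means,
                      _["covs"] = covs, _["loglik"] = loglik,
                      _["trace"] = trace, _["regularized"] = regularized);
}
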