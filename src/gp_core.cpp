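// Gaussian-process core: ARD kernels, negative log marginal likelihood and
// posterior predictive, kept in compiled code because model evaluation runs
// thousands of repeated fits during cross-validation.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// kernel_type: 0 = squared exponential, 1 = Matern 3/2 (both ARD)
static arma::mat kernel_mat(const arma::mat& X1, const arma::mat& X2,
                            const arma::vec& ell, double sf2, int kernel_type) {
  arma::mat D2(X1.n_rows, X2.n_rows, arma::fill::zeros);
  for (arma::uword d = 0; d < X1.n_cols; ++d) {
    arma::vec a = X1.col(d) / ell(d);
    arma::rowvec b = (X2.col(d) / ell(d)).t();
    arma::mat diff = arma::repmat(a, 1, X2.n_rows);
    diff.each_row() -= b;
    D2 += arma::square(diff);
  }
  if (kernel_type == 0) {
    return sf2 * arma::exp(-0.5 * D2);
  }
  arma::mat r = std::sqrt(3.0) * arma::sqrt(D2);
  return sf2 * (1.0 + r) % arma::exp(-r);
}

// logtheta = (log sf2, log ell_1..ell_d, log sn2)
// [[Rcpp::export]]
double gp_nll_cpp(const arma::vec& logtheta, const arma::mat& X,
                  const arma::vec& y, double prior_mean, int kernel_type) {
  const arma::uword n = X.n_rows, d = X.n_cols;
  const double sf2 = std::exp(logtheta(0));
  const arma::vec ell = arma::exp(logtheta.subvec(1, d));
  const double sn2 = std::exp(logtheta(d + 1));

  arma::mat K = kernel_mat(X, X, ell, sf2, kernel_type);
  K.diag() += sn2 + 1e-10 * sf2;
  arma::mat L;
  if (!arma::chol(L, K, "lower")) return 1e10;
  arma::vec yc = y - prior_mean;
  arma::vec alpha = arma::solve(arma::trimatu(L.t()),
                                arma::solve(arma::trimatl(L), yc));
  double nll = 0.5 * arma::dot(yc, alpha) +
               arma::accu(arma::log(L.diag())) +
               0.5 * n * std::log(2.0 * M_PI);
  if (!std::isfinite(nll)) return 1e10;
  return nll;
}

// Stochastic hyperparameter search: annealed greedy random walk around the
// incumbent with occasional uniform restarts, driven by R's RNG so results
// are reproducible under set.seed(). Returns the best log-theta and nll.
// [[Rcpp::export]]
List gp_search_cpp(const arma::vec& start, const arma::vec& lower,
                   const arma::vec& upper, int n_iter, const arma::mat& X,
                   const arma::vec& y, double prior_mean, int kernel_type) {
  RNGScope scope;
  const arma::uword p = start.n_elem;
  arma::vec rng = upper - lower;
  arma::vec best = start;
  double best_nll = gp_nll_cpp(best, X, y, prior_mean, kernel_type);
  arma::vec prop(p);
  for (int it = 1; it <= n_iter; ++it) {
    if (R::runif(0.0, 1.0) < 0.2) {
      for (arma::uword j = 0; j < p; ++j) {
        prop(j) = lower(j) + R::runif(0.0, 1.0) * rng(j);
      }
    } else {
      double scale = 0.5 * (1.0 - double(it) / n_iter) + 0.02;
      for (arma::uword j = 0; j < p; ++j) {
        prop(j) = best(j) + R::norm_rand() * scale * rng(j);
        if (prop(j) < lower(j)) prop(j) = lower(j);
        if (prop(j) > upper(j)) prop(j) = upper(j);
      }
    }
    double f = gp_nll_cpp(prop, X, y, prior_mean, kernel_type);
    if (f < best_nll) {
      best = prop;
      best_nll = f;
    }
  }
  return List::create(_["par"] = best, _["value"] = best_nll);
}

// Posterior mean and epistemic variance on new inputs Xs.
// Handles n = 0 (prior: mean = prior_mean, var = sf2).
// [[Rcpp::export]]
List gp_predict_cpp(const arma::vec& logtheta, const arma::mat& X,
                    const arma::vec& y, double prior_mean,
                    const arma::mat& Xs, int kernel_type) {
  const arma::uword d = Xs.n_cols;
  const double sf2 = std::exp(logtheta(0));
  const arma::vec ell = arma::exp(logtheta.subvec(1, d));
  const double sn2 = std::exp(logtheta(d + 1));

  if (X.n_rows == 0) {
    arma::vec mu(Xs.n_rows, arma::fill::value(prior_mean));
    arma::vec v(Xs.n_rows, arma::fill::value(sf2));
    return List::create(_["mean"] = mu, _["var"] = v, _["noise_var"] = sn2);
  }

  arma::mat K = kernel_mat(X, X, ell, sf2, kernel_type);
  K.diag() += sn2 + 1e-10 * sf2;
  arma::mat L = arma::chol(K, "lower");
  arma::vec yc = y - prior_mean;
  arma::vec alpha = arma::solve(arma::trimatu(L.t()),
                                arma::solve(arma::trimatl(L), yc));
  arma::mat Ks = kernel_mat(X, Xs, ell, sf2, kernel_type); // n x m
  arma::vec mu = prior_mean + Ks.t() * alpha;
  arma::mat V = arma::solve(arma::trimatl(L), Ks);         // n x m
  arma::vec var = sf2 - arma::sum(arma::square(V), 0).t();
  var = arma::clamp(var, 0.0, arma::datum::inf);
  return List::create(_["mean"] = mu, _["var"] = var, _["noise_var"] = sn2);
}
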