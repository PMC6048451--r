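// EM for a k-component Gaussian mixture with per-component diagonal
// covariance, over samples-in-rows data. Initialisation is from random
// responsibilities drawn with R's RNG, so results are reproducible under
// set.seed() from the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".em_diag_gauss_cpp")]]
List em_diag_gauss_cpp(const arma::mat& Y, const int k,
                       const int max_iter, const double tol,
                       const double var_floor) {
  const arma::uword n = Y.n_rows, G = Y.n_cols;
  const double log2pi = std::log(2.0 * M_PI);

  // random responsibilities via R's RNG (row-normalised)
  arma::mat R(n, k);
  for (arma::uword i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < k; ++j) { R(i, j) = R::runif(0.0, 1.0); s += R(i, j); }
    R.row(i) /= s;
  }

  const arma::mat Y2 = arma::square(Y);
  arma::rowvec w(k);
  arma::mat Mu(k, G), V(k, G);
  arma::vec trace_ll(max_iter);
  double ll = -arma::datum::inf, ll_old = -arma::datum::inf;
  bool converged = false;
  int iters = 0;

  for (int iter = 0; iter < max_iter; ++iter) {
    // M step
    arma::rowvec nk = arma::sum(R, 0);
    nk.transform([](double v) { return v < 1e-12 ? 1e-12 : v; });
    w = nk / (double) n;
    Mu = (R.t() * Y);  Mu.each_col() /= nk.t();
    V  = (R.t() * Y2); V.each_col() /= nk.t();
    V -= arma::square(Mu);
    V.transform([var_floor](double v) { return v < var_floor ? var_floor : v; });

    // E step: log densities + log weights
    arma::mat iV = 1.0 / V;                      // k x G
    arma::mat A = Y2 * iV.t();                   // n x k
    arma::mat B = Y * (Mu % iV).t();             // n x k
    arma::rowvec cst = arma::sum(arma::square(Mu) % iV, 1).t()
      + arma::sum(arma::log(V), 1).t() + G * log2pi;
    arma::mat L = -0.5 * A + B;
    L.each_row() += (-0.5 * cst + arma::log(w));

    arma::vec m = arma::max(L, 1);
    arma::vec lse = m + arma::log(arma::sum(arma::exp(L.each_col() - m), 1));
    ll = arma::accu(lse);
    trace_ll(iter) = ll;
    iters = iter + 1;
    R = arma::exp(L.each_col() - lse);

    if (std::isfinite(ll_old) && ll - ll_old < tol) { converged = true; break; }
    ll_old = ll;
  }

  // hard labels: argmax posterior, ties toward the lower component index
  IntegerVector labels(n);
  for (arma::uword i = 0; i < n; ++i) {
    int best = 0; double bv = R(i, 0);
    for (int j = 1; j < k; ++j) if (R(i, j) > bv) { bv = R(i, j); best = j; }
    labels[i] = best + 1;
  }

  bool degenerate = arma::any(w < 1.0 / (double) n);
  if (!degenerate) {
    for (int j = 0; j < k && !degenerate; ++j) {
      degenerate = arma::all(V.row(j) <= var_floor * (1.0 + 1e-9));
    }
  }

  return List::create(
    _["k"] = k,
    _["weights"] = NumericVector(w.begin(), w.end()),
    _["means"] = Mu,
    _["variances"] = V,
    _["log_likelihood"] = ll,
    _["posteriors"] = R,
    _["labels"] = labels,
    _["loglik_trace"] = NumericVector(trace_ll.begin(),
                                      trace_ll.begin() + iters),
    _["degenerate"] = degenerate,
    _["converged"] = converged);
}
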