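#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Penalised Poisson regression with log link by cyclic coordinate descent.
// Outer loop: iteratively-reweighted quadratic approximation at the current
// linear predictor. Inner loop: cyclic coordinate sweeps on that quadratic,
// using precomputed weighted Gram products ("covariance updates") so a
// sweep costs O(k^2) regardless of the number of genes. The intercept is
// unpenalised, so the score equation sum(y) = sum(fitted) holds at
// convergence. Linear predictors are clamped to [-30, 30].

static void poisson_cd_fit(const arma::vec &y, const arma::mat &F,
                           double ridge, int max_iter, double tol,
                           double &beta0, arma::vec &beta, bool &converged,
                           int &iters) {
  const arma::uword g = y.n_elem, k = F.n_cols;
  converged = false;
  iters = 0;
  beta.zeros(k);
  const double ysum = arma::accu(y);
  if (ysum <= 0.0) {            // degenerate all-zero response
    beta0 = -30.0;
    converged = true;
    return;
  }
  beta0 = std::log(ysum / g);

  arma::vec eta(g), mu(g), w(g), z(g), sw(g);
  for (int it = 0; it < max_iter; ++it) {
    iters = it + 1;
    eta = beta0 + F * beta;
    eta.clamp(-30.0, 30.0);
    mu = arma::exp(eta);
    w = mu;
    z = eta + (y - mu) / mu;    // working response
    sw = arma::sqrt(w);
    // weighted Gram products for the quadratic subproblem
    arma::mat Fw = F.each_col() % sw;
    arma::mat G = Fw.t() * Fw;                 // k x k
    arma::vec Fwz = F.t() * (w % z);           // k
    arma::vec Fw1 = F.t() * w;                 // k (intercept column)
    double wsum = arma::accu(w);
    double wz = arma::dot(w, z);
    // cyclic coordinate sweeps to (near-)exact quadratic solution
    double b0_old_outer = beta0;
    arma::vec b_old_outer = beta;
    const double inner_tol = std::max(tol * 1e-2, 1e-13);
    for (int sweep = 0; sweep < 1000; ++sweep) {
      double change = 0.0;
      for (arma::uword j = 0; j < k; ++j) {
        // partial residual projection for coordinate j
        double num = Fwz(j) - Fw1(j) * beta0 - arma::dot(G.col(j), beta)
                     + G(j, j) * beta(j);
        double denom = G(j, j) + ridge;
        double bnew = denom > 0.0 ? num / denom : 0.0;
        double d = std::fabs(bnew - beta(j));
        if (d > change) change = d;
        beta(j) = bnew;
      }
      double b0new = (wz - arma::dot(Fw1, beta)) / wsum;
      double d0 = std::fabs(b0new - beta0);
      if (d0 > change) change = d0;
      beta0 = b0new;
      if (change < inner_tol) break;
    }
    double outer_change = std::fabs(beta0 - b0_old_outer);
    if (k > 0) {
      double bc = arma::abs(beta - b_old_outer).max();
      if (bc > outer_change) outer_change = bc;
    }
    if (outer_change < tol) {
      converged = true;
      break;
    }
  }
}

// [[Rcpp::export(name = ".cpp_poisson_cd")]]
List cpp_poisson_cd(arma::vec y, arma::mat F, double ridge, int max_iter,
                    double tol) {
  if (F.n_rows != y.n_elem && F.n_cols > 0) stop("nrow(F) != length(y)");
  double beta0 = 0.0;
  arma::vec beta;
  bool conv = false;
  int iters = 0;
  poisson_cd_fit(y, F, ridge, max_iter, tol, beta0, beta, conv, iters);
  arma::vec eta(y.n_elem);
  if (F.n_cols > 0) eta = beta0 + F * beta; else eta.fill(beta0);
  eta.clamp(-30.0, 30.0);
  arma::vec fitted = arma::exp(eta);
  return List::create(_["beta0"] = beta0,
                      _["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["fitted"] = NumericVector(fitted.begin(),
                                                  fitted.end()),
                      _["converged"] = conv, _["iterations"] = iters);
}

// Batch counterfactual imputation: for each cell j, build the feature
// matrix F = log1p(Y[, matched cells]) from its matched opposite-condition
// cells, regress the observed column on it, return exp(F beta + beta0).
// idx is k x J, 1-based, NA-padded.
// [[Rcpp::export(name = ".cpp_impute_poisson")]]
List cpp_impute_poisson(const arma::mat &Y, IntegerMatrix idx, double ridge,
                        int max_iter, double tol) {
  const arma::uword g = Y.n_rows, J = Y.n_cols;
  const int kmax = idx.nrow();
  if ((arma::uword)idx.ncol() != J) stop("ncol(idx) != ncol(Y)");
  arma::mat yhat(g, J);
  NumericMatrix coef(kmax + 1, J);
  std::fill(coef.begin(), coef.end(), NA_REAL);
  LogicalVector conv(J);
  const arma::mat Fall = arma::log1p(Y);   // feature transform, shared
  for (arma::uword j = 0; j < J; ++j) {
    int k = 0;
    while (k < kmax && idx(k, j) != NA_INTEGER) ++k;
    if (k == 0) stop("cell has zero matched cells");
    arma::uvec ids(k);
    for (int m = 0; m < k; ++m) {
      int c = idx(m, j) - 1;
      if (c < 0 || (arma::uword)c >= J) stop("matched index out of range");
      ids(m) = (arma::uword)c;
    }
    arma::mat F = Fall.cols(ids);
    double beta0 = 0.0;
    arma::vec beta;
    bool cv = false;
    int iters = 0;
    poisson_cd_fit(Y.col(j), F, ridge, max_iter, tol, beta0, beta, cv,
                   iters);
    conv[j] = cv;
    coef(0, j) = beta0;
    for (int m = 0; m < k; ++m) coef(m + 1, j) = beta(m);
    arma::vec eta = beta0 + F * beta;
    eta.clamp(-30.0, 30.0);
    yhat.col(j) = arma::exp(eta);
  }
  return List::create(_["yhat"] = wrap(yhat), _["coef"] = coef,
                      _["converged"] = conv);
}
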