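// Inner solver for the penalized varying-coefficient normal equations.
//
// The design matrix X holds one B-spline block per smooth (intercept smooth
// plus one varying-coefficient smooth per lagged predictor), each of k
// columns.  For smoothing parameters lambda_1..lambda_B the solve is
//
//   (X'X + sum_b lambda_b S~_b) alpha = X'y
//
// where S~_b embeds the k x k difference penalty S into block b.  Everything
// needed by the GCV search (alpha, RSS, per-block and total effective degrees
// of freedom, GCV score) is computed from the precomputed cross-products
// X'X, X'y, y'y, so one evaluation costs O(p^3) with p = B*k, independent of
// the number of rows.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List pen_fit_cpp(const arma::mat& XtX,
                       const arma::vec& Xty,
                       double yty,
                       int n,
                       const arma::mat& S,
                       const arma::vec& lambda,
                       bool want_cov) {
  const int k = S.n_rows;
  const int nb = lambda.n_elem;
  const int p = XtX.n_rows;
  if (nb * k != p)
    Rcpp::stop("design has %d columns but %d blocks of %d were implied", p, nb, k);

  mat M = XtX;
  for (int b = 0; b < nb; ++b) {
    const int a = b * k;
    M.submat(a, a, a + k - 1, a + k - 1) += lambda[b] * S;
  }

  mat R;
  if (!chol(R, M) || R.diag().min() < 1e-10 * R.diag().max()) {
    return Rcpp::List::create(Rcpp::Named("ok") = false);
  }

  // alpha = M^{-1} X'y ; F = M^{-1} X'X (its trace is the edf / hat trace)
  vec alpha = solve(trimatu(R), solve(trimatl(R.t()), Xty));
  mat F = solve(trimatu(R), solve(trimatl(R.t()), XtX));

  vec edf(nb);
  for (int b = 0; b < nb; ++b) {
    const int a = b * k;
    edf[b] = trace(F.submat(a, a, a + k - 1, a + k - 1));
  }
  double total_edf = trace(F);

  double rss = yty - 2.0 * dot(alpha, Xty) + dot(alpha, XtX * alpha);
  if (rss < 0.0) rss = 0.0;  // guard against rounding on near-perfect fits

  double denom = static_cast<double>(n) - total_edf;
  double gcv = (denom > 1e-10) ? n * rss / (denom * denom) : R_PosInf;

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("ok") = true,
    Rcpp::Named("alpha") = alpha,
    Rcpp::Named("edf") = edf,
    Rcpp::Named("total_edf") = total_edf,
    Rcpp::Named("rss") = rss,
    Rcpp::Named("gcv") = gcv);

  if (want_cov) {
    mat Minv;
    if (!inv_sympd(Minv, M)) Minv = pinv(M);
    out["Minv"] = Minv;
  }
  return out;
}

// GCV score only: the objective of the smoothing-parameter search.
// [[Rcpp::export]]
double pen_gcv_cpp(const arma::mat& XtX,
                   const arma::vec& Xty,
                   double yty,
                   int n,
                   const arma::mat& S,
                   const arma::vec& lambda,
                   double gamma) {
  const int k = S.n_rows;
  const int nb = lambda.n_elem;
  mat M = XtX;
  for (int b = 0; b < nb; ++b) {
    const int a = b * k;
    M.submat(a, a, a + k - 1, a + k - 1) += lambda[b] * S;
  }
  mat R;
  if (!chol(R, M) || R.diag().min() < 1e-10 * R.diag().max()) return R_PosInf;
  vec alpha = solve(trimatu(R), solve(trimatl(R.t()), Xty));
  mat F = solve(trimatu(R), solve(trimatl(R.t()), XtX));
  double total_edf = trace(F);
  double rss = yty - 2.0 * dot(alpha, Xty) + dot(alpha, XtX * alpha);
  if (rss < 0.0) rss = 0.0;
  double denom = static_cast<double>(n) - gamma * total_edf;
  if (denom <= 1e-10) return R_PosInf;
  return n * rss / (denom * denom);
}
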