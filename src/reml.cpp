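// Profiled REML criterion for the crossed random-intercept model.
//
// With V0 = I + Z G Z' (G diagonal with variance ratios gamma per block),
// the Woodbury identity reduces everything to the q x q system
// M = I + G^{1/2} Z'Z G^{1/2}, so one evaluation costs O(q^3) regardless
// of the number of samples. The random-effect columns arrive grouped into
// connected components (experiments nest in tissues in practice), making
// M block-diagonal; the factorization then runs blockwise, one small
// Cholesky per component. A fully crossed design is simply one component.
// Inputs are wrapped as no-copy views: the optimizer calls this hundreds
// of times per probeset.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using Rcpp::NumericMatrix;
using Rcpp::NumericVector;
using Rcpp::IntegerVector;

// theta: log variance ratios (one per random-effect block)
// ZtZ: q x q crossproduct of the random-effect design (component order)
// B0:  q x 3 matrix cbind(Z'X, Z'y)
// XtX: 2 x 2, xty: length 2, yty: scalar, block: 0-based block per column
// comp_sizes: sizes of the diagonal blocks of M (sum = q)
// n:   number of observations
// [[Rcpp::export(name = ".remlCritCpp")]]
double reml_crit_cpp(NumericVector theta, NumericMatrix ZtZ_,
                     NumericMatrix B0_, NumericMatrix XtX_,
                     NumericVector xty, double yty,
                     IntegerVector block, IntegerVector comp_sizes, int n) {
  const arma::uword q = ZtZ_.nrow();
  const arma::mat ZtZ(ZtZ_.begin(), q, q, false, true);
  const arma::mat B0(B0_.begin(), q, 3, false, true);

  arma::vec s(q);
  {
    double g[8];
    const int nb = theta.size();
    for (int r = 0; r < nb; ++r) g[r] = std::sqrt(std::exp(theta[r]));
    for (arma::uword j = 0; j < q; ++j) s[j] = g[block[j]];
  }

  arma::mat A(q, 3);
  double logdetM = 0.0;
  arma::uword off = 0;
  for (int c = 0; c < comp_sizes.size(); ++c) {
    const arma::uword m = (arma::uword) comp_sizes[c];
    const arma::vec sb = s.subvec(off, off + m - 1);
    arma::mat Mb = ZtZ.submat(off, off, off + m - 1, off + m - 1);
    Mb.each_col() %= sb;
    Mb.each_row() %= sb.t();
    Mb.diag() += 1.0;
    arma::mat Cb;
    if (!arma::chol(Cb, Mb)) return 1e12;  // numerically indefinite: reject
    logdetM += 2.0 * arma::sum(arma::log(Cb.diag()));
    arma::mat Bb = B0.rows(off, off + m - 1);
    Bb.each_col() %= sb;
    A.rows(off, off + m - 1) = arma::solve(arma::trimatl(Cb.t()), Bb);
    off += m;
  }

  double x11 = XtX_(0, 0) - arma::dot(A.col(0), A.col(0));
  double x12 = XtX_(0, 1) - arma::dot(A.col(0), A.col(1));
  double x22 = XtX_(1, 1) - arma::dot(A.col(1), A.col(1));
  double v1 = xty[0] - arma::dot(A.col(0), A.col(2));
  double v2 = xty[1] - arma::dot(A.col(1), A.col(2));
  double det2 = x11 * x22 - x12 * x12;
  if (det2 <= 0.0) return 1e12;
  double b1 = (x22 * v1 - x12 * v2) / det2;
  double b2 = (x11 * v2 - x12 * v1) / det2;
  double rss = yty - arma::dot(A.col(2), A.col(2)) - b1 * v1 - b2 * v2;
  if (rss < 1e-12) rss = 1e-12;

  return logdetM + std::log(det2) + (n - 2.0) * std::log(rss);
}
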