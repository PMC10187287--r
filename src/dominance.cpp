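#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// All-subsets R^2 and total-dominance shares from cross-moment matrices.
//
// Cxx: p x p centered cross-products of the predictors (t(Xc) %*% Xc);
// Cxy: p x n centered cross-products with each of n targets;
// vy:  length-n centered sums of squares of the targets.
//
// Subsets are indexed by bitmask; R2 of the empty model is 0. The total
// dominance of predictor x is the average, over subset sizes s, of the mean
// incremental R^2 from adding x to every size-s subset not containing x,
// i.e. sum over subsets S (x not in S) of [R2(S+x) - R2(S)] / (p * C(p-1, |S|)).
//
// [[Rcpp::export]]
Rcpp::List cpp_dominance(const arma::mat& Cxx, const arma::mat& Cxy,
                         const arma::vec& vy, const bool keep_subsets = false) {
  const uword p = Cxx.n_rows;
  const uword n = Cxy.n_cols;
  if (p == 0 || p > 20) Rcpp::stop("predictor count out of range");
  const uword m = (uword(1) << p);

  mat R2(m, n, fill::zeros);
  rowvec vyi = vy.t();
  vyi.transform([](double v) { return v > 0.0 ? 1.0 / v : 0.0; });

  for (uword mask = 1; mask < m; ++mask) {
    uvec ids(static_cast<uword>(__builtin_popcount(mask)));
    uword k = 0;
    for (uword x = 0; x < p; ++x)
      if (mask & (uword(1) << x)) ids(k++) = x;
    mat A = Cxx.submat(ids, ids);
    mat C = Cxy.rows(ids);
    mat B;
    if (!solve(B, A, C, solve_opts::no_approx))
      Rcpp::stop("rank-deficient predictor subset");
    R2.row(mask) = sum(C % B, 0) % vyi;
  }

  vec w(p);
  for (uword s = 0; s < p; ++s)
    w(s) = 1.0 / (double(p) * ::Rf_choose(double(p) - 1.0, double(s)));

  mat dom(p, n, fill::zeros);
  for (uword mask = 0; mask < m; ++mask) {
    const uword s = static_cast<uword>(__builtin_popcount(mask));
    const double ws = w(s < p ? s : p - 1);
    for (uword x = 0; x < p; ++x) {
      const uword bit = (uword(1) << x);
      if (mask & bit) continue;
      dom.row(x) += ws * (R2.row(mask | bit) - R2.row(mask));
    }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("full_r2") = R2.row(m - 1).t(),
      Rcpp::Named("dominance") = dom);
  if (keep_subsets) out["subset_r2"] = R2;
  return out;
}

// Full-model R^2 only, for many (predictor-set, target) combinations.
// Xall: parcels x (p * nsets) column-bound predictor sets; Y: parcels x n
// targets. Both are centered by the caller. Returns nsets x n matrix of R^2.
// [[Rcpp::export]]
arma::mat cpp_block_r2(const arma::mat& Xall, const arma::mat& Y,
                       const int p) {
  const uword np = uword(p);
  if (np == 0 || Xall.n_cols % np != 0) Rcpp::stop("bad block width");
  const uword nsets = Xall.n_cols / np;
  const uword n = Y.n_cols;
  rowvec vy = sum(square(Y), 0);
  vy.transform([](double v) { return v > 0.0 ? 1.0 / v : 0.0; });

  mat out(nsets, n);
  for (uword k = 0; k < nsets; ++k) {
    mat X = Xall.cols(k * np, (k + 1) * np - 1);
    mat A = X.t() * X;
    mat C = X.t() * Y;
    mat B;
    if (!solve(B, A, C, solve_opts::no_approx))
      Rcpp::stop("rank-deficient predictor set");
    out.row(k) = sum(C % B, 0) % vy;
  }
  return out;
}
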