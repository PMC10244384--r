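#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// R^2 of an OLS fit (with intercept) of y on every k-subset of the 20 feature
// columns, computed from the centered Gram matrix G = Xc'Xc and moment vector
// v = Xc'yc. Subsets are enumerated in lexicographic order; rank-deficient
// subsets yield NA. Returns one numeric vector per requested size.
// [[Rcpp::export]]
List subset_r2_scan(const arma::mat& G, const arma::vec& v, double ss_y,
                    IntegerVector sizes) {
  const int p = G.n_rows;
  List out(sizes.size());
  for (int si = 0; si < sizes.size(); ++si) {
    const int k = sizes[si];
    // number of combinations C(p, k)
    double nc = 1.0;
    for (int i = 0; i < k; ++i) nc = nc * (p - i) / (i + 1);
    const R_xlen_t n_comb = (R_xlen_t) std::llround(nc);
    NumericVector r2(n_comb);

    std::vector<int> idx(k);
    for (int i = 0; i < k; ++i) idx[i] = i;
    arma::uvec u(k);
    R_xlen_t pos = 0;
    while (true) {
      for (int i = 0; i < k; ++i) u[i] = idx[i];
      arma::mat Gs = G.submat(u, u);
      arma::vec vs = v.elem(u);
      arma::vec beta;
      bool ok = arma::solve(beta, Gs, vs,
                            arma::solve_opts::no_approx);
      r2[pos++] = ok ? arma::dot(vs, beta) / ss_y : NA_REAL;

      // next lexicographic combination
      int i = k - 1;
      while (i >= 0 && idx[i] == p - k + i) --i;
      if (i < 0) break;
      ++idx[i];
      for (int j = i + 1; j < k; ++j) idx[j] = idx[j - 1] + 1;
    }
    out[si] = r2;
  }
  return out;
}
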