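#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Run the MVAR recursion x_t = sum_r A_r x_{t-r} + e_t over a pre-drawn
// innovation matrix E (samples x channels). Innovations are generated in R so
// set.seed() governs reproducibility; only the sequential loop lives here.
// A is channels x channels x order. Initial condition: zeros before t = 0
// (callers discard a burn-in long enough for the transient to die).
// [[Rcpp::export]]
arma::mat mvar_filter_cpp(const arma::cube& A, const arma::mat& E) {
  const arma::uword p = A.n_slices;
  const arma::uword n = E.n_rows;
  arma::mat X = E; // start from the innovations, add the AR part in place
  for (arma::uword t = 0; t < n; ++t) {
    for (arma::uword r = 1; r <= p && r <= t; ++r) {
      X.row(t) += X.row(t - r) * A.slice(r - 1).t();
    }
  }
  return X;
}
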