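// Frequency-response stack for the delay linear state space:
//   M(w) = i w I - sum_d A_d exp(-i w delta_d)
//   out(., ., k) = V * M(w_k)^{-1} * B
// The hot loop of the spectral forward model; the plain-R
// transfer_matrix() computes the same quantity and serves as its
// cross-check in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::cx_cube transfer_stack_cpp(const arma::cube& A, const arma::vec& delays,
                                 const arma::mat& B, const arma::mat& V,
                                 const arma::vec& omega) {
  const arma::uword nx = A.n_rows, nd = A.n_slices, nw = omega.n_elem;
  arma::cx_cube out(V.n_rows, B.n_cols, nw);
  arma::cx_mat M(nx, nx);
  const arma::cx_mat Bc = arma::conv_to<arma::cx_mat>::from(B);
  const arma::cx_mat Vc = arma::conv_to<arma::cx_mat>::from(V);
  for (arma::uword k = 0; k < nw; ++k) {
    const double w = omega[k];
    M.zeros();
    M.diag() += arma::cx_double(0.0, w);
    for (arma::uword d = 0; d < nd; ++d) {
      const arma::cx_double ph = std::exp(arma::cx_double(0.0, -w * delays[d]));
      M -= ph * A.slice(d);
    }
    arma::cx_mat X;
    if (!arma::solve(X, M, Bc, arma::solve_opts::fast))
      Rcpp::stop("transfer matrix singular at omega = %g rad/s", w);
    out.slice(k) = Vc * X;
  }
  return out;
}
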