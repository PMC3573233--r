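// Fused cross-spectral prediction kernel:
//   S(w) = gu(w) * T(w) T(w)^H + gc(w) I,
//   T(w) = C (iwI - sum_d A_d e^{-iw delta_d})^{-1} B
// The Jacobian blocks are sparse (~100 nonzeros in a 32x32 system), so
// M(w) is assembled by scattering precollected triplets.  Also the VAR(p)
// spectral matrix H E H^H used by the data-feature transform.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::cx_cube csd_stack_cpp(const arma::cube& A, const arma::vec& delays,
                            const arma::mat& B, const arma::mat& C,
                            const arma::vec& omega, const arma::vec& gu,
                            const arma::vec& gc) {
  const arma::uword nx = A.n_rows, nd = A.n_slices, nw = omega.n_elem,
    nch = C.n_rows;
  // collect nonzero triplets per delay block
  std::vector<std::vector<arma::uword>> ri(nd), ci(nd);
  std::vector<std::vector<double>> av(nd);
  for (arma::uword d = 0; d < nd; ++d)
    for (arma::uword j = 0; j < nx; ++j)
      for (arma::uword i = 0; i < nx; ++i)
        if (A(i, j, d) != 0.0) {
          ri[d].push_back(i); ci[d].push_back(j); av[d].push_back(A(i, j, d));
        }
  const arma::cx_mat Bc = arma::conv_to<arma::cx_mat>::from(B);
  const arma::cx_mat Cc = arma::conv_to<arma::cx_mat>::from(C);
  arma::cx_cube out(nch, nch, nw);
  arma::cx_mat M(nx, nx);
  for (arma::uword k = 0; k < nw; ++k) {
    const double w = omega[k];
    M.zeros();
    M.diag() += arma::cx_double(0.0, w);
    for (arma::uword d = 0; d < nd; ++d) {
      const arma::cx_double ph = std::exp(arma::cx_double(0.0, -w * delays[d]));
      const std::size_t nnz = av[d].size();
      for (std::size_t t = 0; t < nnz; ++t)
        M(ri[d][t], ci[d][t]) -= ph * av[d][t];
    }
    arma::cx_mat X;
    if (!arma::solve(X, M, Bc, arma::solve_opts::fast))
      Rcpp::stop("transfer matrix singular at omega = %g rad/s", w);
    const arma::cx_mat T = Cc * X;
    out.slice(k) = gu[k] * (T * T.t());   // .t() on cx_mat = conjugate transpose
    out.slice(k).diag() += gc[k];
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List var_spec_cpp(const arma::cube& Acoef, const arma::mat& E,
                        const arma::vec& freqs, const double fs) {
  const arma::uword d = Acoef.n_rows, p = Acoef.n_slices, nf = freqs.n_elem;
  const arma::cx_mat Ec = arma::conv_to<arma::cx_mat>::from(E);
  arma::cx_cube out(d, d, nf);
  std::vector<double> flagged;
  arma::cx_mat Ap(d, d);
  for (arma::uword i = 0; i < nf; ++i) {
    const arma::cx_double z =
      std::exp(arma::cx_double(0.0, -2.0 * M_PI * freqs[i] / fs));
    Ap.eye(d, d);
    arma::cx_double zk(1.0, 0.0);
    for (arma::uword k = 0; k < p; ++k) {
      zk *= z;
      Ap -= zk * arma::conv_to<arma::cx_mat>::from(Acoef.slice(k));
    }
    if (arma::rcond(Ap) < 1e-10) flagged.push_back(freqs[i]);
    arma::cx_mat H;
    if (!arma::inv(H, Ap))
      Rcpp::stop("AR polynomial singular at %g Hz", freqs[i]);
    out.slice(i) = H * Ec * H.t();
  }
  return Rcpp::List::create(Rcpp::Named("S") = out,
                            Rcpp::Named("flagged") = flagged);
}
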