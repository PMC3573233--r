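// Stochastic Heun integration of the delay linear stochastic system
//   dx = (sum_d A_d x(t - delta_d)) dt + B u(t) dt
// The drift uses a predictor-corrector (improved Euler) step, which
// removes the O(dt) damping bias a plain forward-Euler step leaves in
// resonance peaks; the additive innovation forcing enters as in
// Euler-Maruyama.  Delays are applied through a ring buffer of past
// states (rounded to the integration step); innovations are pre-generated
// in R so seeding and spectral content stay under R's control.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::mat euler_sim_cpp(const arma::cube& A, const arma::vec& delays,
                        const arma::mat& B, const arma::mat& innov,
                        const double dt, const int nkeep) {
  const arma::uword nx = A.n_rows, nd = A.n_slices, nsteps = innov.n_cols;
  arma::uvec lags(nd);
  arma::uword maxlag = 0;
  for (arma::uword d = 0; d < nd; ++d) {
    lags[d] = (arma::uword) std::lround(delays[d] / dt);
    if (lags[d] > maxlag) maxlag = lags[d];
  }
  const arma::uword ring = maxlag + 2;
  arma::mat buf(nx, ring, arma::fill::zeros);
  arma::mat out(nx, nsteps / nkeep);
  arma::vec x(nx, arma::fill::zeros), drift1(nx), drift2(nx), xstar(nx),
    force(nx);
  arma::uword kout = 0;
  // delayed-state lookup: state at time step s (s <= t), zero before start
  auto delayed = [&](arma::sword s) -> arma::vec {
    if (s < 0) return arma::vec(nx, arma::fill::zeros);
    return buf.col(((arma::uword) s) % ring);
  };
  for (arma::uword t = 0; t < nsteps; ++t) {
    buf.col(t % ring) = x;                 // x is the state at time t
    force = B * innov.col(t);
    drift1.zeros();
    for (arma::uword d = 0; d < nd; ++d)
      drift1 += A.slice(d) * (lags[d] == 0 ? x
                              : delayed((arma::sword) t - (arma::sword) lags[d]));
    xstar = x + dt * drift1 + dt * force;
    drift2.zeros();
    for (arma::uword d = 0; d < nd; ++d)
      drift2 += A.slice(d) * (lags[d] == 0 ? xstar
                              : delayed((arma::sword) (t + 1) - (arma::sword) lags[d]));
    x += 0.5 * dt * (drift1 + drift2) + dt * force;
    if ((t + 1) % nkeep == 0) out.col(kout++) = x;
  }
  return out;
}
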