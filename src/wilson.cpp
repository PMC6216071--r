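// Wilson's iterative spectral matrix factorization.
//
// Given a Hermitian positive-definite cross-spectral matrix S(f) sampled on
// the full circular frequency grid f_k = k/n, k = 0..n-1 (conjugate-symmetric
// in k), find the minimum-phase factor psi(f) with S = psi psi^H.  The
// iteration is psi_{k+1} = psi_k [psi_k^{-1} S psi_k^{-H} + I]_+ where []_+
// keeps the causal part of the lag expansion (half weight at lag zero).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Causal-part operator on an M x M x n cube of grid values.  Lags 0..n/2 are
// retained and negative lags zeroed; the lag-0 coefficient is the upper
// triangle of half the lag-0 autocovariance, which pins the rotational
// freedom of the factor (Newton-step normalization), and the lag-n/2
// coefficient -- its own mirror image on the even circular grid -- is
// likewise halved, without which the iteration stalls.  The lag sequence is
// real for Hermitian input on a conjugate-symmetric grid, so the imaginary
// part of the inverse transform is dropped.
static cx_cube plus_operator(const cx_cube& g) {
  const uword M = g.n_rows, n = g.n_slices;
  const uword half = n / 2;
  // lag coefficients per matrix entry
  cube gam(M, M, n);
  cx_vec v(n);
  for (uword i = 0; i < M; ++i)
    for (uword j = 0; j < M; ++j) {
      for (uword f = 0; f < n; ++f) v[f] = g(i, j, f);
      cx_vec gv = ifft(v);
      for (uword k = 0; k < n; ++k) gam(i, j, k) = gv[k].real();
    }
  mat beta0 = trimatu(0.5 * gam.slice(0));
  cx_cube out(M, M, n);
  cx_vec beta(n);
  for (uword i = 0; i < M; ++i)
    for (uword j = 0; j < M; ++j) {
      beta.zeros();
      beta[0] = std::complex<double>(beta0(i, j), 0.0);
      for (uword k = 1; k <= half && k < n; ++k)
        beta[k] = std::complex<double>(gam(i, j, k), 0.0);
      if (2 * half == n) beta[half] *= 0.5;
      cx_vec bf = fft(beta);
      for (uword f = 0; f < n; ++f) out(i, j, f) = bf[f];
    }
  return out;
}

// [[Rcpp::export(name = ".wilson_cpp")]]
Rcpp::List wilson_cpp(const arma::cx_cube& S, double tol, int max_iter) {
  const uword M = S.n_rows, n = S.n_slices;

  // initialization: Cholesky factor of the lag-zero autocovariance
  // (frequency average of S), constant across frequency
  cx_mat gam0(M, M, fill::zeros);
  for (uword f = 0; f < n; ++f) gam0 += S.slice(f);
  gam0 /= static_cast<double>(n);
  mat gam0r = real(gam0);
  gam0r = 0.5 * (gam0r + gam0r.t());
  mat h;
  if (!chol(h, gam0r))
    Rcpp::stop("frequency-averaged spectrum is not positive definite");

  cx_cube psi(M, M, n);
  for (uword f = 0; f < n; ++f) psi.slice(f) = conv_to<cx_mat>::from(h);

  cx_cube g(M, M, n);
  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    for (uword f = 0; f < n; ++f) {
      const cx_mat& P = psi.slice(f);
      cx_mat T1 = solve(P, S.slice(f));
      cx_mat gf = trans(solve(P, trans(T1)));   // psi^-1 S psi^-H
      gf = 0.5 * (gf + trans(gf));              // re-symmetrize
      gf.diag() += 1.0;                         // + I
      g.slice(f) = gf;
    }
    cx_cube gp = plus_operator(g);
    double err = 0.0;
    for (uword f = 0; f < n; ++f) {
      cx_mat pnew = psi.slice(f) * gp.slice(f);
      double d = norm(pnew - psi.slice(f), "fro") /
                 std::max(norm(psi.slice(f), "fro"), 1e-300);
      if (d > err) err = d;
      psi.slice(f) = pnew;
    }
    if (err < tol) { converged = true; break; }
  }
  if (iter > max_iter) iter = max_iter;

  // residual: max over f of per-frequency relative Frobenius error
  double resid = 0.0;
  for (uword f = 0; f < n; ++f) {
    double d = norm(S.slice(f) - psi.slice(f) * trans(psi.slice(f)), "fro") /
               std::max(norm(S.slice(f), "fro"), 1e-300);
    if (d > resid) resid = d;
  }

  // zero-lag causal coefficient A0 = frequency average of psi (real)
  cx_mat a0c(M, M, fill::zeros);
  for (uword f = 0; f < n; ++f) a0c += psi.slice(f);
  a0c /= static_cast<double>(n);
  mat A0 = real(a0c);

  return Rcpp::List::create(
    Rcpp::Named("psi") = psi,
    Rcpp::Named("A0") = A0,
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("residual") = resid);
}
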