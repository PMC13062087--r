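// Wilson spectral matrix factorization: S(f) = H(f) Sigma H(f)^* with H
// minimum phase. Iterative algorithm on the full (two-sided) frequency grid;
// the causal-part ("plus") operator is applied in the lag domain via FFT.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void plus_operator(cx_cube& g) {
  const uword m = g.n_rows;
  const uword N2 = g.n_slices;
  const uword Nh = N2 / 2 + 1;  // lags 0..N2/2 kept
  cx_vec tmp(N2);
  for (uword i = 0; i < m; ++i) {
    for (uword j = 0; j < m; ++j) {
      for (uword k = 0; k < N2; ++k) tmp(k) = g(i, j, k);
      cx_vec lagv = ifft(tmp);
      // zero negative lags
      for (uword k = Nh; k < N2; ++k) lagv(k) = cx_double(0.0, 0.0);
      // half the zero lag and the shared Nyquist lag (lag N2/2 is its own
      // mirror on the circular grid); strictly-lower part of lag 0 removed
      lagv(0) *= 0.5;
      lagv(Nh - 1) *= 0.5;
      if (i > j) lagv(0) = cx_double(0.0, 0.0);
      cx_vec back = fft(lagv);
      for (uword k = 0; k < N2; ++k) g(i, j, k) = back(k);
    }
  }
}

// [[Rcpp::export]]
Rcpp::List wilson_factor_cpp(const arma::cx_cube& Shalf, double fs,
                             double tol, int max_iter) {
  const uword m = Shalf.n_rows;
  const uword Nh = Shalf.n_slices;
  const uword N2 = 2 * (Nh - 1);

  // two-sided spectrum: S(-f) = conj(S(f)) (Hermitian S)
  cx_cube S(m, m, N2);
  for (uword k = 0; k < Nh; ++k) S.slice(k) = Shalf.slice(k);
  for (uword k = Nh; k < N2; ++k) S.slice(k) = conj(Shalf.slice(N2 - k));

  // init: lower Cholesky factor of the frequency-averaged spectrum
  cx_mat Smean(m, m, fill::zeros);
  for (uword k = 0; k < N2; ++k) Smean += S.slice(k);
  Smean /= (double)N2;
  mat S0 = real(Smean);
  S0 = 0.5 * (S0 + S0.t());
  mat L;
  if (!chol(L, S0, "lower")) {
    S0.diag() += 1e-10 * trace(S0) / m + 1e-300;
    chol(L, S0, "lower");
  }
  cx_cube psi(m, m, N2);
  cx_mat L0(L, mat(m, m, fill::zeros));
  for (uword k = 0; k < N2; ++k) psi.slice(k) = L0;

  double normS = 0.0;
  for (uword k = 0; k < N2; ++k) {
    double v = norm(S.slice(k), "fro");
    normS += v * v;
  }
  normS = std::sqrt(normS);

  cx_mat I = eye<cx_mat>(m, m);
  double relres = datum::inf;
  int iters = 0;
  cx_cube g(m, m, N2);
  for (int it = 0; it < max_iter; ++it) {
    iters = it + 1;
    for (uword k = 0; k < N2; ++k) {
      const cx_mat& p = psi.slice(k);
      cx_mat A = solve(p, S.slice(k));
      g.slice(k) = solve(p, A.t()).t() + I;  // p^{-1} S p^{-H} + I
    }
    plus_operator(g);
    for (uword k = 0; k < N2; ++k) psi.slice(k) = psi.slice(k) * g.slice(k);
    // reconstruction residual
    double res = 0.0;
    for (uword k = 0; k < N2; ++k) {
      double v = norm(S.slice(k) - psi.slice(k) * psi.slice(k).t(), "fro");
      res += v * v;
    }
    relres = std::sqrt(res) / normS;
    if (relres < tol) break;
  }

  // lag-0 coefficient of psi
  cx_mat A0(m, m, fill::zeros);
  for (uword k = 0; k < N2; ++k) A0 += psi.slice(k);
  A0 /= (double)N2;
  mat A0r = real(A0);
  mat Sigma = A0r * A0r.t() * fs;
  mat A0inv = inv(A0r);
  cx_cube H(m, m, Nh);
  cx_mat A0i(A0inv, mat(m, m, fill::zeros));
  for (uword k = 0; k < Nh; ++k) H.slice(k) = psi.slice(k) * A0i;

  return Rcpp::List::create(
    Rcpp::Named("H") = H,
    Rcpp::Named("Sigma") = Sigma,
    Rcpp::Named("relres") = relres,
    Rcpp::Named("iterations") = iters,
    Rcpp::Named("converged") = (relres < tol));
}
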