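#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Pivoted (rank-revealing) Cholesky factor of the Gaussian kernel matrix
// K[a,b] = exp(-(x_a - x_b)^2 / 2) of a 1-D sample x. Only the pivot
// columns of K are ever formed, so the cost is O(n * r^2) for the returned
// rank r. Stops once the residual trace drops below rtol * n (K has unit
// diagonal, so the full trace is n) or rank n is reached.
static mat pivoted_chol_gauss(const vec& x, double rtol) {
  const uword n = x.n_elem;
  vec d(n, fill::ones);                 // residual diagonal
  std::vector<uword> used(n, 0);
  mat G(n, 0);
  const double tol = rtol * static_cast<double>(n);
  double resid = static_cast<double>(n);

  for (uword k = 0; k < n; ++k) {
    if (resid <= tol) break;
    uword piv = d.index_max();
    double dp = d(piv);
    if (dp <= 0) break;

    vec col = exp(-0.5 * square(x - x(piv)));   // pivot column of K
    vec g = col;
    if (k > 0) g -= G.cols(0, k - 1) * G.row(piv).cols(0, k - 1).t();
    g /= std::sqrt(dp);

    G.insert_cols(k, g);
    used[piv] = 1;
    d -= square(g);
    for (uword i = 0; i < n; ++i) {
      if (used[i] || d(i) < 0) d(i) = 0;
    }
    resid = accu(d);
  }
  return G;
}

// Centered low-rank factor: H K H = (H G)(H G)^T with H = I - 11^T/n.
static mat centered_factor(const vec& x, double rtol) {
  mat G = pivoted_chol_gauss(x, rtol);
  if (G.n_cols > 0) G.each_row() -= mean(G, 0);
  return G;
}

// Kernel partial correlation of each column of X against y.
//
// rho_j = tr(O^T Ky~ O) / tr(Ky~),  O = Kj~ (Kj~ + n*delta*I)^{-1},
// computed through the identity O = I - c A^{-1} (c = n*delta,
// A = Kj~ + cI) and the Woodbury formula on the low-rank factors, which is
// exact up to the pivoted-Cholesky truncation (rtol ~ 1e-15 by default).
// Columns of X and y are expected to be z-scored already.
// [[Rcpp::export]]
arma::vec kpc_scores_cpp(const arma::mat& X, const arma::vec& y,
                         double delta, double rtol) {
  const uword n = y.n_elem, p = X.n_cols;
  const double c = static_cast<double>(n) * delta;

  mat Gy = centered_factor(y, rtol);
  const double t0 = accu(Gy % Gy);      // tr(Ky~)
  if (!(t0 > 0)) Rcpp::stop("outcome kernel has zero trace (constant y?)");

  vec rho(p);
  for (uword j = 0; j < p; ++j) {
    mat G = centered_factor(X.col(j), rtol);
    double tG = accu(G % G);
    if (tG <= rtol * n) { rho(j) = 0.0; continue; }   // K~ = 0: O = 0

    mat M = G.t() * G;
    M.diag() += c;
    mat W = (Gy - G * solve(M, G.t() * Gy, solve_opts::likely_sympd)) / c;
    double T1 = accu(Gy % W);           // tr(A^{-1} Ky~)
    double T2 = accu(W % W);            // tr(A^{-1} Ky~ A^{-1})
    double r = (t0 - 2.0 * c * T1 + c * c * T2) / t0;
    if (r < 0) r = 0;                   // guard rounding; r in [0,1) in exact arithmetic
    rho(j) = r;
  }
  return rho;
}
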