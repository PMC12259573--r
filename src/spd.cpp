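// Numerical kernels for the affine-invariant geometry of SPD matrices.
// These sit under the R-level riemann_core API; all argument validation
// happens on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat symmetrize(const mat& X) { return 0.5 * (X + X.t()); }

// S^p for symmetric S via eigendecomposition.
static mat sym_pow(const mat& S, double p) {
  vec ev;
  mat V;
  eig_sym(ev, V, symmetrize(S), "dc");
  return V * diagmat(pow(ev, p)) * V.t();
}

static mat sym_log(const mat& S) {
  vec ev;
  mat V;
  eig_sym(ev, V, symmetrize(S), "dc");
  return V * diagmat(log(ev)) * V.t();
}

static mat sym_exp(const mat& S) {
  vec ev;
  mat V;
  eig_sym(ev, V, symmetrize(S), "dc");
  return V * diagmat(exp(ev)) * V.t();
}

static double airm(const mat& A, const mat& B) {
  // d(A,B) = || log(B^{-1/2} A B^{-1/2}) ||_F via Cholesky whitening
  mat L = chol(symmetrize(B), "lower");
  mat Y = solve(trimatl(L), A);
  mat M = solve(trimatl(L), Y.t());
  vec ev = eig_sym(symmetrize(M));
  return std::sqrt(accu(square(log(ev))));
}

// [[Rcpp::export]]
double cpp_airm_distance(const arma::mat& A, const arma::mat& B) {
  return airm(A, B);
}

// [[Rcpp::export]]
arma::mat cpp_dist_to_means(const arma::cube& covs, const arma::cube& means) {
  // rows: matrices in `covs`; cols: candidate class means
  const uword n = covs.n_slices, m = means.n_slices;
  mat D(n, m);
  for (uword j = 0; j < m; ++j) {
    mat L = chol(symmetrize(means.slice(j)), "lower");
    for (uword i = 0; i < n; ++i) {
      mat Y = solve(trimatl(L), covs.slice(i));
      mat M = solve(trimatl(L), Y.t());
      vec ev = eig_sym(symmetrize(M));
      D(i, j) = std::sqrt(accu(square(log(ev))));
    }
  }
  return D;
}

// [[Rcpp::export]]
Rcpp::List cpp_karcher_mean(const arma::cube& covs, double tol, int max_iter,
                            bool le_init) {
  const uword n = covs.n_slices;
  double gnorm = R_PosInf;
  int it = 0;
  if (n == 1) {
    return Rcpp::List::create(Rcpp::Named("mean") = covs.slice(0),
                              Rcpp::Named("iterations") = 0,
                              Rcpp::Named("grad_norm") = 0.0);
  }
  mat S;
  if (le_init) {
    // log-Euclidean mean: a close warm start when inputs are spread out
    mat T(covs.n_rows, covs.n_cols, fill::zeros);
    for (uword i = 0; i < n; ++i) T += sym_log(covs.slice(i));
    S = sym_exp(T / static_cast<double>(n));
  } else {
    S = mean(covs, 2); // arithmetic-mean initialization
  }
  for (it = 0; it < max_iter; ++it) {
    mat Sh = sym_pow(S, 0.5);
    mat Sih = sym_pow(S, -0.5);
    mat T(S.n_rows, S.n_cols, fill::zeros);
    for (uword i = 0; i < n; ++i) {
      T += sym_log(Sih * covs.slice(i) * Sih);
    }
    T /= static_cast<double>(n);
    gnorm = norm(T, "fro");
    if (gnorm < tol) break;
    S = symmetrize(Sh * sym_exp(T) * Sh);
  }
  return Rcpp::List::create(Rcpp::Named("mean") = S,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("grad_norm") = gnorm);
}

// [[Rcpp::export]]
arma::uvec cpp_select_channels(const arma::mat& A, const arma::mat& B, int k) {
  // Backward elimination: repeatedly delete the channel whose removal
  // maximizes the AIRM distance between the two pruned class means.
  // Ties break toward the lowest channel index (first strict improvement).
  uvec kept = regspace<uvec>(0, A.n_rows - 1);
  while (kept.n_elem > static_cast<uword>(k)) {
    double best = -1.0;
    uword best_pos = 0;
    for (uword pos = 0; pos < kept.n_elem; ++pos) {
      uvec sub(kept.n_elem - 1);
      uword q = 0;
      for (uword j = 0; j < kept.n_elem; ++j)
        if (j != pos) sub(q++) = kept(j);
      double d = airm(A.submat(sub, sub), B.submat(sub, sub));
      if (d > best) { // strict: earliest (lowest-index) candidate wins ties
        best = d;
        best_pos = pos;
      }
    }
    kept.shed_row(best_pos);
  }
  return kept + 1; // 1-based for R
}
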