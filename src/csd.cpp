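#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Iterative soft-constrained spherical deconvolution, batched over voxels.
//
// S    : nvox x nd matrix of (b0-normalised) DW measurements
// A    : nd x nc forward convolution matrix (response-weighted SH basis)
// B    : nb x nc SH basis evaluated on the constraint direction set
// tau  : amplitude threshold factor; directions with FOD amplitude below
//        tau * mean(initial amplitude) enter the penalty set
// lam2 : squared penalty weight (already norm-scaled by the caller)
//
// Returns per-voxel SH coefficients, iteration counts and convergence flags.
// Convergence means the active constraint set stabilised before max_iter.
// [[Rcpp::export]]
Rcpp::List csd_fit_batch(const arma::mat& S, const arma::mat& A,
                         const arma::mat& B, double tau, int max_iter,
                         double lam2) {
  const int nvox = S.n_rows;
  const int nc = A.n_cols;

  mat AtA = A.t() * A;
  mat coefs(nvox, nc, fill::zeros);
  Rcpp::IntegerVector iters(nvox);
  Rcpp::LogicalVector converged(nvox);

  for (int v = 0; v < nvox; ++v) {
    vec s = S.row(v).t();
    vec Ats = A.t() * s;
    vec x;
    bool ok = solve(x, AtA, Ats, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) {
      coefs.row(v).fill(datum::nan);
      iters[v] = 0;
      converged[v] = false;
      continue;
    }
    vec amp = B * x;
    double thr = tau * mean(amp);

    uvec active_prev;
    bool have_prev = false;
    bool conv = false;
    int it = 0;
    for (it = 0; it < max_iter; ++it) {
      amp = B * x;
      uvec active = find(amp < thr);
      if (have_prev && active.n_elem == active_prev.n_elem &&
          (active.n_elem == 0 || all(active == active_prev))) {
        conv = true;
        break;
      }
      mat Ba = B.rows(active);
      ok = solve(x, AtA + lam2 * (Ba.t() * Ba), Ats,
                 solve_opts::likely_sympd + solve_opts::no_approx);
      if (!ok) { x.fill(datum::nan); break; }
      active_prev = active;
      have_prev = true;
    }
    coefs.row(v) = x.t();
    iters[v] = it;
    converged[v] = conv;
    if ((v & 255) == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(Rcpp::Named("coefficients") = coefs,
                            Rcpp::Named("iterations") = iters,
                            Rcpp::Named("converged") = converged);
}
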