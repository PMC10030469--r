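#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the Lasso in covariance form.
// Inputs are moments of the standardised problem: G = X'X / n and
// q = X'y / n, with diag(G) = 1 for unit-variance columns. For each
// penalty in `alphas` (visited in the given order, warm-starting from
// the previous solution) the update for coordinate j is the
// soft-threshold  w_j <- S(q_j - sum_{l != j} G_jl w_l, alpha) / G_jj,
// which minimises (1/(2n))||y - Xw||^2 + alpha * ||w||_1 coordinate-wise.
// Convergence: max absolute coefficient change below `tol`.

// [[Rcpp::export]]
NumericMatrix lasso_cd_path(NumericMatrix G, NumericVector q,
                            NumericVector alphas, int max_sweeps,
                            double tol) {
  const int p = q.size();
  const int na = alphas.size();
  NumericMatrix B(p, na);
  std::vector<double> w(p, 0.0);
  for (int a = 0; a < na; ++a) {
    const double alpha = alphas[a];
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      double maxdel = 0.0;
      for (int j = 0; j < p; ++j) {
        double gj = q[j];
        for (int l = 0; l < p; ++l) {
          if (l != j) gj -= G(j, l) * w[l];
        }
        double wnew = 0.0;
        const double d = G(j, j);
        if (d > 0.0) {
          if (gj > alpha) wnew = (gj - alpha) / d;
          else if (gj < -alpha) wnew = (gj + alpha) / d;
        }
        const double del = std::abs(wnew - w[j]);
        if (del > maxdel) maxdel = del;
        w[j] = wnew;
      }
      if (maxdel < tol) break;
    }
    for (int j = 0; j < p; ++j) B(j, a) = w[j];
  }
  return B;
}
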