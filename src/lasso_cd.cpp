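#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cyclic coordinate descent for the objective
//   (1/(2n)) * ||y - X beta||^2 + lambda * ||beta||_1
// on precomputed Gram quantities G = X'X and c = X'y, warm-started
// along a decreasing lambda grid. Columns with G_jj == 0 (zero
// variance) are held at zero.

inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// [[Rcpp::export]]
List lasso_cd_path(NumericMatrix G, NumericVector c, double n,
                   NumericVector lambda, double tol, int max_iter) {
  const int p = G.ncol();
  const int L = lambda.size();
  NumericMatrix beta(p, L);
  IntegerVector n_iter(L);
  LogicalVector converged(L);
  std::vector<double> b(p, 0.0);
  // grad_part[j] = (c_j - sum_k G_jk b_k) / n, maintained incrementally
  std::vector<double> resid_corr(p);
  for (int j = 0; j < p; ++j) resid_corr[j] = c[j] / n;

  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l];
    int it = 0;
    bool ok = false;
    for (; it < max_iter; ++it) {
      double max_delta = 0.0;
      for (int j = 0; j < p; ++j) {
        const double gjj = G(j, j) / n;
        if (gjj <= 0.0) continue;
        const double z = resid_corr[j] + gjj * b[j];
        const double bj_new = soft(z, lam) / gjj;
        const double delta = bj_new - b[j];
        if (delta != 0.0) {
          for (int k = 0; k < p; ++k) resid_corr[k] -= G(k, j) / n * delta;
          b[j] = bj_new;
          const double ad = std::fabs(delta);
          if (ad > max_delta) max_delta = ad;
        }
      }
      if (max_delta < tol) { ok = true; ++it; break; }
    }
    n_iter[l] = it;
    converged[l] = ok;
    for (int j = 0; j < p; ++j) beta(j, l) = b[j];
  }
  return List::create(_["beta"] = beta, _["n_iter"] = n_iter,
                      _["converged"] = converged);
}
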