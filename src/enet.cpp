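#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cyclic coordinate descent for the elastic net over a decreasing lambda
// path with warm starts. X is expected column-standardized (mean 0, unit
// population SD; all-zero columns allowed, their coefficients stay 0) and y
// centered. Objective per lambda:
//   (1/2n) * ||y - X b||^2 + lambda * (alpha * |b|_1 + (1-alpha)/2 * |b|_2^2)
// Convergence: max absolute coefficient change in a sweep < tol, or
// max_sweeps full sweeps.
// [[Rcpp::export]]
NumericMatrix enet_path_cd(const NumericMatrix& X, const NumericVector& y,
                           double alpha, const NumericVector& lambda,
                           double tol, int max_sweeps) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  NumericMatrix B(p, L);
  std::vector<double> beta(p, 0.0), r(y.begin(), y.end()), xx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xx[j] = s / n;
  }
  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l];
    const double l1 = lam * alpha, l2 = lam * (1.0 - alpha);
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      double maxdel = 0.0;
      for (int j = 0; j < p; ++j) {
        if (xx[j] <= 0.0) continue;
        const double bj = beta[j];
        double rho = 0.0;
        for (int i = 0; i < n; ++i) rho += X(i, j) * r[i];
        rho = rho / n + xx[j] * bj;
        const double z = std::fabs(rho) - l1;
        const double bnew = (z > 0.0)
          ? ((rho > 0.0 ? z : -z) / (xx[j] + l2))
          : 0.0;
        const double del = bnew - bj;
        if (del != 0.0) {
          for (int i = 0; i < n; ++i) r[i] -= del * X(i, j);
          beta[j] = bnew;
        }
        if (std::fabs(del) > maxdel) maxdel = std::fabs(del);
      }
      if (maxdel < tol) break;
    }
    for (int j = 0; j < p; ++j) B(j, l) = beta[j];
  }
  return B;
}
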