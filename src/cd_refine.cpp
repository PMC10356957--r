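#include <Rcpp.h>
using namespace Rcpp;

// Active-set cyclic coordinate descent for the elastic-net objective
//   1/(2n) ||y - X b||^2 + lambda (r |b|_1 + (1 - r)/2 ||b||_2^2),
// warm-started from an approximate solution. Sweeps the active set to
// stationarity, then checks the KKT conditions over all coordinates and
// admits violators, until none remain. X is expected column-standardized;
// xx holds colSums(X^2)/n.
// [[Rcpp::export]]
NumericVector cd_refine_cpp(NumericMatrix X, NumericVector y,
                            NumericVector beta0, double lambda,
                            double l1_ratio, NumericVector xx,
                            double tol, int max_outer, int max_sweeps) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector beta = clone(beta0);
  std::vector<double> res(n);
  for (int i = 0; i < n; ++i) res[i] = y[i];
  for (int j = 0; j < p; ++j) {
    if (beta[j] != 0.0) {
      const double* xj = &X(0, j);
      for (int i = 0; i < n; ++i) res[i] -= xj[i] * beta[j];
    }
  }
  const double thr = lambda * l1_ratio;
  const double ridge = lambda * (1.0 - l1_ratio);
  std::vector<int> active;
  std::vector<char> in_active(p, 0);
  for (int j = 0; j < p; ++j) {
    if (beta[j] != 0.0) { active.push_back(j); in_active[j] = 1; }
  }
  for (int outer = 0; outer < max_outer; ++outer) {
    for (int sweep = 0; sweep < max_sweeps && !active.empty(); ++sweep) {
      double delta = 0.0;
      for (size_t k = 0; k < active.size(); ++k) {
        const int j = active[k];
        const double bj = beta[j];
        const double* xj = &X(0, j);
        double rho = 0.0;
        for (int i = 0; i < n; ++i) rho += xj[i] * res[i];
        rho = rho / n + xx[j] * bj;
        double bn = 0.0;
        const double a = std::abs(rho) - thr;
        if (a > 0.0) bn = ((rho > 0) - (rho < 0)) * a / (xx[j] + ridge);
        if (bn != bj) {
          const double d = bj - bn;
          for (int i = 0; i < n; ++i) res[i] += xj[i] * d;
          if (std::abs(d) > delta) delta = std::abs(d);
          beta[j] = bn;
        }
      }
      if (delta < tol) break;
    }
    bool violated = false;
    for (int j = 0; j < p; ++j) {
      if (in_active[j]) continue;
      const double* xj = &X(0, j);
      double grad = 0.0;
      for (int i = 0; i < n; ++i) grad += xj[i] * res[i];
      grad /= n;
      if (std::abs(grad) > thr + tol) {
        active.push_back(j);
        in_active[j] = 1;
        violated = true;
      }
    }
    if (!violated) break;
  }
  return beta;
}
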