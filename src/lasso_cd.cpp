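#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the multi-response lasso in covariance form.
// Minimizes 1/(2N) ||y - X b||^2 + lambda ||b||_1 per response column, given
// xtx = X'X/N and xty = X'y/N. Columns are independent problems sharing X; a
// column whose sweep-wise maximum coefficient change falls below `tol` is
// converged and skipped from then on.
// [[Rcpp::export(name = ".lasso_cd_engine")]]
List lasso_cd_engine(NumericMatrix xtx, NumericMatrix xty, NumericMatrix binit,
                     double lambda, double tol, int max_iter) {
  const int p = xtx.nrow();
  const int v = xty.ncol();
  NumericMatrix b = clone(binit);
  NumericMatrix g(p, v); // running X'X b / N
  for (int col = 0; col < v; ++col) {
    double* gcol = &g(0, col);
    for (int j = 0; j < p; ++j) {
      const double bj = b(j, col);
      if (bj != 0.0) {
        const double* xj = &xtx(0, j);
        for (int i = 0; i < p; ++i) gcol[i] += xj[i] * bj;
      }
    }
  }
  std::vector<bool> done(v, false);
  std::vector<double> dcol(v, 0.0);
  bool converged = false;
  int it = 0;
  while (it < max_iter && !converged) {
    ++it;
    std::fill(dcol.begin(), dcol.end(), 0.0);
    for (int j = 0; j < p; ++j) {
      const double cjj = xtx(j, j);
      const double* xj = &xtx(0, j);
      for (int col = 0; col < v; ++col) {
        if (done[col]) continue;
        const double rho = xty(j, col) - g(j, col) + cjj * b(j, col);
        double bn = 0.0;
        if (rho > lambda) bn = (rho - lambda) / cjj;
        else if (rho < -lambda) bn = (rho + lambda) / cjj;
        const double d = bn - b(j, col);
        if (d != 0.0) {
          b(j, col) = bn;
          const double ad = d < 0 ? -d : d;
          if (ad > dcol[col]) dcol[col] = ad;
          double* gcol = &g(0, col);
          for (int i = 0; i < p; ++i) gcol[i] += xj[i] * d;
        }
      }
    }
    converged = true;
    for (int col = 0; col < v; ++col) {
      if (!done[col]) {
        if (dcol[col] < tol) done[col] = true;
        else converged = false;
      }
    }
  }
  return List::create(_["b"] = b, _["converged"] = converged, _["iter"] = it);
}
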