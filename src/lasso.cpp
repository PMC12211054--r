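#include <Rcpp.h>
using namespace Rcpp;

// Coordinate-descent solver for the Lasso objective
//   (1/2n) * ||y - b0 - X b||^2 + lambda * ||b||_1
// over a decreasing lambda path with warm starts. X is used as supplied
// (callers standardize); the intercept is handled as an unpenalized
// coordinate.

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

static void cd_path_core(const double* X, const double* y, int n, int p,
                         const double* lambdas, int nl, double tol,
                         int max_iter, double* beta_out, double* b0_out) {
  std::vector<double> beta(p, 0.0), xsq(p);
  std::vector<double> r(y, y + n);  // residual y - b0 - Xb
  std::vector<char> active(p, 0);
  double b0 = 0.0;
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X[j * n + i] * X[j * n + i];
    xsq[j] = s / n;
  }
  // convergence threshold scaled by the response variance (glmnet-style):
  // stop when max_j xsq_j * delta_j^2 < tol * var(y)
  double ym = 0.0, yv = 0.0;
  for (int i = 0; i < n; ++i) ym += y[i];
  ym /= n;
  for (int i = 0; i < n; ++i) yv += (y[i] - ym) * (y[i] - ym);
  yv /= n;
  const double thr = tol * (yv > 0 ? yv : 1.0);

  auto update_j = [&](int j, double lam) -> double {
    if (xsq[j] <= 0.0) return 0.0;
    const double* xj = X + (size_t)j * n;
    double rho = 0.0;
    for (int i = 0; i < n; ++i) rho += xj[i] * r[i];
    rho = rho / n + xsq[j] * beta[j];
    double bnew = soft(rho, lam) / xsq[j];
    double d = bnew - beta[j];
    if (d != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= xj[i] * d;
      beta[j] = bnew;
      if (bnew != 0.0) active[j] = 1;
    }
    return xsq[j] * d * d;
  };
  auto update_b0 = [&]() -> double {
    double rm = 0.0;
    for (int i = 0; i < n; ++i) rm += r[i];
    rm /= n;
    if (rm != 0.0) {
      b0 += rm;
      for (int i = 0; i < n; ++i) r[i] -= rm;
    }
    return rm * rm;
  };

  for (int l = 0; l < nl; ++l) {
    double lam = lambdas[l];
    int it = 0;
    while (it < max_iter) {
      // full sweep over all coordinates
      double dlx = update_b0();
      for (int j = 0; j < p; ++j) {
        double d = update_j(j, lam);
        if (d > dlx) dlx = d;
      }
      ++it;
      if (dlx < thr) break;
      // inner loops restricted to the active set
      while (it < max_iter) {
        double dla = update_b0();
        for (int j = 0; j < p; ++j) {
          if (!active[j]) continue;
          double d = update_j(j, lam);
          if (d > dla) dla = d;
        }
        ++it;
        if (dla < thr) break;
      }
    }
    for (int j = 0; j < p; ++j) beta_out[(size_t)l * p + j] = beta[j];
    b0_out[l] = b0;
  }
}

// [[Rcpp::export(name = ".cd_lasso_path")]]
List cd_lasso_path(NumericMatrix X, NumericVector y, NumericVector lambdas,
                   double tol = 1e-7, int max_iter = 100000) {
  int n = X.nrow(), p = X.ncol(), nl = lambdas.size();
  NumericMatrix beta(p, nl);
  NumericVector b0(nl);
  cd_path_core(REAL(X), REAL(y), n, p, REAL(lambdas), nl, tol, max_iter,
               REAL(beta), REAL(b0));
  return List::create(_["beta"] = beta, _["intercept"] = b0,
                      _["lambda"] = lambdas);
}

// Cross-validated squared prediction errors along the path. foldid holds
// 1-based fold labels; fold k is held out while the path is fit on the
// rest. Returns the n x nlambda matrix of held-out squared errors.
// [[Rcpp::export(name = ".cd_lasso_cv_err")]]
NumericMatrix cd_lasso_cv_err(NumericMatrix X, NumericVector y,
                              NumericVector lambdas, IntegerVector foldid,
                              double tol = 1e-7, int max_iter = 100000) {
  int n = X.nrow(), p = X.ncol(), nl = lambdas.size();
  int nfold = 0;
  for (int i = 0; i < n; ++i) if (foldid[i] > nfold) nfold = foldid[i];
  NumericMatrix err(n, nl);
  std::vector<double> Xtr((size_t)n * p), ytr(n);
  std::vector<double> beta((size_t)p * nl), b0(nl);
  for (int k = 1; k <= nfold; ++k) {
    int ntr = 0;
    for (int i = 0; i < n; ++i) if (foldid[i] != k) ++ntr;
    if (ntr == 0 || ntr == n) continue;
    // pack training rows column-major
    int row = 0;
    for (int i = 0; i < n; ++i) {
      if (foldid[i] == k) continue;
      ytr[row] = y[i];
      for (int j = 0; j < p; ++j) Xtr[(size_t)j * ntr + row] = X(i, j);
      ++row;
    }
    cd_path_core(Xtr.data(), ytr.data(), ntr, p, REAL(lambdas), nl, tol,
                 max_iter, beta.data(), b0.data());
    for (int i = 0; i < n; ++i) {
      if (foldid[i] != k) continue;
      for (int l = 0; l < nl; ++l) {
        double pred = b0[l];
        for (int j = 0; j < p; ++j) pred += X(i, j) * beta[(size_t)l * p + j];
        double e = y[i] - pred;
        err(i, l) = e * e;
      }
    }
  }
  return err;
}
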