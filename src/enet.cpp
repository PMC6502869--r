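#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent with soft-thresholding for the elastic-net
// objective (1/2m)||Xw - y||^2 + l1*||w||_1 + (l2/2)*||w||^2 on an already
// standardized/centered design. Uses covariance (Gram-matrix) updates, so a
// full cycle costs O(n^2) regardless of m. Deterministic start at w = 0 (or
// a supplied warm start); stops when the largest per-cycle weight change
// falls below tol.
// [[Rcpp::export(name = ".enet_cd")]]
List enet_cd(NumericMatrix Xs, NumericVector yc, double alpha, double rho,
             LogicalVector constant, double tol, int max_iter,
             NumericVector w0) {
  const int m = Xs.nrow(), n = Xs.ncol();
  std::vector<double> G((size_t)n * n), c(n), w(n, 0.0);
  for (int j = 0; j < n; ++j) {
    const double* xj = &Xs(0, j);
    double cj = 0.0;
    for (int i = 0; i < m; ++i) cj += xj[i] * yc[i];
    c[j] = cj / m;
    for (int k = j; k < n; ++k) {
      const double* xk = &Xs(0, k);
      double g = 0.0;
      for (int i = 0; i < m; ++i) g += xj[i] * xk[i];
      g /= m;
      G[(size_t)j * n + k] = g;
      G[(size_t)k * n + j] = g;
    }
  }
  if (w0.size() == n) for (int j = 0; j < n; ++j) w[j] = w0[j];
  const double l1 = alpha * rho, l2 = alpha * (1.0 - rho);
  int it = 0;
  bool converged = false;
  while (it < max_iter) {
    ++it;
    double delta_max = 0.0;
    for (int j = 0; j < n; ++j) {
      const double dj = G[(size_t)j * n + j];
      if (constant[j] || dj == 0.0) continue;
      const double* Gj = &G[(size_t)j * n];
      double s = 0.0;
      for (int k = 0; k < n; ++k) s += Gj[k] * w[k];
      const double z = c[j] - s + dj * w[j];
      const double wn = (z > l1 ? z - l1 : (z < -l1 ? z + l1 : 0.0)) / (dj + l2);
      const double ad = std::fabs(wn - w[j]);
      if (ad > delta_max) delta_max = ad;
      w[j] = wn;
    }
    if (delta_max < tol) { converged = true; break; }
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["iterations"] = it, _["converged"] = converged);
}
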