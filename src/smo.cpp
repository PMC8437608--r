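#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sequential minimal optimization for the C-SVC dual with a precomputed
// kernel matrix: maximal-violating-pair working-set selection (first-order),
// pairwise analytic update, O(n) gradient maintenance.
//
//   min_a  1/2 a' Q a - e' a ,  0 <= a_i <= C ,  y' a = 0 ,  Q_ij = y_i y_j K_ij
//
// Indefinite K (e.g. sigmoid kernels) is tolerated: non-positive pairwise
// curvature is floored at a small tau, as SMO implementations commonly do.
// Returns alpha, the intercept b of f(x) = sum_i a_i y_i K(x_i, x) + b,
// the iteration count, a convergence flag, and whether negative curvature
// was encountered (a cheap indefiniteness signal).

// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, IntegerVector y, double C,
               double tol, int max_iter) {
  const int n = K.nrow();
  std::vector<double> alpha(n, 0.0);
  std::vector<double> grad(n, -1.0);  // grad_i = (Q a)_i - 1; a = 0 initially
  bool neg_curv = false;
  int iter = 0;
  double gmax = 0.0, gmin = 0.0;

  for (iter = 0; iter < max_iter; ++iter) {
    int i = -1, j = -1;
    gmax = -R_PosInf;
    gmin = R_PosInf;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * grad[t];
      if ((y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0.0)) {
        if (v > gmax) { gmax = v; i = t; }
      }
      if ((y[t] == 1 && alpha[t] > 0.0) || (y[t] == -1 && alpha[t] < C)) {
        if (v < gmin) { gmin = v; j = t; }
      }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) break;

    // curvature of the dual along the pair direction (da_i = y_i d,
    // da_j = -y_j d); the label factors cancel
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 0.0) { neg_curv = true; quad = 1e-12; }

    // step d along the feasible direction a_i += y_i d, a_j -= y_j d
    double d = (gmax - gmin) / quad;
    const double dmax_i = (y[i] == 1) ? (C - alpha[i]) : alpha[i];
    const double dmax_j = (y[j] == 1) ? alpha[j] : (C - alpha[j]);
    if (d > dmax_i) d = dmax_i;
    if (d > dmax_j) d = dmax_j;
    if (d <= 0.0) break;  // boundary degenerate; KKT gap cannot shrink here

    const double dai = y[i] * d;   // change in alpha_i
    const double daj = -y[j] * d;  // change in alpha_j
    alpha[i] += dai;
    alpha[j] += daj;
    for (int t = 0; t < n; ++t)
      grad[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
  }

  // intercept: average y_t - f0(t) over free vectors, f0(t) = y_t(grad_t + 1)
  double bsum = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-12 && alpha[t] < C - 1e-12) {
      bsum += y[t] - y[t] * (grad[t] + 1.0);
      ++nfree;
    }
  }
  double b;
  if (nfree > 0) {
    b = bsum / nfree;
  } else {
    // all alphas at bounds: midpoint of the violating interval
    b = (R_finite(gmax) && R_finite(gmin)) ? (gmax + gmin) / 2.0 : 0.0;
  }

  return List::create(
    _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
    _["b"] = b,
    _["iterations"] = iter,
    _["converged"] = (iter < max_iter),
    _["negative_curvature"] = neg_curv);
}
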