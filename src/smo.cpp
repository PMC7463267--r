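#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Soft-margin SVM dual solver (SMO with maximal-violating-pair working-set
// selection, as in LIBSVM).  Minimizes
//   f(a) = 1/2 a' Q a - e' a,  Q_st = y_s y_t K_st,
// subject to 0 <= a_t <= C and y' a = 0.
//
// K: n x n kernel matrix; y: labels in {-1, +1}; C: box constraint;
// tol: stopping tolerance on the maximal KKT violation; max_iter: hard cap.
//
// Returns alpha, the bias b, the iteration count and whether the KKT
// tolerance was reached.
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double C,
               double tol = 1e-3, int max_iter = 1000000) {
  const int n = K.nrow();
  if (K.ncol() != n) stop("kernel matrix must be square");
  if (y.size() != n) stop("label/kernel size mismatch");
  if (C <= 0) stop("C must be positive");

  std::vector<double> alpha(n, 0.0);
  std::vector<double> grad(n, -1.0);  // grad f(0) = -e

  int iter = 0;
  bool converged = false;
  double Gmax = 0.0, Gmin = 0.0;

  while (iter < max_iter) {
    int i = -1, j = -1;
    Gmax = -1e300; Gmin = 1e300;
    for (int t = 0; t < n; ++t) {
      const bool up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      const double v = -y[t] * grad[t];
      if (up  && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < tol) { converged = true; break; }

    // Two-variable subproblem along a_i += y_i t, a_j -= y_j t.
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 0) quad = 1e-12;
    double t_step = (Gmax - Gmin) / quad;

    // Box limits on t for both coordinates.
    double t_hi = t_step;
    if (y[i] > 0) t_hi = std::min(t_hi, C - alpha[i]);
    else          t_hi = std::min(t_hi, alpha[i]);
    if (y[j] > 0) t_hi = std::min(t_hi, alpha[j]);
    else          t_hi = std::min(t_hi, C - alpha[j]);
    t_step = t_hi;

    const double dai = y[i] * t_step;   // change in alpha_i
    const double daj = -y[j] * t_step;  // change in alpha_j
    alpha[i] += dai;
    alpha[j] += daj;
    for (int t = 0; t < n; ++t)
      grad[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
    ++iter;
  }
  if (iter >= max_iter) {
    // recompute the final violation for the bias below
    Gmax = -1e300; Gmin = 1e300;
    for (int t = 0; t < n; ++t) {
      const bool up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      const double v = -y[t] * grad[t];
      if (up  && v > Gmax) Gmax = v;
      if (low && v < Gmin) Gmin = v;
    }
  }

  // Bias from free support vectors (KKT: y_t f(x_t) = 1 there), else the
  // midpoint of the violation interval.
  if (Gmax < -1e299) Gmax = 0.0;
  if (Gmin > 1e299) Gmin = 0.0;
  double bsum = 0.0; int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 0 && alpha[t] < C) { bsum += -y[t] * grad[t]; ++nfree; }
  }
  const double b = nfree > 0 ? bsum / nfree : (Gmax + Gmin) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b,
                      _["iterations"] = iter,
                      _["converged"] = converged || iter < max_iter);
}
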