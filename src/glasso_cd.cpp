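#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Block coordinate descent for the l1-penalized inverse-covariance objective
//   argmin_Theta  sum_ij S_ij Theta_ij - log det(Theta) + rho * sum_ij |Theta_ij|
// (diagonal penalized, hence the working covariance starts at S + rho I).
// Each column's subproblem is a lasso solved by coordinate descent.

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// [[Rcpp::export(name = ".glasso_cd")]]
List glasso_cd(NumericMatrix Sin, double rho, int maxit = 100,
               double tol = 1e-6, int inner_maxit = 200) {
  int p = Sin.nrow();
  NumericMatrix S(clone(Sin));
  NumericMatrix W(p, p);
  NumericMatrix B(p, p);   // lasso coefficients, column j holds beta for block j
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j) W(i, j) = S(i, j);
  for (int i = 0; i < p; ++i) W(i, i) = S(i, i) + rho;

  // convergence threshold scaled by mean absolute off-diagonal of S
  double sbar = 0.0; int nov = 0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) { sbar += std::fabs(S(i, j)); ++nov; }
  sbar = nov > 0 ? sbar / nov : 0.0;
  double thr = tol * (sbar > 0 ? sbar : 1.0);

  bool converged = false, finite = true;
  int iter = 0;
  if (p == 1) {
    converged = true;
  }
  for (iter = 0; iter < maxit && p > 1; ++iter) {
    double dw = 0.0;
    for (int j = 0; j < p; ++j) {
      // coordinate descent on beta for column j
      for (int it2 = 0; it2 < inner_maxit; ++it2) {
        double dmax = 0.0;
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          double z = S(k, j);
          for (int mIdx = 0; mIdx < p; ++mIdx) {
            if (mIdx == j || mIdx == k) continue;
            z -= W(k, mIdx) * B(mIdx, j);
          }
          double bnew = soft(z, rho) / W(k, k);
          double d = std::fabs(bnew - B(k, j));
          if (d > dmax) dmax = d;
          B(k, j) = bnew;
        }
        if (!std::isfinite(dmax)) { finite = false; break; }
        if (dmax < thr) break;
      }
      if (!finite) break;
      // w12 = W11 * beta
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        double v = 0.0;
        for (int mIdx = 0; mIdx < p; ++mIdx) {
          if (mIdx == j) continue;
          v += W(k, mIdx) * B(mIdx, j);
        }
        double d = std::fabs(v - W(k, j));
        if (d > dw) dw = d;
        W(k, j) = v;
        W(j, k) = v;
      }
      if (!std::isfinite(dw)) { finite = false; break; }
    }
    if (!finite) break;
    if (dw < thr) { converged = true; ++iter; break; }
  }

  // recover the precision matrix from W and the lasso coefficients
  NumericMatrix Theta(p, p);
  if (finite) {
    for (int j = 0; j < p; ++j) {
      double q = W(j, j);
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        q -= W(k, j) * B(k, j);
      }
      double tjj = 1.0 / q;
      Theta(j, j) = tjj;
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        Theta(k, j) = -B(k, j) * tjj;
      }
    }
    // symmetrize
    for (int i = 0; i < p; ++i)
      for (int j = i + 1; j < p; ++j) {
        double v = 0.5 * (Theta(i, j) + Theta(j, i));
        Theta(i, j) = v;
        Theta(j, i) = v;
      }
    for (int i = 0; i < p && finite; ++i)
      for (int j = 0; j < p; ++j)
        if (!std::isfinite(Theta(i, j)) || !std::isfinite(W(i, j)))
          finite = false;
  }

  return List::create(_["w"] = W, _["theta"] = Theta,
                      _["converged"] = converged, _["iterations"] = iter,
                      _["finite"] = finite);
}
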