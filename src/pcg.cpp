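#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Jacobi-preconditioned conjugate gradient for a symmetric positive-definite
// sparse system in compressed sparse column form (dgCMatrix slots).
// Returns the solution, the final relative residual and the iteration count.
// [[Rcpp::export]]
List pcg_solve(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
               NumericVector b, double tol, int maxit) {
  const int n = b.size();
  std::vector<double> x(n, 0.0), r(n), z(n), p(n), q(n), dinv(n);

  // diagonal for Jacobi preconditioner
  for (int j = 0; j < n; ++j) {
    double d = 0.0;
    for (int k = Ap[j]; k < Ap[j + 1]; ++k)
      if (Ai[k] == j) { d = Ax[k]; break; }
    if (d <= 0.0) stop("system diagonal not positive at unknown %d", j + 1);
    dinv[j] = 1.0 / d;
  }

  double bnorm = 0.0;
  for (int i = 0; i < n; ++i) { r[i] = b[i]; bnorm += b[i] * b[i]; }
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0)
    return List::create(_["x"] = NumericVector(n), _["relres"] = 0.0,
                        _["iter"] = 0);

  double rho = 0.0;
  for (int i = 0; i < n; ++i) { z[i] = dinv[i] * r[i]; rho += r[i] * z[i]; }
  p = z;

  double relres = 1.0;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    // q = A p; the matrix is symmetric, so the CSC column j is row j and
    // the product can be computed as a cache-friendly gather
    {
      const int* ap = INTEGER(Ap);
      const int* ai = INTEGER(Ai);
      const double* ax = REAL(Ax);
      const double* pv = p.data();
      for (int j = 0; j < n; ++j) {
        double acc = 0.0;
        for (int k = ap[j]; k < ap[j + 1]; ++k) acc += ax[k] * pv[ai[k]];
        q[j] = acc;
      }
    }
    double pq = 0.0;
    for (int i = 0; i < n; ++i) pq += p[i] * q[i];
    if (pq <= 0.0) stop("matrix not positive definite (p'Ap = %g)", pq);
    const double alpha = rho / pq;
    double rnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * q[i];
      rnorm += r[i] * r[i];
    }
    relres = std::sqrt(rnorm) / bnorm;
    if (relres < tol) break;
    double rho_new = 0.0;
    for (int i = 0; i < n; ++i) {
      z[i] = dinv[i] * r[i];
      rho_new += r[i] * z[i];
    }
    const double beta = rho_new / rho;
    rho = rho_new;
    for (int i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
  }

  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["relres"] = relres, _["iter"] = it);
}
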