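// Incomplete-Cholesky (IC0) preconditioned conjugate gradient for the
// sparse SPD systems produced by the finite-volume discretization.
// The matrix is passed in compressed sparse column form (dgCMatrix slots);
// the IC(0) factor is built on the lower-triangular pattern. The FVM
// matrix is a Stieltjes matrix, for which IC(0) exists; a diagonal shift
// retry guards against rounding-induced pivot breakdown.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct CscLower {
  std::vector<int> p, i;     // column pointers, row indices (rows >= col)
  std::vector<double> x;
  int n;
};

// extract the lower triangle (including diagonal) of a symmetric CSC matrix
CscLower lower_triangle(const IntegerVector& Ap, const IntegerVector& Ai,
                        const NumericVector& Ax, int n) {
  CscLower L;
  L.n = n;
  L.p.assign(n + 1, 0);
  for (int j = 0; j < n; ++j)
    for (int k = Ap[j]; k < Ap[j + 1]; ++k)
      if (Ai[k] >= j) ++L.p[j + 1];
  for (int j = 0; j < n; ++j) L.p[j + 1] += L.p[j];
  L.i.resize(L.p[n]);
  L.x.resize(L.p[n]);
  std::vector<int> pos(L.p.begin(), L.p.end() - 1);
  for (int j = 0; j < n; ++j)
    for (int k = Ap[j]; k < Ap[j + 1]; ++k)
      if (Ai[k] >= j) {
        L.i[pos[j]] = Ai[k];
        L.x[pos[j]] = Ax[k];
        ++pos[j];
      }
  return L;
}

// in-place IC(0): returns false on pivot breakdown
bool ic0(CscLower& L) {
  const int n = L.n;
  for (int j = 0; j < n; ++j) {
    int cj0 = L.p[j], cj1 = L.p[j + 1];
    if (cj0 >= cj1 || L.i[cj0] != j) return false;  // missing diagonal
    double d = L.x[cj0];
    if (d <= 0.0) return false;
    d = std::sqrt(d);
    L.x[cj0] = d;
    for (int k = cj0 + 1; k < cj1; ++k) L.x[k] /= d;
    // update remaining columns that appear as rows in column j
    for (int k = cj0 + 1; k < cj1; ++k) {
      int i2 = L.i[k];               // target column
      double ljk = L.x[k];
      int t0 = L.p[i2], t1 = L.p[i2 + 1];
      // subtract ljk * L(i, j) from existing entries (i, i2), i >= i2
      int t = t0;
      for (int m = k; m < cj1; ++m) {
        int irow = L.i[m];
        while (t < t1 && L.i[t] < irow) ++t;
        if (t < t1 && L.i[t] == irow) L.x[t] -= ljk * L.x[m];
      }
    }
  }
  return true;
}

// z = (L L^T)^{-1} r
void ic_solve(const CscLower& L, const std::vector<double>& r,
              std::vector<double>& y, std::vector<double>& z) {
  const int n = L.n;
  y.assign(r.begin(), r.end());
  for (int j = 0; j < n; ++j) {            // forward: L y = r
    int c0 = L.p[j], c1 = L.p[j + 1];
    double yj = y[j] / L.x[c0];
    y[j] = yj;
    for (int k = c0 + 1; k < c1; ++k) y[L.i[k]] -= L.x[k] * yj;
  }
  z.assign(y.begin(), y.end());
  for (int j = n - 1; j >= 0; --j) {       // backward: L^T z = y
    int c0 = L.p[j], c1 = L.p[j + 1];
    double s = z[j];
    for (int k = c0 + 1; k < c1; ++k) s -= L.x[k] * z[L.i[k]];
    z[j] = s / L.x[c0];
  }
}

void matvec(const IntegerVector& Ap, const IntegerVector& Ai,
            const NumericVector& Ax, const std::vector<double>& x,
            std::vector<double>& y) {
  const int n = (int)x.size();
  std::fill(y.begin(), y.end(), 0.0);
  for (int j = 0; j < n; ++j) {
    double xj = x[j];
    for (int k = Ap[j]; k < Ap[j + 1]; ++k) y[Ai[k]] += Ax[k] * xj;
  }
}

}  // namespace

// [[Rcpp::export(name = ".ic0_pcg")]]
List ic0_pcg(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
             NumericVector b, NumericVector x0, double tol, int maxit) {
  const int n = b.size();
  CscLower L = lower_triangle(Ap, Ai, Ax, n);
  // pivot-breakdown guard: retry with growing diagonal shift
  CscLower Lfac = L;
  double shift = 0.0;
  if (!ic0(Lfac)) {
    double dmean = 0.0;
    for (int j = 0; j < n; ++j) dmean += L.x[L.p[j]];
    dmean /= std::max(1, n);
    shift = 1e-3 * dmean;
    for (int tries = 0; tries < 8; ++tries, shift *= 10.0) {
      Lfac = L;
      for (int j = 0; j < n; ++j) Lfac.x[Lfac.p[j]] += shift;
      if (ic0(Lfac)) break;
      if (tries == 7) stop("IC(0) factorization failed");
    }
  }
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> r(n), z(n), p(n), Apv(n), ytmp(n);
  matvec(Ap, Ai, Ax, x, Apv);
  double bnorm = 0.0;
  for (int j = 0; j < n; ++j) {
    r[j] = b[j] - Apv[j];
    bnorm += b[j] * b[j];
  }
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) bnorm = 1.0;
  double rnorm = 0.0;
  for (int j = 0; j < n; ++j) rnorm += r[j] * r[j];
  rnorm = std::sqrt(rnorm);
  int it = 0;
  double rz = 0.0;
  if (rnorm / bnorm > tol) {
    ic_solve(Lfac, r, ytmp, z);
    p = z;
    for (int j = 0; j < n; ++j) rz += r[j] * z[j];
    for (it = 1; it <= maxit; ++it) {
      matvec(Ap, Ai, Ax, p, Apv);
      double pAp = 0.0;
      for (int j = 0; j < n; ++j) pAp += p[j] * Apv[j];
      double alpha = rz / pAp;
      rnorm = 0.0;
      for (int j = 0; j < n; ++j) {
        x[j] += alpha * p[j];
        r[j] -= alpha * Apv[j];
        rnorm += r[j] * r[j];
      }
      rnorm = std::sqrt(rnorm);
      if (rnorm / bnorm <= tol) break;
      ic_solve(Lfac, r, ytmp, z);
      double rz_new = 0.0;
      for (int j = 0; j < n; ++j) rz_new += r[j] * z[j];
      double beta = rz_new / rz;
      rz = rz_new;
      for (int j = 0; j < n; ++j) p[j] = z[j] + beta * p[j];
    }
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["iterations"] = std::min(it, maxit),
                      _["relres"] = rnorm / bnorm,
                      _["converged"] = (rnorm / bnorm <= tol),
                      _["shift"] = shift);
}
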