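#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gauss-Seidel / SOR relaxation for the flux-conservative 7-point
// discretisation of the desolvation-modified Poisson-Boltzmann equation.
//
// Node (i,j,k), 0-based, linear index i + n*(j + n*k) (column-major, matches
// R arrays). phi holds the boundary condition on the box faces; only
// interior nodes are updated. Per interior node the discrete balance is
//
//   phi0 * (E + A * sum_i z_i^2 lam_i)           (linear mode)
//     = S + src + A * sum_i z_i lam_i
//   F(phi0) = phi0*E - S - src - A*sum_i z_i lam_i exp(-z_i phi0) = 0
//                                                 (nonlinear mode, Newton)
//
// with E = sum of the six face permittivities, S = sum eps_f * phi_nbr,
// src = 4*pi*q_node'/h (q' scaled so phi is in kT/e), A = 4*pi*h^2*f*c and
// lam_i the per-species ion-accessibility weight exp(-dG_solv,i / RT).
//
// [[Rcpp::export]]
List pbe_relax(NumericVector phi, NumericVector epsx, NumericVector epsy,
               NumericVector epsz, NumericVector src, NumericMatrix lambda,
               IntegerVector zval, double A, int n, double tol, int maxit,
               double omega, bool nonlinear) {
  const int n2 = n * n;
  const int nm = n - 1;           // faces per axis
  const int nsp = zval.size();
  double *p = REAL(phi);
  const double *ex = REAL(epsx), *ey = REAL(epsy), *ez = REAL(epsz);
  const double *sq = REAL(src);
  NumericVector history(maxit);
  bool converged = false;
  int sweeps = 0;

  for (int it = 0; it < maxit; ++it) {
    double maxup = 0.0;
    for (int k = 1; k < n - 1; ++k) {
      for (int j = 1; j < n - 1; ++j) {
        const int base = n * j + n2 * k;
        for (int i = 1; i < n - 1; ++i) {
          const int id = i + base;
          // face permittivities: eps_x dims (n-1, n, n) etc.
          const double exl = ex[(i - 1) + nm * (j + n * k)];
          const double exr = ex[i       + nm * (j + n * k)];
          const double eyl = ey[i + n * ((j - 1) + nm * k)];
          const double eyr = ey[i + n * (j       + nm * k)];
          const double ezl = ez[i + n * (j + n * (k - 1))];
          const double ezr = ez[i + n * (j + n * k)];
          const double E = exl + exr + eyl + eyr + ezl + ezr;
          const double S = exl * p[id - 1]  + exr * p[id + 1]
                         + eyl * p[id - n]  + eyr * p[id + n]
                         + ezl * p[id - n2] + ezr * p[id + n2];
          double xnew;
          if (!nonlinear) {
            double coef = 0.0, cst = 0.0;
            for (int s = 0; s < nsp; ++s) {
              const double lam = lambda(id, s);
              coef += (double)zval[s] * zval[s] * lam;
              cst  += (double)zval[s] * lam;
            }
            xnew = (S + sq[id] + A * cst) / (E + A * coef);
          } else {
            // one Newton step per visit, from the current value
            const double x0 = p[id];
            double G = 0.0, dG = 0.0;
            for (int s = 0; s < nsp; ++s) {
              const double t = (double)zval[s] * lambda(id, s) *
                               std::exp(-(double)zval[s] * x0);
              G  += t;
              dG += (double)zval[s] * t;   // -dG/dphi = sum z^2 lam e^{-z phi}
            }
            const double F  = x0 * E - S - sq[id] - A * G;
            const double Fp = E + A * dG;
            xnew = x0 - F / Fp;
          }
          const double xr = (1.0 - omega) * p[id] + omega * xnew;
          const double up = std::fabs(xr - p[id]);
          if (up > maxup) maxup = up;
          p[id] = xr;
        }
      }
    }
    if (!std::isfinite(maxup))
      stop("numerical error: non-finite potential during relaxation sweep %d",
           it + 1);
    history[it] = maxup;
    sweeps = it + 1;
    if (maxup <= tol) { converged = true; break; }
  }
  return List::create(_["iterations"] = sweeps,
                      _["converged"] = converged,
                      _["history"] = history[Range(0, sweeps - 1)]);
}

// Binary min-heap ranking of candidate sites by energy, with lexicographic
// grid-index tie-break (ix, then iy, then iz). Only negative energies are
// stored; returns 1-based positions into the input vectors, in pop order.
//
// [[Rcpp::export]]
IntegerVector heap_rank(NumericVector energy, IntegerVector ix,
                        IntegerVector iy, IntegerVector iz) {
  const int m = energy.size();
  std::vector<int> heap;
  heap.reserve(m);
  const double *e = REAL(energy);
  const int *x = INTEGER(ix), *y = INTEGER(iy), *z = INTEGER(iz);

  auto before = [&](int a, int b) {   // strict priority order
    if (e[a] != e[b]) return e[a] < e[b];
    if (x[a] != x[b]) return x[a] < x[b];
    if (y[a] != y[b]) return y[a] < y[b];
    return z[a] < z[b];
  };

  for (int i = 0; i < m; ++i) {
    if (e[i] >= 0.0) continue;       // only negative-energy sites are stored
    heap.push_back(i);
    int c = (int)heap.size() - 1;
    while (c > 0) {
      int par = (c - 1) / 2;
      if (before(heap[c], heap[par])) { std::swap(heap[c], heap[par]); c = par; }
      else break;
    }
  }
  const int kept = (int)heap.size();
  IntegerVector out(kept);
  for (int r = 0; r < kept; ++r) {
    out[r] = heap[0] + 1;
    heap[0] = heap.back();
    heap.pop_back();
    int c = 0, sz = (int)heap.size();
    while (true) {
      int l = 2 * c + 1, rgt = l + 1, best = c;
      if (l < sz && before(heap[l], heap[best])) best = l;
      if (rgt < sz && before(heap[rgt], heap[best])) best = rgt;
      if (best == c) break;
      std::swap(heap[c], heap[best]);
      c = best;
    }
  }
  return out;
}
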