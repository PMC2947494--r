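#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Harmonic mean of two node dielectric values: the face permittivity of the
// flux-conservative 7-point stencil.
static inline double hmean(double a, double b) { return 2.0 * a * b / (a + b); }

// y <- A x at interior nodes, where
//   (A x)_p = sum_faces c_f (x_p - x_nb) + diag_p x_p,
//   c_f = hmean(eps_p, eps_nb) / h_axis^2.
// Boundary entries of x are read (Dirichlet coupling) but y is left 0 there.
static void apply_op(const double* eps, const double* dg, const double* x,
                     double* y, int nx, int ny, int nz,
                     double ax, double ay, double az) {
  const long nxy = (long)nx * ny;
  for (int k = 1; k < nz - 1; ++k) {
    for (int j = 1; j < ny - 1; ++j) {
      long row = 1 + nx * (long)j + nxy * k;
      for (int i = 1; i < nx - 1; ++i) {
        long p = row + (i - 1);
        double e0 = eps[p];
        double cxm = ax * hmean(e0, eps[p - 1]);
        double cxp = ax * hmean(e0, eps[p + 1]);
        double cym = ay * hmean(e0, eps[p - nx]);
        double cyp = ay * hmean(e0, eps[p + nx]);
        double czm = az * hmean(e0, eps[p - nxy]);
        double czp = az * hmean(e0, eps[p + nxy]);
        y[p] = (cxm + cxp + cym + cyp + czm + czp + dg[p]) * x[p]
             - cxm * x[p - 1] - cxp * x[p + 1]
             - cym * x[p - nx] - cyp * x[p + nx]
             - czm * x[p - nxy] - czp * x[p + nxy];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector lpbe_apply_cpp(NumericVector eps, NumericVector diag,
                             NumericVector x, IntegerVector dims,
                             NumericVector h) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector y(eps.size());
  apply_op(eps.begin(), diag.begin(), x.begin(), y.begin(), nx, ny, nz,
           1.0 / (h[0] * h[0]), 1.0 / (h[1] * h[1]), 1.0 / (h[2] * h[2]));
  return y;
}

// Jacobi-preconditioned conjugate gradient for A phi = rhs with Dirichlet
// boundary values bnd on the six faces.  All vectors are full-grid length;
// boundary contributions are folded into the right-hand side, then CG runs
// on the interior unknowns (boundary entries of the work vectors stay 0).
// [[Rcpp::export]]
List lpbe_cg_cpp(NumericVector eps, NumericVector diag, NumericVector rhs,
                 NumericVector bnd, IntegerVector dims, NumericVector h,
                 double tol, int maxit) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long N = (long)nx * ny * nz;
  const long nxy = (long)nx * ny;
  double ax = 1.0 / (h[0] * h[0]), ay = 1.0 / (h[1] * h[1]),
         az = 1.0 / (h[2] * h[2]);

  std::vector<double> x(N, 0.0), r(N, 0.0), z(N, 0.0), p(N, 0.0),
      Ap(N, 0.0), dA(N, 1.0);

  // Boundary-lifted vector: boundary = bnd, interior = 0.
  std::vector<double> xb(N, 0.0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (i == 0 || j == 0 || k == 0 || i == nx - 1 || j == ny - 1 ||
            k == nz - 1) {
          long q = i + nx * (long)j + nxy * k;
          xb[q] = bnd[q];
        }
  apply_op(eps.begin(), diag.begin(), xb.data(), r.data(), nx, ny, nz, ax, ay,
           az);
  // r = rhs_eff = rhs - A*lift  (interior only)
  double bnorm2 = 0.0;
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        long q = i + nx * (long)j + nxy * k;
        r[q] = rhs[q] - r[q];
        bnorm2 += r[q] * r[q];
        double e0 = eps[q];
        dA[q] = ax * (hmean(e0, eps[q - 1]) + hmean(e0, eps[q + 1])) +
                ay * (hmean(e0, eps[q - nx]) + hmean(e0, eps[q + nx])) +
                az * (hmean(e0, eps[q - nxy]) + hmean(e0, eps[q + nxy])) +
                diag[q];
      }

  int iters = 0;
  double relres = 0.0;
  if (bnorm2 == 0.0) {
    relres = 0.0;  // solution is pure boundary lift
  } else {
    double rz = 0.0;
    for (long q = 0; q < N; ++q) {
      z[q] = r[q] / dA[q];
      p[q] = z[q];
      rz += r[q] * z[q];
    }
    double bnorm = std::sqrt(bnorm2);
    for (iters = 1; iters <= maxit; ++iters) {
      std::fill(Ap.begin(), Ap.end(), 0.0);
      apply_op(eps.begin(), diag.begin(), p.data(), Ap.data(), nx, ny, nz, ax,
               ay, az);
      double pAp = 0.0;
      for (long q = 0; q < N; ++q) pAp += p[q] * Ap[q];
      double alpha = rz / pAp;
      double rnorm2 = 0.0;
      for (long q = 0; q < N; ++q) {
        x[q] += alpha * p[q];
        r[q] -= alpha * Ap[q];
        rnorm2 += r[q] * r[q];
      }
      relres = std::sqrt(rnorm2) / bnorm;
      if (relres <= tol) break;
      double rz_new = 0.0;
      for (long q = 0; q < N; ++q) {
        z[q] = r[q] / dA[q];
        rz_new += r[q] * z[q];
      }
      double beta = rz_new / rz;
      rz = rz_new;
      for (long q = 0; q < N; ++q) p[q] = z[q] + beta * p[q];
    }
  }

  NumericVector phi(N);
  for (long q = 0; q < N; ++q) phi[q] = x[q] + xb[q];
  return List::create(_["phi"] = phi, _["iterations"] = iters,
                      _["relres"] = relres,
                      _["converged"] = (relres <= tol));
}

// Mark grid nodes lying strictly inside any of a set of spheres.
// [[Rcpp::export]]
LogicalVector nodes_in_spheres_cpp(IntegerVector dims, NumericVector origin,
                                   NumericVector h, NumericMatrix centers,
                                   NumericVector radii) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long N = (long)nx * ny * nz;
  LogicalVector out(N, false);
  int ns = centers.nrow();
  for (int s = 0; s < ns; ++s) {
    double cx = centers(s, 0), cy = centers(s, 1), cz = centers(s, 2);
    double r = radii[s];
    if (r <= 0) continue;
    double r2 = r * r;
    int i0 = (int)std::ceil((cx - r - origin[0]) / h[0]);
    int i1 = (int)std::floor((cx + r - origin[0]) / h[0]);
    int j0 = (int)std::ceil((cy - r - origin[1]) / h[1]);
    int j1 = (int)std::floor((cy + r - origin[1]) / h[1]);
    int k0 = (int)std::ceil((cz - r - origin[2]) / h[2]);
    int k1 = (int)std::floor((cz + r - origin[2]) / h[2]);
    if (i0 < 0) i0 = 0; if (i1 > nx - 1) i1 = nx - 1;
    if (j0 < 0) j0 = 0; if (j1 > ny - 1) j1 = ny - 1;
    if (k0 < 0) k0 = 0; if (k1 > nz - 1) k1 = nz - 1;
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + k * h[2] - cz;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j * h[1] - cy;
        double dyz = dy * dy + dz * dz;
        if (dyz > r2) continue;
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + i * h[0] - cx;
          if (dx * dx + dyz < r2)
            out[i + nx * (long)j + (long)nx * ny * k] = true;
        }
      }
    }
  }
  return out;
}

// For each query point, is it buried inside any sphere (dist < radius - tol)?
// Used to test solvent-probe centers against the inflated atom spheres.
// [[Rcpp::export]]
LogicalVector points_buried_cpp(NumericMatrix pts, NumericMatrix centers,
                                NumericVector radii, double tol) {
  int np = pts.nrow(), ns = centers.nrow();
  LogicalVector out(np, false);
  for (int i = 0; i < np; ++i) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    for (int s = 0; s < ns; ++s) {
      double r = radii[s] - tol;
      if (r <= 0) continue;
      double dx = px - centers(s, 0), dy = py - centers(s, 1),
             dz = pz - centers(s, 2);
      if (dx * dx + dy * dy + dz * dz < r * r) {
        out[i] = true;
        break;
      }
    }
  }
  return out;
}
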