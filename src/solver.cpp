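// Structured-grid finite-volume discretization of div(sigma grad phi) = 0
// with harmonic-mean face conductivities, and a matrix-free Jacobi
// preconditioned conjugate-gradient solver. Grids are column-major
// (i fastest), matching R arrays. Lengths arrive in mm, conductivity in
// S/m; face conductances are formed in siemens so currents come out in A.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double harm(double a, double b) {
  if (a <= 0.0 || b <= 0.0) return 0.0;
  return 2.0 * a * b / (a + b);
}

struct Grid {
  int nx, ny, nz;
  double hx, hy, hz;               // mm
  std::vector<double> gx, gy, gz;  // face conductances (S)
  std::vector<double> diag;        // row sums of face conductances

  Grid(IntegerVector dims, NumericVector h, const NumericVector& sigma) {
    nx = dims[0]; ny = dims[1]; nz = dims[2];
    hx = h[0]; hy = h[1]; hz = h[2];
    size_t n = (size_t)nx * ny * nz;
    gx.assign(n, 0.0); gy.assign(n, 0.0); gz.assign(n, 0.0);
    diag.assign(n, 0.0);
    // conductance scale: sigma [S/m] * area [mm^2] / dist [mm] * 1e-3 -> S
    const double cx = hy * hz / hx * 1e-3;
    const double cy = hx * hz / hy * 1e-3;
    const double cz = hx * hy / hz * 1e-3;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t id = idx(i, j, k);
          double s = sigma[id];
          if (i + 1 < nx) gx[id] = cx * harm(s, sigma[idx(i + 1, j, k)]);
          if (j + 1 < ny) gy[id] = cy * harm(s, sigma[idx(i, j + 1, k)]);
          if (k + 1 < nz) gz[id] = cz * harm(s, sigma[idx(i, j, k + 1)]);
        }
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t id = idx(i, j, k);
          double d = gx[id] + gy[id] + gz[id];
          if (i > 0) d += gx[idx(i - 1, j, k)];
          if (j > 0) d += gy[idx(i, j - 1, k)];
          if (k > 0) d += gz[idx(i, j, k - 1)];
          diag[id] = d;
        }
  }
  inline size_t idx(int i, int j, int k) const {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
  }
};

// y = A x restricted to active cells (x assumed 0 on inactive cells)
static void matvec(const Grid& g, const std::vector<char>& active,
                   const std::vector<double>& x, std::vector<double>& y) {
  const int nx = g.nx, ny = g.ny, nz = g.nz;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t id = g.idx(i, j, k);
        if (!active[id]) { y[id] = 0.0; continue; }
        double acc = g.diag[id] * x[id];
        if (i + 1 < nx && active[id + 1])        acc -= g.gx[id] * x[id + 1];
        if (i > 0 && active[id - 1])             acc -= g.gx[id - 1] * x[id - 1];
        size_t sy = (size_t)nx;
        if (j + 1 < ny && active[id + sy])       acc -= g.gy[id] * x[id + sy];
        if (j > 0 && active[id - sy])            acc -= g.gy[id - sy] * x[id - sy];
        size_t sz = (size_t)nx * ny;
        if (k + 1 < nz && active[id + sz])       acc -= g.gz[id] * x[id + sz];
        if (k > 0 && active[id - sz])            acc -= g.gz[id - sz] * x[id - sz];
        y[id] = acc;
      }
}

// Incomplete Cholesky (zero fill) for the 7-point operator, used as the
// CG preconditioner: M = (L+D) D^{-1} (L+D)^T with L the strict lower
// triangle of A (entries -g) and D from the factorization sweep.
struct IC0 {
  const Grid& g;
  const std::vector<char>& active;
  std::vector<double> d;
  // modified incomplete Cholesky: discarded fill is compensated into the
  // pivot (theta < 1 keeps the factorization safely positive)
  IC0(const Grid& gg, const std::vector<char>& act, double theta = 0.95)
      : g(gg), active(act) {
    const int nx = g.nx, ny = g.ny, nz = g.nz;
    const size_t sy = (size_t)nx, sz = (size_t)nx * ny;
    size_t n = (size_t)nx * ny * nz;
    d.assign(n, 1.0);
    auto up = [&](size_t j, int skip) {
      // nonzero face conductance implies the +direction neighbor exists
      double s = 0.0;
      if (skip != 0 && g.gx[j] > 0 && active[j + 1])  s += g.gx[j];
      if (skip != 1 && g.gy[j] > 0 && active[j + sy]) s += g.gy[j];
      if (skip != 2 && g.gz[j] > 0 && active[j + sz]) s += g.gz[j];
      return s;
    };
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t id = g.idx(i, j, k);
          if (!active[id]) continue;
          double t = g.diag[id];
          if (i > 0 && active[id - 1] && d[id - 1] > 0) {
            size_t jj = id - 1;
            t -= g.gx[jj] * (g.gx[jj] + theta * up(jj, 0)) / d[jj];
          }
          if (j > 0 && active[id - sy] && d[id - sy] > 0) {
            size_t jj = id - sy;
            t -= g.gy[jj] * (g.gy[jj] + theta * up(jj, 1)) / d[jj];
          }
          if (k > 0 && active[id - sz] && d[id - sz] > 0) {
            size_t jj = id - sz;
            t -= g.gz[jj] * (g.gz[jj] + theta * up(jj, 2)) / d[jj];
          }
          d[id] = (t > 1e-8 * g.diag[id]) ? t : g.diag[id];
        }
  }
  // z = M^{-1} r
  void apply(const std::vector<double>& r, std::vector<double>& z) const {
    const int nx = g.nx, ny = g.ny, nz = g.nz;
    const size_t sy = (size_t)nx, sz = (size_t)nx * ny;
    // forward: (L+D) u = r, stored into z
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t id = g.idx(i, j, k);
          if (!active[id]) { z[id] = 0.0; continue; }
          double t = r[id];
          if (i > 0 && active[id - 1])  t += g.gx[id - 1] * z[id - 1];
          if (j > 0 && active[id - sy]) t += g.gy[id - sy] * z[id - sy];
          if (k > 0 && active[id - sz]) t += g.gz[id - sz] * z[id - sz];
          z[id] = t / d[id];
        }
    // scale: u2 = D u ; backward: (L+D)^T zfinal = u2
    for (int k = nz - 1; k >= 0; --k)
      for (int j = ny - 1; j >= 0; --j)
        for (int i = nx - 1; i >= 0; --i) {
          size_t id = g.idx(i, j, k);
          if (!active[id]) continue;
          double t = z[id] * d[id];
          if (i + 1 < nx && active[id + 1])  t += g.gx[id] * z[id + 1];
          if (j + 1 < ny && active[id + sy]) t += g.gy[id] * z[id + sy];
          if (k + 1 < nz && active[id + sz]) t += g.gz[id] * z[id + sz];
          z[id] = t / d[id];
        }
  }
};

// [[Rcpp::export(name = ".fv_solve")]]
List fv_solve(IntegerVector dims, NumericVector h, NumericVector sigma,
              IntegerVector fixed, NumericVector fixedval,
              NumericVector phi0, double tol = 1e-7, int maxit = 20000) {
  Grid g(dims, h, sigma);
  size_t n = (size_t)g.nx * g.ny * g.nz;
  std::vector<char> active(n);
  bool any_fixed = false;
  for (size_t id = 0; id < n; ++id) {
    active[id] = (fixed[id] == 0 && sigma[id] > 0.0) ? 1 : 0;
    if (fixed[id] != 0) any_fixed = true;
  }
  if (!any_fixed) stop("no fixed-potential (electrode) cells: singular system");
  IC0 prec(g, active);

  // boundary values folded into the right-hand side
  std::vector<double> x(n, 0.0), b(n, 0.0), r(n), z(n), p(n), Ap(n);
  const int nx = g.nx, ny = g.ny, nz = g.nz;
  const size_t sy = (size_t)nx, sz = (size_t)nx * ny;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t id = g.idx(i, j, k);
        if (!active[id]) continue;
        x[id] = phi0[id];
        double acc = 0.0;
        if (i + 1 < nx && fixed[id + 1])   acc += g.gx[id] * fixedval[id + 1];
        if (i > 0 && fixed[id - 1])        acc += g.gx[id - 1] * fixedval[id - 1];
        if (j + 1 < ny && fixed[id + sy])  acc += g.gy[id] * fixedval[id + sy];
        if (j > 0 && fixed[id - sy])       acc += g.gy[id - sy] * fixedval[id - sy];
        if (k + 1 < nz && fixed[id + sz])  acc += g.gz[id] * fixedval[id + sz];
        if (k > 0 && fixed[id - sz])       acc += g.gz[id - sz] * fixedval[id - sz];
        b[id] = acc;
      }

  double bnorm = 0.0;
  for (size_t id = 0; id < n; ++id) bnorm += b[id] * b[id];
  bnorm = std::sqrt(bnorm);

  int it = 0;
  double relres = 0.0;
  if (bnorm == 0.0) {
    std::fill(x.begin(), x.end(), 0.0);
  } else {
    matvec(g, active, x, Ap);
    for (size_t id = 0; id < n; ++id)
      r[id] = active[id] ? b[id] - Ap[id] : 0.0;
    prec.apply(r, z);
    double rz = 0.0;
    for (size_t id = 0; id < n; ++id) { p[id] = z[id]; rz += r[id] * z[id]; }
    for (it = 0; it < maxit; ++it) {
      double rn = 0.0;
      for (size_t id = 0; id < n; ++id) rn += r[id] * r[id];
      relres = std::sqrt(rn) / bnorm;
      if (relres <= tol) break;
      matvec(g, active, p, Ap);
      double pAp = 0.0;
      for (size_t id = 0; id < n; ++id) pAp += p[id] * Ap[id];
      if (pAp <= 0.0) break;
      double alpha = rz / pAp;
      for (size_t id = 0; id < n; ++id) {
        x[id] += alpha * p[id];
        r[id] -= alpha * Ap[id];
      }
      prec.apply(r, z);
      double rznew = 0.0;
      for (size_t id = 0; id < n; ++id) rznew += r[id] * z[id];
      double beta = rznew / rz;
      rz = rznew;
      for (size_t id = 0; id < n; ++id) p[id] = z[id] + beta * p[id];
    }
  }

  NumericVector phi(n);
  for (size_t id = 0; id < n; ++id)
    phi[id] = fixed[id] ? fixedval[id] : x[id];
  return List::create(_["phi"] = phi, _["iterations"] = it,
                      _["relres"] = relres,
                      _["converged"] = (bnorm == 0.0 || relres <= tol));
}

// Cell-centered field magnitude |grad phi| in V/mm. Central differences
// where both neighbors conduct, one-sided otherwise; non-conducting cells
// (sigma <= 0) report 0 and are excluded from their neighbors' stencils.
// [[Rcpp::export(name = ".field_magnitude")]]
NumericVector field_magnitude(NumericVector phi, IntegerVector dims,
                              NumericVector h, NumericVector sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector E(n);
  const size_t sy = (size_t)nx, sz = (size_t)nx * ny;
  auto idx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t id = idx(i, j, k);
        if (sigma[id] <= 0.0) { E[id] = 0.0; continue; }
        double gx = 0, gy = 0, gz = 0;
        bool lo, hi;
        lo = i > 0 && sigma[id - 1] > 0; hi = i + 1 < nx && sigma[id + 1] > 0;
        if (lo && hi) gx = (phi[id + 1] - phi[id - 1]) / (2 * h[0]);
        else if (hi)  gx = (phi[id + 1] - phi[id]) / h[0];
        else if (lo)  gx = (phi[id] - phi[id - 1]) / h[0];
        lo = j > 0 && sigma[id - sy] > 0; hi = j + 1 < ny && sigma[id + sy] > 0;
        if (lo && hi) gy = (phi[id + sy] - phi[id - sy]) / (2 * h[1]);
        else if (hi)  gy = (phi[id + sy] - phi[id]) / h[1];
        else if (lo)  gy = (phi[id] - phi[id - sy]) / h[1];
        lo = k > 0 && sigma[id - sz] > 0; hi = k + 1 < nz && sigma[id + sz] > 0;
        if (lo && hi) gz = (phi[id + sz] - phi[id - sz]) / (2 * h[2]);
        else if (hi)  gz = (phi[id + sz] - phi[id]) / h[2];
        else if (lo)  gz = (phi[id] - phi[id - sz]) / h[2];
        E[id] = std::sqrt(gx * gx + gy * gy + gz * gz);
      }
  return E;
}

// Net current (A) flowing out of a marked cell set through its boundary
// faces, from the discrete face fluxes.
// [[Rcpp::export(name = ".set_current")]]
double set_current(NumericVector phi, IntegerVector dims, NumericVector h,
                   NumericVector sigma, LogicalVector inset) {
  Grid g(dims, h, sigma);
  int nx = g.nx, ny = g.ny, nz = g.nz;
  const size_t sy = (size_t)nx, sz = (size_t)nx * ny;
  double I = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t id = g.idx(i, j, k);
        if (!inset[id]) continue;
        if (i + 1 < nx && !inset[id + 1])  I += g.gx[id] * (phi[id] - phi[id + 1]);
        if (i > 0 && !inset[id - 1])       I += g.gx[id - 1] * (phi[id] - phi[id - 1]);
        if (j + 1 < ny && !inset[id + sy]) I += g.gy[id] * (phi[id] - phi[id + sy]);
        if (j > 0 && !inset[id - sy])      I += g.gy[id - sy] * (phi[id] - phi[id - sy]);
        if (k + 1 < nz && !inset[id + sz]) I += g.gz[id] * (phi[id] - phi[id + sz]);
        if (k > 0 && !inset[id - sz])      I += g.gz[id - sz] * (phi[id] - phi[id - sz]);
      }
  return I;
}
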