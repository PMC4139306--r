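#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation on a uniform grid; points outside the hull are
// clamped to the hull faces.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector values, NumericVector origin,
                            double spacing, NumericMatrix pts) {
  IntegerVector dv = values.attr("dim");
  const int nx = dv[0], ny = dv[1], nz = dv[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double *v = values.begin();
  for (int p = 0; p < n; ++p) {
    double fx = (pts(p, 0) - origin[0]) / spacing;
    double fy = (pts(p, 1) - origin[1]) / spacing;
    double fz = (pts(p, 2) - origin[2]) / spacing;
    fx = std::min(std::max(fx, 0.0), (double)(nx - 1));
    fy = std::min(std::max(fy, 0.0), (double)(ny - 1));
    fz = std::min(std::max(fz, 0.0), (double)(nz - 1));
    int i0 = std::min((int)std::floor(fx), nx - 2);
    int j0 = std::min((int)std::floor(fy), ny - 2);
    int k0 = std::min((int)std::floor(fz), nz - 2);
    double tx = fx - i0, ty = fy - j0, tz = fz - k0;
    double acc = 0.0;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          double w = (di ? tx : 1 - tx) * (dj ? ty : 1 - ty) *
                     (dk ? tz : 1 - tz);
          acc += w * v[(size_t)(i0 + di) +
                       (size_t)nx * ((j0 + dj) + (size_t)ny * (k0 + dk))];
        }
    out[p] = acc;
  }
  return out;
}

// Screened-Coulomb (Debye-Hueckel) superposition over point charges:
//   phi(r) = sum_i q_i * K * exp(-kappa*(r_i - a)) / (eps * (1 + kappa*a) * r_i)
// in kcal/mol/e, with r_i clamped below r_min (clamped voxels reported).
// [[Rcpp::export]]
List cpp_analytic_potential(NumericMatrix coords, NumericVector charges,
                            IntegerVector dims, NumericVector origin,
                            double spacing, double kappa, double eps,
                            double coulomb_k, NumericVector a_ion,
                            double r_min = 1e-3) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((size_t)nx * ny * nz);
  out.attr("dim") = dims;
  std::vector<int> clamped;
  const int na = coords.nrow();
  // per-atom prefactor and exclusion radius (a_ion recycled if scalar)
  std::vector<double> pref(na), aexc(na);
  for (int a = 0; a < na; ++a) {
    aexc[a] = a_ion[a % a_ion.size()];
    pref[a] = coulomb_k / (eps * (1.0 + kappa * aexc[a]));
  }
  for (int k = 0; k < nz; ++k) {
    double z = origin[2] + k * spacing;
    for (int j = 0; j < ny; ++j) {
      double y = origin[1] + j * spacing;
      size_t base = (size_t)nx * (j + (size_t)ny * k);
      for (int i = 0; i < nx; ++i) {
        double x = origin[0] + i * spacing;
        double acc = 0.0;
        bool cl = false;
        for (int a = 0; a < na; ++a) {
          double dx = x - coords(a, 0), dy = y - coords(a, 1),
                 dz = z - coords(a, 2);
          double r = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (r < r_min) { r = r_min; cl = true; }
          acc += charges[a] * pref[a] * std::exp(-kappa * (r - aexc[a])) / r;
        }
        out[base + i] = acc;
        if (cl) clamped.push_back((int)(base + i) + 1);
      }
    }
  }
  return List::create(_["values"] = out, _["clamped"] = wrap(clamped));
}

// Row-wise median of the first `used` columns (used is odd in remedian use,
// but general n is supported with the lower/upper midpoint rule).
// [[Rcpp::export]]
NumericVector cpp_row_median(NumericMatrix m, int used) {
  const int n = m.nrow();
  NumericVector out(n);
  std::vector<double> buf(used);
  for (int r = 0; r < n; ++r) {
    for (int c = 0; c < used; ++c) buf[c] = m(r, c);
    std::sort(buf.begin(), buf.begin() + used);
    out[r] = (used % 2) ? buf[used / 2]
                        : 0.5 * (buf[used / 2 - 1] + buf[used / 2]);
  }
  return out;
}

// Weighted-median completion of the remedian buffers: per voxel, the
// counts[l] entries of buffer l carry weight w[l] = b^l; the weighted median
// is the smallest value whose cumulative weight reaches half the total
// (midpoint of the straddling pair when it hits half exactly).
// [[Rcpp::export]]
NumericVector cpp_weighted_median(List bufs, IntegerVector counts,
                                  NumericVector weights) {
  const int k = bufs.size();
  std::vector<NumericMatrix> B;
  for (int l = 0; l < k; ++l) B.push_back(as<NumericMatrix>(bufs[l]));
  int nvox = B[0].nrow();
  int m = 0;
  double wtot = 0.0;
  for (int l = 0; l < k; ++l) { m += counts[l]; wtot += counts[l] * weights[l]; }
  NumericVector out(nvox);
  std::vector<std::pair<double, double>> vw(m);
  for (int r = 0; r < nvox; ++r) {
    int p = 0;
    for (int l = 0; l < k; ++l)
      for (int c = 0; c < counts[l]; ++c) vw[p++] = {B[l](r, c), weights[l]};
    std::sort(vw.begin(), vw.end());
    double half = wtot / 2.0, cum = 0.0;
    for (int i = 0; i < m; ++i) {
      cum += vw[i].second;
      if (cum > half) { out[r] = vw[i].first; break; }
      if (cum == half) { out[r] = 0.5 * (vw[i].first + vw[i + 1].first); break; }
    }
  }
  return out;
}

static inline size_t idx3(int i, int j, int k, int nx, int ny) {
  return (size_t)i + (size_t)nx * (j + (size_t)ny * k);
}

// Red-black SOR for the 7-point variable-coefficient stencil
//   sum_f eps_f (phi_nbr - phi_c)/h^2 - kbar2_c phi_c + src_c = 0
// with Dirichlet boundary values already present in phi. eps_x has dims
// (nx-1, ny, nz) etc. (face between voxel i and i+1). src = 4*pi*K*q/h^3.
// Deterministic: result at convergence is independent of traversal order.
// [[Rcpp::export]]
List cpp_sor_solve(NumericVector phi_in, NumericVector eps_x,
                   NumericVector eps_y, NumericVector eps_z,
                   NumericVector kbar2, NumericVector src, IntegerVector dims,
                   double h, double omega, double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector phi = clone(phi_in);
  const double h2 = h * h;
  const double *ex = eps_x.begin(), *ey = eps_y.begin(), *ez = eps_z.begin();
  const double *kb = kbar2.begin(), *b = src.begin();
  double *ph = phi.begin();
  const int nxm = nx - 1, nym = ny - 1;

  // reference norm: source plus boundary-value contributions
  double bnorm2 = 0.0;
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        size_t c = idx3(i, j, k, nx, ny);
        double bc = b[c];
        if (i == 1) bc += ex[idx3(0, j, k, nxm, ny)] * ph[idx3(0, j, k, nx, ny)] / h2;
        if (i == nx - 2) bc += ex[idx3(nx - 2, j, k, nxm, ny)] * ph[idx3(nx - 1, j, k, nx, ny)] / h2;
        if (j == 1) bc += ey[idx3(i, 0, k, nx, nym)] * ph[idx3(i, 0, k, nx, ny)] / h2;
        if (j == ny - 2) bc += ey[idx3(i, ny - 2, k, nx, nym)] * ph[idx3(i, ny - 1, k, nx, ny)] / h2;
        if (k == 1) bc += ez[idx3(i, j, 0, nx, ny)] * ph[idx3(i, j, 0, nx, ny)] / h2;
        if (k == nz - 2) bc += ez[idx3(i, j, nz - 2, nx, ny)] * ph[idx3(i, j, nz - 1, nx, ny)] / h2;
        bnorm2 += bc * bc;
      }
  double bnorm = std::sqrt(bnorm2);
  if (bnorm == 0.0) bnorm = 1.0;

  double rel = NA_REAL;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    for (int color = 0; color < 2; ++color) {
      for (int k = 1; k < nz - 1; ++k)
        for (int j = 1; j < ny - 1; ++j) {
          int istart = 1 + ((j + k + 1 + color) % 2);
          for (int i = istart; i < nx - 1; i += 2) {
            size_t c = idx3(i, j, k, nx, ny);
            double exl = ex[idx3(i - 1, j, k, nxm, ny)];
            double exr = ex[idx3(i, j, k, nxm, ny)];
            double eyl = ey[idx3(i, j - 1, k, nx, nym)];
            double eyr = ey[idx3(i, j, k, nx, nym)];
            double ezl = ez[idx3(i, j, k - 1, nx, ny)];
            double ezr = ez[idx3(i, j, k, nx, ny)];
            double num = (exl * ph[c - 1] + exr * ph[c + 1] +
                          eyl * ph[c - nx] + eyr * ph[c + nx] +
                          ezl * ph[c - (size_t)nx * ny] +
                          ezr * ph[c + (size_t)nx * ny]) / h2 + b[c];
            double den = (exl + exr + eyl + eyr + ezl + ezr) / h2 + kb[c];
            double target = num / den;
            ph[c] += omega * (target - ph[c]);
          }
        }
    }
    if (it % 5 == 0 || it == maxit) {
      double r2 = 0.0;
      for (int k = 1; k < nz - 1; ++k)
        for (int j = 1; j < ny - 1; ++j)
          for (int i = 1; i < nx - 1; ++i) {
            size_t c = idx3(i, j, k, nx, ny);
            double exl = ex[idx3(i - 1, j, k, nxm, ny)];
            double exr = ex[idx3(i, j, k, nxm, ny)];
            double eyl = ey[idx3(i, j - 1, k, nx, nym)];
            double eyr = ey[idx3(i, j, k, nx, nym)];
            double ezl = ez[idx3(i, j, k - 1, nx, ny)];
            double ezr = ez[idx3(i, j, k, nx, ny)];
            double r = (exl * (ph[c - 1] - ph[c]) + exr * (ph[c + 1] - ph[c]) +
                        eyl * (ph[c - nx] - ph[c]) + eyr * (ph[c + nx] - ph[c]) +
                        ezl * (ph[c - (size_t)nx * ny] - ph[c]) +
                        ezr * (ph[c + (size_t)nx * ny] - ph[c])) / h2 -
                       kb[c] * ph[c] + b[c];
            r2 += r * r;
          }
      rel = std::sqrt(r2) / bnorm;
      if (rel <= tol) break;
    }
  }
  phi.attr("dim") = dims;
  return List::create(_["phi"] = phi, _["iterations"] = std::min(it, maxit),
                      _["residual"] = rel,
                      _["converged"] = (rel <= tol));
}
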