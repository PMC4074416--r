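#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher separable lower-envelope distance transform,
// generalised to anisotropic sample spacing. Squared distances separate per
// axis, so applying the 1D transform along x, then y, then z with each
// axis's physical step yields the exact Euclidean distance in mm.
static void dt1d(std::vector<double>& f, int n, double step,
                 std::vector<double>& d, std::vector<int>& v,
                 std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * step;
    while (true) {
      double xv = v[k] * step;
      double s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) {
        --k;
      } else {
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * step;
    d[q] = dx * dx + f[v[k]];
  }
}

// Exact Euclidean distance (mm) from every voxel center to the nearest
// TRUE voxel center of `mask`, honouring anisotropic spacing.
// [[Rcpp::export(name = ".edt_mm")]]
NumericVector edt_mm(LogicalVector mask, IntegerVector dims,
                     NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  // finite "far" sentinel (> any achievable squared distance) keeps the
  // lower-envelope intersection arithmetic well-defined on empty lines
  double far2 = 0.0;
  far2 += (double)nx * spacing[0] * nx * spacing[0];
  far2 += (double)ny * spacing[1] * ny * spacing[1];
  far2 += (double)nz * spacing[2] * nz * spacing[2];
  far2 = 4.0 * far2 + 1.0;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : far2;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // along x (fastest-varying)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, nx, spacing[0], d, v, z);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, ny, spacing[1], d, v, z);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // along z
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nxy];
      dt1d(f, nz, spacing[2], d, v, z);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nxy] = std::sqrt(d[k]);
    }
  return out;
}
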