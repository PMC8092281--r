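#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Accumulate per-atom isotropic Gaussians on a regular grid.
// xyz: n x 3 atom positions (Angstrom); amp: per-atom amplitude already
// scaled so the voxel sum integrates to the atomic number; inv2s2 =
// 1 / (2 sigma^2); cutoff: splat half-width in voxels.
// [[Rcpp::export]]
NumericVector cpp_splat(const NumericMatrix& xyz, const NumericVector& amp,
                        const IntegerVector& dims, const NumericVector& origin,
                        double voxel, double inv2s2, int cutoff) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector grid(static_cast<R_xlen_t>(nx) * ny * nz);
  std::vector<double> gx(2 * cutoff + 2), gy(2 * cutoff + 2), gz(2 * cutoff + 2);
  for (int a = 0; a < xyz.nrow(); ++a) {
    const double ax = xyz(a, 0), ay = xyz(a, 1), az = xyz(a, 2);
    const double ci = (ax - origin[0]) / voxel;  // 0-based fractional index
    const double cj = (ay - origin[1]) / voxel;
    const double ck = (az - origin[2]) / voxel;
    int i0 = std::max(0, (int)std::floor(ci) - cutoff);
    int i1 = std::min(nx - 1, (int)std::ceil(ci) + cutoff);
    int j0 = std::max(0, (int)std::floor(cj) - cutoff);
    int j1 = std::min(ny - 1, (int)std::ceil(cj) + cutoff);
    int k0 = std::max(0, (int)std::floor(ck) - cutoff);
    int k1 = std::min(nz - 1, (int)std::ceil(ck) + cutoff);
    if (i0 > i1 || j0 > j1 || k0 > k1) continue;
    for (int i = i0; i <= i1; ++i) {
      double d = origin[0] + i * voxel - ax; gx[i - i0] = std::exp(-d * d * inv2s2);
    }
    for (int j = j0; j <= j1; ++j) {
      double d = origin[1] + j * voxel - ay; gy[j - j0] = std::exp(-d * d * inv2s2);
    }
    for (int k = k0; k <= k1; ++k) {
      double d = origin[2] + k * voxel - az; gz[k - k0] = std::exp(-d * d * inv2s2);
    }
    const double A = amp[a];
    for (int k = k0; k <= k1; ++k) {
      const double Az = A * gz[k - k0];
      const R_xlen_t base_k = static_cast<R_xlen_t>(k) * nx * ny;
      for (int j = j0; j <= j1; ++j) {
        const double Azy = Az * gy[j - j0];
        const R_xlen_t base = base_k + static_cast<R_xlen_t>(j) * nx;
        for (int i = i0; i <= i1; ++i) grid[base + i] += Azy * gx[i - i0];
      }
    }
  }
  return grid;
}

// Mark voxels whose centre lies within `radius` of any atom.
// [[Rcpp::export]]
LogicalVector cpp_mask(const NumericMatrix& xyz, const IntegerVector& dims,
                       const NumericVector& origin, double voxel, double radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector mask(static_cast<R_xlen_t>(nx) * ny * nz, false);
  const int cutoff = (int)std::ceil(radius / voxel);
  const double r2 = radius * radius;
  for (int a = 0; a < xyz.nrow(); ++a) {
    const double ax = xyz(a, 0), ay = xyz(a, 1), az = xyz(a, 2);
    int i0 = std::max(0, (int)std::floor((ax - origin[0]) / voxel) - cutoff);
    int i1 = std::min(nx - 1, (int)std::ceil((ax - origin[0]) / voxel) + cutoff);
    int j0 = std::max(0, (int)std::floor((ay - origin[1]) / voxel) - cutoff);
    int j1 = std::min(ny - 1, (int)std::ceil((ay - origin[1]) / voxel) + cutoff);
    int k0 = std::max(0, (int)std::floor((az - origin[2]) / voxel) - cutoff);
    int k1 = std::min(nz - 1, (int)std::ceil((az - origin[2]) / voxel) + cutoff);
    if (i0 > i1 || j0 > j1 || k0 > k1) continue;
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * voxel - az;
      const R_xlen_t base_k = static_cast<R_xlen_t>(k) * nx * ny;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * voxel - ay;
        const double dzy = dz * dz + dy * dy;
        if (dzy > r2) continue;
        const R_xlen_t base = base_k + static_cast<R_xlen_t>(j) * nx;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * voxel - ax;
          if (dzy + dx * dx <= r2) mask[base + i] = true;
        }
      }
    }
  }
  return mask;
}

// Trilinear interpolation of a grid at fractional 0-based coordinates;
// points outside the grid sample as 0.
// [[Rcpp::export]]
NumericVector cpp_trilinear(const NumericVector& grid, const IntegerVector& dims,
                            const NumericMatrix& frac) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = frac.nrow();
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    const double fx = frac(p, 0), fy = frac(p, 1), fz = frac(p, 2);
    const int i = (int)std::floor(fx), j = (int)std::floor(fy), k = (int)std::floor(fz);
    if (i < 0 || i > nx - 2 || j < 0 || j > ny - 2 || k < 0 || k > nz - 2) continue;
    const double wx = fx - i, wy = fy - j, wz = fz - k;
    const R_xlen_t b = static_cast<R_xlen_t>(k) * nx * ny + static_cast<R_xlen_t>(j) * nx + i;
    const R_xlen_t sx = 1, sy = nx, sz = static_cast<R_xlen_t>(nx) * ny;
    out[p] =
      (1 - wx) * (1 - wy) * (1 - wz) * grid[b] +
      wx * (1 - wy) * (1 - wz) * grid[b + sx] +
      (1 - wx) * wy * (1 - wz) * grid[b + sy] +
      wx * wy * (1 - wz) * grid[b + sx + sy] +
      (1 - wx) * (1 - wy) * wz * grid[b + sz] +
      wx * (1 - wy) * wz * grid[b + sx + sz] +
      (1 - wx) * wy * wz * grid[b + sy + sz] +
      wx * wy * wz * grid[b + sx + sy + sz];
  }
  return out;
}
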