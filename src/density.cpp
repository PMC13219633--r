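#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sum-of-Gaussians density on a regular grid. Each atom contributes
// w * exp(-r^2 / (2 sigma^2)) within rcut of its center. The grid is
// column-major with x fastest, matching R array layout.
// [[Rcpp::export]]
NumericVector cpp_simulate_density(const NumericMatrix& xyz,
                                   const NumericVector& weight,
                                   double sigma,
                                   const NumericVector& origin,
                                   const NumericVector& voxel,
                                   const IntegerVector& dims,
                                   double rcut) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double rcut2 = rcut * rcut;
  for (int a = 0; a < xyz.nrow(); ++a) {
    const double ax = xyz(a, 0), ay = xyz(a, 1), az = xyz(a, 2), w = weight[a];
    const int i0 = std::max(0, (int)std::ceil((ax - rcut - origin[0]) / voxel[0]));
    const int i1 = std::min(nx - 1, (int)std::floor((ax + rcut - origin[0]) / voxel[0]));
    const int j0 = std::max(0, (int)std::ceil((ay - rcut - origin[1]) / voxel[1]));
    const int j1 = std::min(ny - 1, (int)std::floor((ay + rcut - origin[1]) / voxel[1]));
    const int k0 = std::max(0, (int)std::ceil((az - rcut - origin[2]) / voxel[2]));
    const int k1 = std::min(nz - 1, (int)std::floor((az + rcut - origin[2]) / voxel[2]));
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * voxel[2] - az;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * voxel[1] - ay;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > rcut2) continue;
        const R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * voxel[0] - ax;
          const double r2 = dx * dx + dyz2;
          if (r2 <= rcut2) out[base + i] += w * std::exp(-r2 * inv2s2);
        }
      }
    }
  }
  return out;
}

// Trilinear interpolation of grid values at arbitrary points.
// Points outside the grid evaluate to 0.
// [[Rcpp::export]]
NumericVector cpp_trilinear(const NumericVector& values,
                            const IntegerVector& dims,
                            const NumericVector& origin,
                            const NumericVector& voxel,
                            const NumericMatrix& points) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int np = points.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    const double fx = (points(p, 0) - origin[0]) / voxel[0];
    const double fy = (points(p, 1) - origin[1]) / voxel[1];
    const double fz = (points(p, 2) - origin[2]) / voxel[2];
    const int ix = (int)std::floor(fx), iy = (int)std::floor(fy), iz = (int)std::floor(fz);
    if (ix < 0 || iy < 0 || iz < 0 || ix >= nx - 1 || iy >= ny - 1 || iz >= nz - 1) {
      out[p] = 0.0;
      continue;
    }
    const double tx = fx - ix, ty = fy - iy, tz = fz - iz;
    double v = 0.0;
    for (int dk = 0; dk <= 1; ++dk) {
      const double wz = dk ? tz : 1.0 - tz;
      for (int dj = 0; dj <= 1; ++dj) {
        const double wy = dj ? ty : 1.0 - ty;
        for (int di = 0; di <= 1; ++di) {
          const double wx = di ? tx : 1.0 - tx;
          v += wx * wy * wz *
               values[(R_xlen_t)(iz + dk) * nx * ny + (R_xlen_t)(iy + dj) * nx + (ix + di)];
        }
      }
    }
    out[p] = v;
  }
  return out;
}
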