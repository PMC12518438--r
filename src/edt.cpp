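#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher), with a
// physical grid step `h` so anisotropic voxel spacing is exact.
static void edt_1d(const std::vector<double>& f, std::vector<double>& d,
                   double h) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF) { v[0] = q; z[0] = -INF; z[1] = INF; continue; }
    double s = 0;
    while (k >= 0) {
      double xq = q * h, xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s > z[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// Exact anisotropic squared Euclidean distance transform of a 3D mask.
// `mask` nonzero = feature (distance 0). Returns squared distances in
// physical units (spacing = per-axis voxel size).
// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(LogicalVector mask, IntegerVector dims,
                       NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(nx * ny * nz);
  for (int i = 0; i < out.size(); ++i) out[i] = mask[i] ? 0.0 : INF;
  std::vector<double> f, d;

  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const long base = (long)z * nx * ny + (long)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      edt_1d(f, d, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      const long base = (long)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (long)y * nx];
      edt_1d(f, d, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (long)y * nx] = d[y];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      const long base = (long)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = out[base + (long)z * nx * ny];
      edt_1d(f, d, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + (long)z * nx * ny] = d[z];
    }
  return out;
}
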