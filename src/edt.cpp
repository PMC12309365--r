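#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact Euclidean distance transform on an anisotropic grid
// (Felzenszwalb & Huttenlocher lower-envelope algorithm, run separably with
// the physical spacing of each axis). Returns, for every voxel, the distance
// in nm to the nearest foreground voxel center (0 inside the foreground).

// Large finite sentinel keeps the envelope arithmetic free of INF-INF.
static const double BIG = 1e30;

// 1D squared-distance transform over samples at positions i*s
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double s, std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    const double sq = (double)q * s;
    double cross;
    while (true) {
      const double sv = (double)v[k] * s;
      cross = ((f[q] + sq * sq) - (f[v[k]] + sv * sv)) / (2.0 * (sq - sv));
      if (cross <= z[k] && k > 0) { --k; } else break;
    }
    if (cross <= z[k]) { // k == 0, new parabola dominates everywhere
      v[0] = q; z[0] = -BIG; z[1] = BIG;
    } else {
      ++k; v[k] = q; z[k] = cross; z[k + 1] = BIG;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double sq = (double)q * s;
    while (z[k + 1] < sq) ++k;
    const double sv = (double)v[k] * s;
    d[q] = (sq - sv) * (sq - sv) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const long sy = nz, sx = (long)nz * ny;
  const long n = (long)nz * ny * nx;
  std::vector<double> g(n);
  for (long t = 0; t < n; ++t) g[t] = mask[t] ? 0.0 : BIG;

  const int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  for (int i = 0; i < nx; ++i) // z axis
    for (int j = 0; j < ny; ++j) {
      const long base = sy * j + sx * i;
      for (int k = 0; k < nz; ++k) f[k] = g[base + k];
      dt1d(f, d, nz, spacing[0], v, z);
      for (int k = 0; k < nz; ++k) g[base + k] = std::min(d[k], BIG);
    }
  for (int i = 0; i < nx; ++i) // y axis
    for (int k = 0; k < nz; ++k) {
      const long base = k + sx * i;
      for (int j = 0; j < ny; ++j) f[j] = g[base + sy * j];
      dt1d(f, d, ny, spacing[1], v, z);
      for (int j = 0; j < ny; ++j) g[base + sy * j] = std::min(d[j], BIG);
    }
  for (int j = 0; j < ny; ++j) // x axis
    for (int k = 0; k < nz; ++k) {
      const long base = k + sy * j;
      for (int i = 0; i < nx; ++i) f[i] = g[base + sx * i];
      dt1d(f, d, nx, spacing[2], v, z);
      for (int i = 0; i < nx; ++i) g[base + sx * i] = std::min(d[i], BIG);
    }

  NumericVector out(n);
  for (long t = 0; t < n; ++t)
    out[t] = (g[t] >= BIG) ? R_PosInf : std::sqrt(g[t]);
  out.attr("dim") = dim;
  return out;
}
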