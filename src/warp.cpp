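#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear resampling of a scalar volume at displaced coordinates:
// out(k,j,i) = arr(k + uz, j + uy, i + ux), displacements in voxel units,
// coordinates clamped at the border. Used to translate object boundaries by
// a smooth random field without eroding thin structures.
// [[Rcpp::export]]
NumericVector cpp_warp3d(NumericVector arr, IntegerVector dim,
                         NumericVector uz, NumericVector uy,
                         NumericVector ux) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const long sy = nz, sx = (long)nz * ny;
  const long n = (long)nz * ny * nx;
  NumericVector out(n);
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      for (int k = 0; k < nz; ++k) {
        const long t = k + sy * j + sx * i;
        double zq = k + uz[t], yq = j + uy[t], xq = i + ux[t];
        if (zq < 0) zq = 0; if (zq > nz - 1) zq = nz - 1;
        if (yq < 0) yq = 0; if (yq > ny - 1) yq = ny - 1;
        if (xq < 0) xq = 0; if (xq > nx - 1) xq = nx - 1;
        const int z0 = (int)zq, y0 = (int)yq, x0 = (int)xq;
        const int z1 = std::min(z0 + 1, nz - 1);
        const int y1 = std::min(y0 + 1, ny - 1);
        const int x1 = std::min(x0 + 1, nx - 1);
        const double fz = zq - z0, fy = yq - y0, fx = xq - x0;
        double acc = 0;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              const double w = (dz ? fz : 1 - fz) * (dy ? fy : 1 - fy) *
                               (dx ? fx : 1 - fx);
              if (w == 0) continue;
              const long tt = (dz ? z1 : z0) + sy * (dy ? y1 : y0) +
                              sx * (dx ? x1 : x0);
              acc += w * arr[tt];
            }
        out[t] = acc;
      }
  out.attr("dim") = dim;
  return out;
}
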