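#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Arrays arrive as R column-major vectors with dim = (nz, ny, nx), i.e. the
// element (k, j, i) sits at k + nz*j + nz*ny*i (0-based). Spacing vectors are
// ordered (c, b, a) nm to match (z, y, x).

// reflect index into [0, n) (half-sample symmetric)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : period - 1 - i;
}

static void conv1d_axis(std::vector<double>& src, std::vector<double>& dst,
                        int nz, int ny, int nx, int axis,
                        const std::vector<double>& kernel) {
  const int r = (int(kernel.size()) - 1) / 2;
  const long sz = 1, sy = nz, sx = (long)nz * ny;
  const long strides[3] = { sz, sy, sx };
  const int lens[3] = { nz, ny, nx };
  const long stride = strides[axis];
  const int n = lens[axis];
  // iterate over all lines along `axis`
  const int a1 = (axis == 0) ? 1 : 0;
  const int a2 = (axis == 2) ? 1 : 2;
  for (int u = 0; u < lens[a1]; ++u) {
    for (int v = 0; v < lens[a2]; ++v) {
      const long base = u * strides[a1] + v * strides[a2];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          const int ii = reflect_idx(i + t, n);
          acc += kernel[t + r] * src[base + (long)ii * stride];
        }
        dst[base + (long)i * stride] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian3d(NumericVector arr, IntegerVector dim,
                             NumericVector sigma_vox) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const long n = (long)nz * ny * nx;
  std::vector<double> a(arr.begin(), arr.end()), b(n);
  for (int axis = 0; axis < 3; ++axis) {
    const double s = sigma_vox[axis];
    if (s <= 0) continue;
    const int r = std::max(1, (int)std::ceil(3.5 * s));
    std::vector<double> k(2 * r + 1);
    double sum = 0.0;
    for (int t = -r; t <= r; ++t) { k[t + r] = std::exp(-0.5 * t * t / (s * s)); sum += k[t + r]; }
    for (double& v : k) v /= sum;
    conv1d_axis(a, b, nz, ny, nx, axis, k);
    a.swap(b);
  }
  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// Median filter with per-axis half-widths; windows truncate at the borders.
// The lower median is taken so integer inputs stay integer and the filter is
// monotone on pointwise-ordered inputs.
// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector arr, IntegerVector dim,
                           IntegerVector halfwidth) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int hz = halfwidth[0], hy = halfwidth[1], hx = halfwidth[2];
  const long sy = nz, sx = (long)nz * ny;
  NumericVector out((long)nz * ny * nx);
  std::vector<double> win;
  win.reserve((2 * hz + 1) * (2 * hy + 1) * (2 * hx + 1));
  for (int i = 0; i < nx; ++i) {
    const int i0 = std::max(0, i - hx), i1 = std::min(nx - 1, i + hx);
    for (int j = 0; j < ny; ++j) {
      const int j0 = std::max(0, j - hy), j1 = std::min(ny - 1, j + hy);
      for (int k = 0; k < nz; ++k) {
        const int k0 = std::max(0, k - hz), k1 = std::min(nz - 1, k + hz);
        win.clear();
        for (int ii = i0; ii <= i1; ++ii)
          for (int jj = j0; jj <= j1; ++jj)
            for (int kk = k0; kk <= k1; ++kk)
              win.push_back(arr[kk + sy * jj + sx * ii]);
        const size_t m = (win.size() - 1) / 2;  // lower median
        std::nth_element(win.begin(), win.begin() + m, win.end());
        out[k + sy * j + sx * i] = win[m];
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
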