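#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; i++) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;
  return k;
}

static void conv_axis(std::vector<double> &a, int nz, int ny, int nx,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  std::vector<double> k = gauss_kernel(sigma);
  int r = ((int)k.size() - 1) / 2;
  int n = axis == 0 ? nz : (axis == 1 ? ny : nx);
  int64_t stride = axis == 0 ? 1 : (axis == 1 ? nz : (int64_t)nz * ny);
  std::vector<double> line(n);
  // iterate over all lines along the chosen axis
  int n1 = axis == 0 ? ny : nz;
  int n2 = axis == 2 ? ny : nx;
  for (int b = 0; b < n2; b++)
    for (int a1 = 0; a1 < n1; a1++) {
      int64_t base;
      if (axis == 0) base = (int64_t)nz * (a1 + (int64_t)ny * b);
      else if (axis == 1) base = a1 + (int64_t)nz * ny * b;
      else base = a1 + (int64_t)nz * b; // a1 = z, b = y
      for (int i = 0; i < n; i++) line[i] = a[base + stride * i];
      for (int i = 0; i < n; i++) {
        double s = 0;
        for (int j = -r; j <= r; j++) {
          int ii = i + j;
          if (ii < 0) ii = -ii;                 // reflect
          if (ii >= n) ii = 2 * n - 2 - ii;
          if (ii < 0) ii = 0;
          s += k[j + r] * line[ii];
        }
        a[base + stride * i] = s;
      }
    }
}

// Separable Gaussian blur of a 3D grid; sigma given per axis in voxel units,
// ordered (z, y, x) to match dim = (nz, ny, nx). Reflecting boundaries.
// [[Rcpp::export]]
NumericVector gauss3d_cpp(NumericVector arr, IntegerVector dim,
                          NumericVector sigma_vox) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> a(arr.begin(), arr.end());
  conv_axis(a, nz, ny, nx, 0, sigma_vox[0]);
  conv_axis(a, nz, ny, nx, 1, sigma_vox[1]);
  conv_axis(a, nz, ny, nx, 2, sigma_vox[2]);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}
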