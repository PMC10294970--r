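#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1-D squared distance transform (lower envelope of parabolas) with
// arbitrary sample spacing s; positions are x_i = i*s.
static void dt1d(const double *f, double *d, int n, double s) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1; // parabolas with infinite height never enter the envelope
  for (int q = 0; q < n; q++) {
    if (f[q] == INF) continue;
    double xq = q * s;
    while (k >= 0) {
      double xv = v[k] * s;
      double sint = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) /
                    (2.0 * (xq - xv));
      if (sint <= z[k]) k--; else break;
    }
    k++;
    v[k] = q;
    z[k] = (k == 0) ? -INF
                    : ((f[q] + xq * xq) -
                       (f[v[k - 1]] + (v[k - 1] * s) * (v[k - 1] * s))) /
                          (2.0 * (xq - v[k - 1] * s));
    z[k + 1] = INF;
  }
  if (k < 0) { // whole line infinite
    for (int q = 0; q < n; q++) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * s;
    while (z[j + 1] < xq) j++;
    double xv = v[j] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[j]];
  }
}

// Euclidean distance (physical units) from every voxel to the nearest TRUE
// voxel. dim = (nz, ny, nx); spacing = (dz, dy, dx); array column-major with
// z fastest. Voxels where no TRUE voxel exists anywhere get Inf.
// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> D(n);
  for (R_xlen_t i = 0; i < n; i++) D[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f(std::max(nz, std::max(ny, nx)));
  std::vector<double> d(f.size());

  // pass along z
  for (int x = 0; x < nx; x++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      bool any = false;
      for (int z = 0; z < nz; z++) { f[z] = D[base + z]; if (f[z] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), d.data(), nz, dz);
      for (int z = 0; z < nz; z++) D[base + z] = d[z];
    }
  // pass along y
  for (int x = 0; x < nx; x++)
    for (int z = 0; z < nz; z++) {
      R_xlen_t base = z + (R_xlen_t)nz * ny * x;
      bool any = false;
      for (int y = 0; y < ny; y++) { f[y] = D[base + (R_xlen_t)nz * y]; if (f[y] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), d.data(), ny, dy);
      for (int y = 0; y < ny; y++) D[base + (R_xlen_t)nz * y] = d[y];
    }
  // pass along x
  for (int y = 0; y < ny; y++)
    for (int z = 0; z < nz; z++) {
      R_xlen_t base = z + (R_xlen_t)nz * y;
      bool any = false;
      for (int x = 0; x < nx; x++) { f[x] = D[base + (R_xlen_t)nz * ny * x]; if (f[x] < INF) any = true; }
      if (!any) continue;
      dt1d(f.data(), d.data(), nx, dx);
      for (int x = 0; x < nx; x++) D[base + (R_xlen_t)nz * ny * x] = d[x];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = std::sqrt(D[i]);
  return out;
}
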