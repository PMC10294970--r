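#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Closest distance from point p to triangle (a, b, c); Ericson-style
// region test via clamped barycentric coordinates.
static double point_tri_dist(const double p[3], const double a[3],
                             const double b[3], const double c[3]) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; i++) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double q[3];
  if (d1 <= 0 && d2 <= 0) {
    q[0] = a[0]; q[1] = a[1]; q[2] = a[2];
  } else {
    double bp[3], cp[3];
    for (int i = 0; i < 3; i++) {
      bp[i] = p[i] - b[i];
      cp[i] = p[i] - c[i];
    }
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
    double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
    if (d3 >= 0 && d4 <= d3) {
      q[0] = b[0]; q[1] = b[1]; q[2] = b[2];
    } else if (d6 >= 0 && d5 <= d6) {
      q[0] = c[0]; q[1] = c[1]; q[2] = c[2];
    } else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        double t = d1 / (d1 - d3);
        for (int i = 0; i < 3; i++) q[i] = a[i] + t * ab[i];
      } else {
        double vb = d5 * d2 - d1 * d6;
        if (vb <= 0 && d2 >= 0 && d6 <= 0) {
          double t = d2 / (d2 - d6);
          for (int i = 0; i < 3; i++) q[i] = a[i] + t * ac[i];
        } else {
          double va = d3 * d6 - d5 * d4;
          if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
            double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
            for (int i = 0; i < 3; i++) q[i] = b[i] + t * (c[i] - b[i]);
          } else {
            double denom = 1.0 / (va + vb + vc);
            double v = vb * denom, w = vc * denom;
            for (int i = 0; i < 3; i++)
              q[i] = a[i] + ab[i] * v + ac[i] * w;
          }
        }
      }
    }
  }
  double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// Exact unsigned distance from voxel centres to the triangle surface,
// computed inside a narrow band (distance <= band) and +Inf outside it.
// Each triangle visits the voxels of its band-expanded bounding box, so the
// minimum over triangles is exact for all voxels truly within the band.
// [[Rcpp::export]]
NumericVector band_distance_cpp(NumericMatrix verts, IntegerMatrix faces,
                                IntegerVector dim, NumericVector spacing,
                                NumericVector origin, double band) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  const double z0 = origin[0], y0 = origin[1], x0 = origin[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n, std::numeric_limits<double>::infinity());
  const int nf = faces.nrow();
  double a[3], b[3], c[3], p[3];
  for (int f = 0; f < nf; f++) {
    for (int i = 0; i < 3; i++) {
      a[i] = verts(faces(f, 0) - 1, i);
      b[i] = verts(faces(f, 1) - 1, i);
      c[i] = verts(faces(f, 2) - 1, i);
    }
    double xmin = std::min(a[0], std::min(b[0], c[0])) - band;
    double xmax = std::max(a[0], std::max(b[0], c[0])) + band;
    double ymin = std::min(a[1], std::min(b[1], c[1])) - band;
    double ymax = std::max(a[1], std::max(b[1], c[1])) + band;
    double zmin = std::min(a[2], std::min(b[2], c[2])) - band;
    double zmax = std::max(a[2], std::max(b[2], c[2])) + band;
    int k0 = std::max(0, (int)std::ceil((xmin - x0) / dx));
    int k1 = std::min(nx - 1, (int)std::floor((xmax - x0) / dx));
    int j0 = std::max(0, (int)std::ceil((ymin - y0) / dy));
    int j1 = std::min(ny - 1, (int)std::floor((ymax - y0) / dy));
    int i0 = std::max(0, (int)std::ceil((zmin - z0) / dz));
    int i1 = std::min(nz - 1, (int)std::floor((zmax - z0) / dz));
    for (int k = k0; k <= k1; k++) {
      p[0] = x0 + k * dx;
      for (int j = j0; j <= j1; j++) {
        p[1] = y0 + j * dy;
        R_xlen_t base = (R_xlen_t)nz * (j + (R_xlen_t)ny * k);
        for (int i = i0; i <= i1; i++) {
          p[2] = z0 + i * dz;
          double d = point_tri_dist(p, a, b, c);
          if (d < out[base + i]) out[base + i] = d;
        }
      }
    }
  }
  return out;
}
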