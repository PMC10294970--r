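#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Wall-thickness estimation by inward ray casting: from the centroid of each
// sampled face a ray is cast along the inward normal (opposite the face's
// outward winding normal); the distance to the first triangle hit is the
// local wall thickness. Moller-Trumbore intersection. Returns NA where no
// hit occurs within max_dist.
// [[Rcpp::export]]
NumericVector ray_thickness_cpp(NumericMatrix verts, IntegerMatrix faces,
                                IntegerVector sample, double max_dist) {
  const int nf = faces.nrow();
  const int ns = sample.size();
  NumericVector out(ns, NA_REAL);
  const double EPS = 1e-12;
  for (int s = 0; s < ns; s++) {
    int f = sample[s] - 1;
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    double ox = (verts(a, 0) + verts(b, 0) + verts(c, 0)) / 3.0;
    double oy = (verts(a, 1) + verts(b, 1) + verts(c, 1)) / 3.0;
    double oz = (verts(a, 2) + verts(b, 2) + verts(c, 2)) / 3.0;
    double ux = verts(b, 0) - verts(a, 0), uy = verts(b, 1) - verts(a, 1), uz = verts(b, 2) - verts(a, 2);
    double wx = verts(c, 0) - verts(a, 0), wy = verts(c, 1) - verts(a, 1), wz = verts(c, 2) - verts(a, 2);
    double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz, nz = ux * wy - uy * wx;
    double nl = std::sqrt(nx * nx + ny * ny + nz * nz);
    if (nl < EPS) continue;
    // inward direction = -outward normal
    double dxr = -nx / nl, dyr = -ny / nl, dzr = -nz / nl;
    double best = std::numeric_limits<double>::infinity();
    for (int g = 0; g < nf; g++) {
      if (g == f) continue;
      int p = faces(g, 0) - 1, q = faces(g, 1) - 1, r = faces(g, 2) - 1;
      double e1x = verts(q, 0) - verts(p, 0), e1y = verts(q, 1) - verts(p, 1), e1z = verts(q, 2) - verts(p, 2);
      double e2x = verts(r, 0) - verts(p, 0), e2y = verts(r, 1) - verts(p, 1), e2z = verts(r, 2) - verts(p, 2);
      double hx = dyr * e2z - dzr * e2y, hy = dzr * e2x - dxr * e2z, hz = dxr * e2y - dyr * e2x;
      double det = e1x * hx + e1y * hy + e1z * hz;
      if (std::fabs(det) < EPS) continue;
      double inv = 1.0 / det;
      double sx = ox - verts(p, 0), sy = oy - verts(p, 1), sz = oz - verts(p, 2);
      double u = (sx * hx + sy * hy + sz * hz) * inv;
      if (u < -1e-9 || u > 1 + 1e-9) continue;
      double qx = sy * e1z - sz * e1y, qy = sz * e1x - sx * e1z, qz = sx * e1y - sy * e1x;
      double v = (dxr * qx + dyr * qy + dzr * qz) * inv;
      if (v < -1e-9 || u + v > 1 + 1e-9) continue;
      double t = (e2x * qx + e2y * qy + e2z * qz) * inv;
      if (t <= 1e-7 || t >= best) continue;
      // wall thickness is the distance to the face the ray exits through;
      // grazing hits on neighbouring surface bumps (normal nearly
      // perpendicular or opposing the ray) are not exits
      double gnx = e1y * e2z - e1z * e2y;
      double gny = e1z * e2x - e1x * e2z;
      double gnz = e1x * e2y - e1y * e2x;
      double gl = std::sqrt(gnx * gnx + gny * gny + gnz * gnz);
      if (gl < EPS) continue;
      double cosex = (dxr * gnx + dyr * gny + dzr * gnz) / gl;
      if (cosex < 0.2) continue;
      best = t;
    }
    if (best <= max_dist) out[s] = best;
  }
  return out;
}
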