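#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Occupancy voxelization of a closed triangle mesh by parity ray casting
// along +z. For every (y, x) voxel column the z positions where the column's
// ray crosses the surface are collected; voxel centres between successive
// crossing pairs are inside. Sample positions carry a tiny deterministic
// offset so rays avoid grazing triangle edges of meshes built on round
// coordinates. Columns with an odd crossing count (numerically degenerate)
// drop their last crossing.
// [[Rcpp::export]]
LogicalVector voxelize_cpp(NumericMatrix verts, IntegerMatrix faces,
                           IntegerVector dim, NumericVector spacing,
                           NumericVector origin) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  const double z0 = origin[0], y0 = origin[1], x0 = origin[2];
  const double jx = 0.128763e-3 * dx, jy = 0.231971e-3 * dy; // irrational-ish
  const R_xlen_t ncol_ = (R_xlen_t)ny * nx;
  std::vector<std::vector<double> > hits(ncol_);

  const int nf = faces.nrow();
  for (int f = 0; f < nf; f++) {
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    double ax = verts(a, 0), ay = verts(a, 1), az = verts(a, 2);
    double bx = verts(b, 0), by = verts(b, 1), bz = verts(b, 2);
    double cx = verts(c, 0), cy = verts(c, 1), cz = verts(c, 2);
    double xmin = std::min(ax, std::min(bx, cx)), xmax = std::max(ax, std::max(bx, cx));
    double ymin = std::min(ay, std::min(by, cy)), ymax = std::max(ay, std::max(by, cy));
    int k0 = (int)std::ceil((xmin - x0 - jx) / dx - 0.5);
    int k1 = (int)std::floor((xmax - x0 - jx) / dx + 0.5);
    int j0 = (int)std::ceil((ymin - y0 - jy) / dy - 0.5);
    int j1 = (int)std::floor((ymax - y0 - jy) / dy + 0.5);
    if (k0 < 0) k0 = 0;
    if (k1 >= nx) k1 = nx - 1;
    if (j0 < 0) j0 = 0;
    if (j1 >= ny) j1 = ny - 1;
    double d00x = bx - ax, d00y = by - ay;
    double d01x = cx - ax, d01y = cy - ay;
    double det = d00x * d01y - d01x * d00y;
    if (std::fabs(det) < 1e-300) continue; // degenerate in projection
    for (int k = k0; k <= k1; k++) {
      double px = x0 + k * dx + jx - ax;
      for (int j = j0; j <= j1; j++) {
        double py = y0 + j * dy + jy - ay;
        double u = (px * d01y - d01x * py) / det;
        double v = (d00x * py - px * d00y) / det;
        if (u < 0 || v < 0 || u + v > 1) continue;
        double zhit = az + u * (bz - az) + v * (cz - az);
        hits[(R_xlen_t)j + (R_xlen_t)ny * k].push_back(zhit);
      }
    }
  }

  LogicalVector occ((R_xlen_t)nz * ny * nx, (int)false);
  for (int k = 0; k < nx; k++)
    for (int j = 0; j < ny; j++) {
      std::vector<double> &h = hits[(R_xlen_t)j + (R_xlen_t)ny * k];
      if (h.size() < 2) continue;
      std::sort(h.begin(), h.end());
      size_t npair = h.size() / 2;
      for (size_t p = 0; p < npair; p++) {
        double za = h[2 * p], zb = h[2 * p + 1];
        int i0 = (int)std::ceil((za - z0) / dz);
        int i1 = (int)std::floor((zb - z0) / dz);
        if (i0 < 0) i0 = 0;
        if (i1 >= nz) i1 = nz - 1;
        for (int i = i0; i <= i1; i++)
          occ[i + (R_xlen_t)nz * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  return occ;
}

// Mark every voxel touched by the triangle surface (dense barycentric
// sampling at roughly half-voxel pitch). Used to build unsigned distance
// fields for open meshes.
// [[Rcpp::export]]
LogicalVector mark_surface_cpp(NumericMatrix verts, IntegerMatrix faces,
                               IntegerVector dim, NumericVector spacing,
                               NumericVector origin) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  const double z0 = origin[0], y0 = origin[1], x0 = origin[2];
  const double pitch = 0.5 * std::min(dz, std::min(dy, dx));
  LogicalVector occ((R_xlen_t)nz * ny * nx, (int)false);
  const int nf = faces.nrow();
  for (int f = 0; f < nf; f++) {
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    double ax = verts(a, 0), ay = verts(a, 1), az = verts(a, 2);
    double ux = verts(b, 0) - ax, uy = verts(b, 1) - ay, uz = verts(b, 2) - az;
    double wx = verts(c, 0) - ax, wy = verts(c, 1) - ay, wz = verts(c, 2) - az;
    double lu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double lw = std::sqrt(wx * wx + wy * wy + wz * wz);
    int nu = std::max(1, (int)std::ceil(lu / pitch));
    int nw = std::max(1, (int)std::ceil(lw / pitch));
    for (int iu = 0; iu <= nu; iu++) {
      double s = (double)iu / nu;
      for (int iw = 0; iw <= nw; iw++) {
        double t = (double)iw / nw;
        if (s + t > 1.0) break;
        double px = ax + s * ux + t * wx;
        double py = ay + s * uy + t * wy;
        double pz = az + s * uz + t * wz;
        int k = (int)std::lround((px - x0) / dx);
        int j = (int)std::lround((py - y0) / dy);
        int i = (int)std::lround((pz - z0) / dz);
        if (i < 0 || i >= nz || j < 0 || j >= ny || k < 0 || k >= nx) continue;
        occ[i + (R_xlen_t)nz * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  }
  return occ;
}
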