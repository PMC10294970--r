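#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// neighbour offsets for 6- or 26-connectivity in (z, y, x) index space
static int build_neigh(int conn, int off[][3]) {
  int m = 0;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (conn == 6 && manh != 1) continue;
        off[m][0] = dz; off[m][1] = dy; off[m][2] = dx; m++;
      }
  return m;
}

// Connected-component labels of a binary grid, 0 = background.
// Labels are assigned in scan order; relabelling by size happens in R.
// With nz == 1 the 26/6 neighbourhoods reduce to 8/4 in-plane.
// [[Rcpp::export]]
IntegerVector label_cpp(LogicalVector mask, IntegerVector dim, int conn) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  int off[26][3];
  const int m = build_neigh(conn, off);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; i++) {
    if (!mask[i] || lab[i]) continue;
    next++;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int z = (int)(cur % nz);
      int y = (int)((cur / nz) % ny);
      int x = (int)(cur / ((R_xlen_t)nz * ny));
      for (int k = 0; k < m; k++) {
        int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  return lab;
}

// Flood fill from a seed voxel restricted to intensities in [low, high].
// [[Rcpp::export]]
LogicalVector region_grow_cpp(NumericVector img, IntegerVector dim,
                              IntegerVector seed_zyx, double low, double high,
                              int conn) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  LogicalVector out(n, (int)false);
  int off[26][3];
  const int m = build_neigh(conn, off);
  R_xlen_t s = seed_zyx[0] + (R_xlen_t)nz * (seed_zyx[1] + (R_xlen_t)ny * seed_zyx[2]);
  if (img[s] < low || img[s] > high)
    stop("seed intensity outside [low, high]");
  std::vector<R_xlen_t> stack;
  out[s] = true;
  stack.push_back(s);
  while (!stack.empty()) {
    R_xlen_t cur = stack.back(); stack.pop_back();
    int z = (int)(cur % nz);
    int y = (int)((cur / nz) % ny);
    int x = (int)(cur / ((R_xlen_t)nz * ny));
    for (int k = 0; k < m; k++) {
      int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      if (!out[j] && img[j] >= low && img[j] <= high) {
        out[j] = true;
        stack.push_back(j);
      }
    }
  }
  return out;
}
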