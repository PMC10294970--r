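#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Iso-surface extraction by marching tetrahedra on a scalar field sampled at
// voxel centres. Each grid cube is decomposed into the six tetrahedra sharing
// the main diagonal (the per-face diagonals of this decomposition match
// between neighbouring cubes, so the triangulation is crack-free). Cut
// vertices are interpolated linearly along grid/diagonal edges and shared via
// an edge-keyed hash, so closed regions yield watertight meshes.
//
// dim = (nz, ny, nx); spacing = (dz, dy, dx); origin = (z0, y0, x0).
// "inside" is field > level; triangle winding gives outward normals
// (pointing from inside to outside).

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
  const double *field;
  int nz, ny, nx;
  double dz, dy, dx, z0, y0, x0, level;
};

static inline void idx2zyx(const MTState &S, int64_t id, int &z, int &y, int &x) {
  z = (int)(id % S.nz);
  y = (int)((id / S.nz) % S.ny);
  x = (int)(id / ((int64_t)S.nz * S.ny));
}

static int cut_vertex(MTState &S, int64_t g1, int64_t g2) {
  if (g1 > g2) std::swap(g1, g2);
  uint64_t key = ((uint64_t)g1 << 32) | (uint64_t)g2;
  auto it = S.edge_vertex.find(key);
  if (it != S.edge_vertex.end()) return it->second;
  double v1 = S.field[g1], v2 = S.field[g2];
  double t = (S.level - v1) / (v2 - v1);
  if (t < 1e-9) t = 1e-9;
  if (t > 1.0 - 1e-9) t = 1.0 - 1e-9;
  int z1, y1, x1, z2, y2, x2;
  idx2zyx(S, g1, z1, y1, x1);
  idx2zyx(S, g2, z2, y2, x2);
  double px = S.x0 + (x1 + t * (x2 - x1)) * S.dx;
  double py = S.y0 + (y1 + t * (y2 - y1)) * S.dy;
  double pz = S.z0 + (z1 + t * (z2 - z1)) * S.dz;
  int id = (int)S.vx.size();
  S.vx.push_back(px); S.vy.push_back(py); S.vz.push_back(pz);
  S.edge_vertex.emplace(key, id);
  return id;
}

// append triangle (a,b,c), flipping so the normal points away from refpoint
static void emit_tri(MTState &S, int a, int b, int c,
                     double rx, double ry, double rz) {
  double ax = S.vx[a], ay = S.vy[a], az = S.vz[a];
  double ux = S.vx[b] - ax, uy = S.vy[b] - ay, uz = S.vz[b] - az;
  double wx = S.vx[c] - ax, wy = S.vy[c] - ay, wz = S.vz[c] - az;
  double nxv = uy * wz - uz * wy;
  double nyv = uz * wx - ux * wz;
  double nzv = ux * wy - uy * wx;
  double cx = (ax + S.vx[b] + S.vx[c]) / 3.0 - rx;
  double cy = (ay + S.vy[b] + S.vy[c]) / 3.0 - ry;
  double cz = (az + S.vz[b] + S.vz[c]) / 3.0 - rz;
  if (nxv * cx + nyv * cy + nzv * cz < 0) std::swap(b, c);
  S.f0.push_back(a); S.f1.push_back(b); S.f2.push_back(c);
}

static void do_tet(MTState &S, const int64_t g[4]) {
  bool in[4];
  int nin = 0;
  for (int i = 0; i < 4; i++) {
    in[i] = S.field[g[i]] > S.level;
    if (in[i]) nin++;
  }
  if (nin == 0 || nin == 4) return;
  // reference point: mean of inside corners (orientation anchor)
  double rx = 0, ry = 0, rz = 0;
  for (int i = 0; i < 4; i++) {
    if (!in[i]) continue;
    int z, y, x;
    idx2zyx(S, g[i], z, y, x);
    rx += S.x0 + x * S.dx; ry += S.y0 + y * S.dy; rz += S.z0 + z * S.dz;
  }
  rx /= nin; ry /= nin; rz /= nin;

  if (nin == 1 || nin == 3) {
    int lone = -1;
    for (int i = 0; i < 4; i++)
      if (in[i] == (nin == 1)) lone = i;
    int e[3], m = 0;
    for (int i = 0; i < 4; i++)
      if (i != lone) e[m++] = cut_vertex(S, g[lone], g[i]);
    emit_tri(S, e[0], e[1], e[2], rx, ry, rz);
  } else { // 2 in, 2 out -> quad
    int a = -1, b = -1, c = -1, d = -1;
    for (int i = 0; i < 4; i++) {
      if (in[i]) { if (a < 0) a = i; else b = i; }
      else       { if (c < 0) c = i; else d = i; }
    }
    int q0 = cut_vertex(S, g[a], g[c]);
    int q1 = cut_vertex(S, g[a], g[d]);
    int q2 = cut_vertex(S, g[b], g[d]);
    int q3 = cut_vertex(S, g[b], g[c]);
    emit_tri(S, q0, q1, q2, rx, ry, rz);
    emit_tri(S, q0, q2, q3, rx, ry, rz);
  }
}

// [[Rcpp::export]]
List march_tets_cpp(NumericVector field, IntegerVector dim,
                    NumericVector spacing, NumericVector origin,
                    double level) {
  MTState S;
  S.field = REAL(field);
  S.nz = dim[0]; S.ny = dim[1]; S.nx = dim[2];
  S.dz = spacing[0]; S.dy = spacing[1]; S.dx = spacing[2];
  S.z0 = origin[0]; S.y0 = origin[1]; S.x0 = origin[2];
  S.level = level;

  // axis unit steps in linear-index space
  const int64_t sz = 1, sy = S.nz, sx = (int64_t)S.nz * S.ny;
  const int64_t step[3] = {sz, sy, sx};
  static const int perm[6][3] = {
    {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};

  for (int x = 0; x < S.nx - 1; x++)
    for (int y = 0; y < S.ny - 1; y++)
      for (int z = 0; z < S.nz - 1; z++) {
        int64_t c0 = z + (int64_t)S.nz * (y + (int64_t)S.ny * x);
        // quick reject: all 8 corners same side
        bool anyin = false, anyout = false;
        for (int b = 0; b < 8; b++) {
          int64_t c = c0 + (b & 1 ? sz : 0) + (b & 2 ? sy : 0) + (b & 4 ? sx : 0);
          if (S.field[c] > S.level) anyin = true; else anyout = true;
        }
        if (!anyin || !anyout) continue;
        int64_t c7 = c0 + sz + sy + sx;
        for (int p = 0; p < 6; p++) {
          int64_t g[4];
          g[0] = c0;
          g[1] = c0 + step[perm[p][0]];
          g[2] = g[1] + step[perm[p][1]];
          g[3] = c7;
          do_tet(S, g);
        }
      }

  int nv = (int)S.vx.size(), nf = (int)S.f0.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; i++) {
    V(i, 0) = S.vx[i]; V(i, 1) = S.vy[i]; V(i, 2) = S.vz[i];
  }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; i++) {
    F(i, 0) = S.f0[i] + 1; F(i, 1) = S.f1[i] + 1; F(i, 2) = S.f2[i] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
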