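#include <Rcpp.h>
#include <vector>
#include <numeric>
using namespace Rcpp;

static int find_root(std::vector<int> &p, int i) {
  while (p[i] != i) { p[i] = p[p[i]]; i = p[i]; }
  return i;
}

// Connected components of a triangle mesh via vertex-sharing union-find.
// Returns a 1-based component id per face.
// [[Rcpp::export]]
IntegerVector mesh_components_cpp(int n_vertices, IntegerMatrix faces) {
  std::vector<int> parent(n_vertices);
  std::iota(parent.begin(), parent.end(), 0);
  const int nf = faces.nrow();
  for (int f = 0; f < nf; f++) {
    int a = find_root(parent, faces(f, 0) - 1);
    int b = find_root(parent, faces(f, 1) - 1);
    int c = find_root(parent, faces(f, 2) - 1);
    parent[b] = a;
    parent[find_root(parent, c)] = find_root(parent, a);
  }
  std::vector<int> remap(n_vertices, 0);
  int next = 0;
  IntegerVector out(nf);
  for (int f = 0; f < nf; f++) {
    int r = find_root(parent, faces(f, 0) - 1);
    if (!remap[r]) remap[r] = ++next;
    out[f] = remap[r];
  }
  return out;
}
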