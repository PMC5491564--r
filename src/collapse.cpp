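#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Random edge-collapse decimation down to a target vertex count, used to
// give replicate meshes non-corresponding vertex sets. Collapsed pairs are
// merged to the edge midpoint via a union-find over vertices; degenerate
// faces are dropped afterwards. Randomness comes from R's RNG stream.

static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// [[Rcpp::export(name = ".edge_collapse_cpp")]]
List edge_collapse_cpp(NumericMatrix V, IntegerMatrix F, int n_target) {
  const int nv = V.nrow(), nf = F.nrow();
  std::vector<int> parent(nv);
  std::vector<double> px(nv), py(nv), pz(nv);
  for (int i = 0; i < nv; i++) {
    parent[i] = i;
    px[i] = V(i, 0); py[i] = V(i, 1); pz[i] = V(i, 2);
  }
  int alive = nv;
  GetRNGstate();
  long guard = 0, guard_max = 200L * (long)nv + 1000L;
  while (alive > n_target && guard++ < guard_max) {
    int f = (int)std::floor(unif_rand() * nf);
    if (f >= nf) f = nf - 1;
    int e = (int)std::floor(unif_rand() * 3.0);
    int a = F(f, e) - 1, b = F(f, (e + 1) % 3) - 1;
    int ra = uf_find(parent, a), rb = uf_find(parent, b);
    if (ra == rb) continue;
    if (rb < ra) std::swap(ra, rb);
    px[ra] = 0.5 * (px[ra] + px[rb]);
    py[ra] = 0.5 * (py[ra] + py[rb]);
    pz[ra] = 0.5 * (pz[ra] + pz[rb]);
    parent[rb] = ra;
    alive--;
  }
  PutRNGstate();
  // remap faces, drop degenerates, compact vertex ids
  std::vector<int> newid(nv, -1);
  int nv2 = 0;
  std::vector<int> tri;
  tri.reserve(3 * (size_t)nf);
  for (int f = 0; f < nf; f++) {
    int r[3];
    for (int c = 0; c < 3; c++) r[c] = uf_find(parent, F(f, c) - 1);
    if (r[0] == r[1] || r[1] == r[2] || r[0] == r[2]) continue;
    for (int c = 0; c < 3; c++) {
      if (newid[r[c]] < 0) newid[r[c]] = nv2++;
      tri.push_back(newid[r[c]]);
    }
  }
  NumericMatrix V2(nv2, 3);
  for (int i = 0; i < nv; i++)
    if (newid[i] >= 0) {
      V2(newid[i], 0) = px[i];
      V2(newid[i], 1) = py[i];
      V2(newid[i], 2) = pz[i];
    }
  int nf2 = (int)(tri.size() / 3);
  IntegerMatrix F2(nf2, 3);
  for (int f = 0; f < nf2; f++)
    for (int c = 0; c < 3; c++) F2(f, c) = tri[3 * (size_t)f + c] + 1;
  return List::create(_["vertices"] = V2, _["faces"] = F2);
}
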