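#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Iso-surface extraction by marching tetrahedra: every cube is split into
// the same six tetrahedra around the 0-6 body diagonal (Kuhn subdivision),
// so shared cube faces carry matching diagonals and the triangulation is
// watertight and free of the marching-cubes face ambiguities by
// construction. Surface vertices are interpolated on grid edges and welded
// through an edge-keyed hash, triangles oriented with normals pointing
// from negative values (inside) to positive values (outside).

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> verts;   // x0 y0 z0 x1 y1 z1 ...
  std::vector<int> tris;       // 0-based vertex ids
};

static int edge_point(MTState& st, R_xlen_t ga, R_xlen_t gb, double sa,
                      double sb, const double* pa, const double* pb) {
  uint64_t a = (uint64_t)ga, b = (uint64_t)gb;
  if (a > b) { std::swap(a, b); std::swap(sa, sb); std::swap(pa, pb); }
  uint64_t key = (a << 32) | b;
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  double t = sa / (sa - sb);
  int id = (int)(st.verts.size() / 3);
  for (int c = 0; c < 3; c++)
    st.verts.push_back(pa[c] + t * (pb[c] - pa[c]));
  st.edge_vertex.emplace(key, id);
  return id;
}

static void emit_tri(MTState& st, int a, int b, int c, const double* inside) {
  // orient so the normal points away from the tetrahedron's inside corners
  const double* A = &st.verts[3 * (size_t)a];
  const double* B = &st.verts[3 * (size_t)b];
  const double* C = &st.verts[3 * (size_t)c];
  double u[3], v[3], n[3], d[3];
  for (int q = 0; q < 3; q++) {
    u[q] = B[q] - A[q];
    v[q] = C[q] - A[q];
    d[q] = (A[q] + B[q] + C[q]) / 3.0 - inside[q];
  }
  n[0] = u[1] * v[2] - u[2] * v[1];
  n[1] = u[2] * v[0] - u[0] * v[2];
  n[2] = u[0] * v[1] - u[1] * v[0];
  double dot = n[0] * d[0] + n[1] * d[1] + n[2] * d[2];
  if (dot < 0) std::swap(b, c);
  st.tris.push_back(a);
  st.tris.push_back(b);
  st.tris.push_back(c);
}

static void do_tet(MTState& st, const R_xlen_t* g, const double* s,
                   const double (*p)[3], const int* idx) {
  int neg[4], pos[4], nn = 0, np = 0;
  for (int q = 0; q < 4; q++) {
    if (s[idx[q]] < 0) neg[nn++] = idx[q]; else pos[np++] = idx[q];
  }
  if (nn == 0 || nn == 4) return;
  double inside[3] = {0, 0, 0};
  for (int q = 0; q < nn; q++)
    for (int c = 0; c < 3; c++) inside[c] += p[neg[q]][c] / nn;
  if (nn == 1 || nn == 3) {
    int a = (nn == 1) ? neg[0] : pos[0];
    const int* oth = (nn == 1) ? pos : neg;
    int e0 = edge_point(st, g[a], g[oth[0]], s[a], s[oth[0]], p[a], p[oth[0]]);
    int e1 = edge_point(st, g[a], g[oth[1]], s[a], s[oth[1]], p[a], p[oth[1]]);
    int e2 = edge_point(st, g[a], g[oth[2]], s[a], s[oth[2]], p[a], p[oth[2]]);
    emit_tri(st, e0, e1, e2, inside);
  } else {
    // two inside, two outside: quad split into two triangles
    int a = neg[0], b = neg[1], c = pos[0], d = pos[1];
    int eac = edge_point(st, g[a], g[c], s[a], s[c], p[a], p[c]);
    int ead = edge_point(st, g[a], g[d], s[a], s[d], p[a], p[d]);
    int ebc = edge_point(st, g[b], g[c], s[b], s[c], p[b], p[c]);
    int ebd = edge_point(st, g[b], g[d], s[b], s[d], p[b], p[d]);
    emit_tri(st, eac, ead, ebd, inside);
    emit_tri(st, eac, ebd, ebc, inside);
  }
}

// [[Rcpp::export(name = ".mtet_cpp")]]
List mtet_cpp(NumericVector values, IntegerVector dim, NumericVector spacing,
              NumericVector origin, double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  // corner offsets of the cube, standard ordering
  static const int off[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                                {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
  static const int tets[6][4] = {{0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
                                 {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};
  MTState st;
  double s[8], p[8][3];
  R_xlen_t g[8];
  for (int k = 0; k + 1 < nz; k++)
    for (int j = 0; j + 1 < ny; j++)
      for (int i = 0; i + 1 < nx; i++) {
        bool anyneg = false, anypos = false;
        for (int c = 0; c < 8; c++) {
          int ii = i + off[c][0], jj = j + off[c][1], kk = k + off[c][2];
          g[c] = ii + (R_xlen_t)nx * jj + nxy * kk;
          s[c] = values[g[c]] - level;
          if (s[c] < 0) anyneg = true; else anypos = true;
          p[c][0] = origin[0] + ii * spacing[0];
          p[c][1] = origin[1] + jj * spacing[1];
          p[c][2] = origin[2] + kk * spacing[2];
        }
        if (!anyneg || !anypos) continue;
        for (int t = 0; t < 6; t++) do_tet(st, g, s, p, tets[t]);
      }
  int nv = (int)(st.verts.size() / 3);
  int nf = (int)(st.tris.size() / 3);
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int q = 0; q < nv; q++)
    for (int c = 0; c < 3; c++) V(q, c) = st.verts[3 * (size_t)q + c];
  for (int q = 0; q < nf; q++)
    for (int c = 0; c < 3; c++) F(q, c) = st.tris[3 * (size_t)q + c] + 1;
  return List::create(_["vertices"] = V, _["faces"] = F);
}
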