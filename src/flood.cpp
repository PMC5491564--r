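#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 6-connected flood fills on 3-D grids (column-major, dims nx,ny,nz).

static inline R_xlen_t gid(int i, int j, int k, int nx, int ny) {
  return i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
}

// Connected component of {v : lower <= value <= upper} containing seed.
// [[Rcpp::export(name = ".region_grow_cpp")]]
LogicalVector region_grow_cpp(NumericVector values, IntegerVector dim,
                              IntegerVector seed0, double lower, double upper) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  std::vector<R_xlen_t> stack;
  R_xlen_t s = gid(seed0[0], seed0[1], seed0[2], nx, ny);
  out[s] = TRUE;
  stack.push_back(s);
  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  while (!stack.empty()) {
    R_xlen_t g = stack.back();
    stack.pop_back();
    int i = (int)(g % nx);
    int j = (int)((g / nx) % ny);
    int k = (int)(g / ((R_xlen_t)nx * ny));
    for (int q = 0; q < 6; q++) {
      int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      R_xlen_t g2 = gid(ii, jj, kk, nx, ny);
      if (out[g2]) continue;
      double v = values[g2];
      if (v >= lower && v <= upper) {
        out[g2] = TRUE;
        stack.push_back(g2);
      }
    }
  }
  return out;
}

// Background voxels 6-connected to the grid border (for hole filling).
// [[Rcpp::export(name = ".border_background_cpp")]]
LogicalVector border_background_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  std::vector<R_xlen_t> stack;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        if (i != 0 && j != 0 && k != 0 && i != nx - 1 && j != ny - 1 &&
            k != nz - 1)
          continue;
        R_xlen_t g = gid(i, j, k, nx, ny);
        if (!mask[g] && !out[g]) {
          out[g] = TRUE;
          stack.push_back(g);
        }
      }
  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  while (!stack.empty()) {
    R_xlen_t g = stack.back();
    stack.pop_back();
    int i = (int)(g % nx);
    int j = (int)((g / nx) % ny);
    int k = (int)(g / ((R_xlen_t)nx * ny));
    for (int q = 0; q < 6; q++) {
      int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      R_xlen_t g2 = gid(ii, jj, kk, nx, ny);
      if (!mask[g2] && !out[g2]) {
        out[g2] = TRUE;
        stack.push_back(g2);
      }
    }
  }
  return out;
}
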