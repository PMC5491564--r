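#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Nearest-neighbour vertex search on a uniform hash grid. Ties in distance
// resolve to the lowest target vertex index so results are deterministic.

// [[Rcpp::export(name = ".nn_cpp")]]
List nn_cpp(NumericMatrix query, NumericMatrix target) {
  const int nq = query.nrow(), nt = target.nrow();
  double lo[3], hi[3];
  for (int c = 0; c < 3; c++) {
    lo[c] = std::numeric_limits<double>::infinity();
    hi[c] = -std::numeric_limits<double>::infinity();
  }
  for (int i = 0; i < nt; i++)
    for (int c = 0; c < 3; c++) {
      lo[c] = std::min(lo[c], target(i, c));
      hi[c] = std::max(hi[c], target(i, c));
    }
  double ext = 0.0;
  for (int c = 0; c < 3; c++) ext = std::max(ext, hi[c] - lo[c]);
  int ncell = std::max(1, std::min(128, (int)std::cbrt((double)nt)));
  double cell = (ext > 0) ? ext / ncell : 1.0;
  int dims[3];
  for (int c = 0; c < 3; c++)
    dims[c] = std::max(1, (int)std::floor((hi[c] - lo[c]) / cell) + 1);
  R_xlen_t ncells = (R_xlen_t)dims[0] * dims[1] * dims[2];

  std::vector<int> cell_of(nt);
  std::vector<int> counts(ncells + 1, 0);
  auto cix = [&](double x, int c) {
    int q = (int)std::floor((x - lo[c]) / cell);
    return std::max(0, std::min(dims[c] - 1, q));
  };
  for (int i = 0; i < nt; i++) {
    int cx = cix(target(i, 0), 0), cy = cix(target(i, 1), 1),
        cz = cix(target(i, 2), 2);
    cell_of[i] = cx + dims[0] * (cy + dims[1] * cz);
    counts[cell_of[i] + 1]++;
  }
  for (R_xlen_t c = 0; c < ncells; c++) counts[c + 1] += counts[c];
  std::vector<int> bucket(nt);
  {
    std::vector<int> cur(counts.begin(), counts.end() - 1);
    for (int i = 0; i < nt; i++) bucket[cur[cell_of[i]]++] = i;
  }

  NumericVector dist(nq);
  IntegerVector idx(nq);
  for (int q = 0; q < nq; q++) {
    double px = query(q, 0), py = query(q, 1), pz = query(q, 2);
    int cx = cix(px, 0), cy = cix(py, 1), cz = cix(pz, 2);
    double best = std::numeric_limits<double>::infinity();
    int besti = -1;
    int maxr = std::max(dims[0], std::max(dims[1], dims[2]));
    for (int r = 0; r <= maxr; r++) {
      // once a candidate is known, stop when the ring cannot beat it
      if (besti >= 0 && (double)(r - 1) * cell > std::sqrt(best)) break;
      bool any = false;
      for (int dz = -r; dz <= r; dz++) {
        int z = cz + dz;
        if (z < 0 || z >= dims[2]) continue;
        for (int dy = -r; dy <= r; dy++) {
          int y = cy + dy;
          if (y < 0 || y >= dims[1]) continue;
          for (int dx = -r; dx <= r; dx++) {
            // only the shell of the ring
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != r)
              continue;
            int x = cx + dx;
            if (x < 0 || x >= dims[0]) continue;
            any = true;
            R_xlen_t cc = x + (R_xlen_t)dims[0] * (y + (R_xlen_t)dims[1] * z);
            for (int b = counts[cc]; b < counts[cc + 1]; b++) {
              int i = bucket[b];
              double d0 = target(i, 0) - px, d1 = target(i, 1) - py,
                     d2 = target(i, 2) - pz;
              double d = d0 * d0 + d1 * d1 + d2 * d2;
              if (d < best || (d == best && i < besti)) {
                best = d;
                besti = i;
              }
            }
          }
        }
      }
      if (!any && besti >= 0) break;
    }
    dist[q] = std::sqrt(best);
    idx[q] = besti + 1;
  }
  return List::create(_["distance"] = dist, _["index"] = idx);
}
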