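#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian convolution with reflected boundaries, per-axis sigma
// in voxel units; kernel truncated at 4 sigma and normalised to unit sum.

static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; i++) {
    double w = std::exp(-0.5 * (i / sigma) * (i / sigma));
    k[i + r] = w;
    s += w;
  }
  for (size_t i = 0; i < k.size(); i++) k[i] /= s;
  return k;
}

static inline int reflect(int i, int n) {
  // symmetric reflection (…2 1 0 | 0 1 2… style half-sample reflection)
  if (n == 1) return 0;
  int p = 2 * n;
  i = ((i % p) + p) % p;
  return (i < n) ? i : p - 1 - i;
}

static void conv_axis(std::vector<double>& a, int nx, int ny, int nz, int axis,
                      const std::vector<double>& kern) {
  int r = ((int)kern.size() - 1) / 2;
  int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  std::vector<double> line(n), outl(n);
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  int d1 = (axis == 0) ? ny : nx;
  int d2 = (axis == 2) ? ny : nz;
  for (int b = 0; b < d2; b++)
    for (int a1 = 0; a1 < d1; a1++) {
      R_xlen_t base;
      R_xlen_t stride;
      if (axis == 0) { base = (R_xlen_t)nx * (a1 + (R_xlen_t)ny * b); stride = 1; }
      else if (axis == 1) { base = a1 + nxy * (R_xlen_t)b; stride = nx; }
      else { base = a1 + (R_xlen_t)nx * b; stride = nxy; }
      for (int q = 0; q < n; q++) line[q] = a[base + stride * q];
      for (int q = 0; q < n; q++) {
        double s = 0.0;
        for (int t = -r; t <= r; t++) s += kern[t + r] * line[reflect(q + t, n)];
        outl[q] = s;
      }
      for (int q = 0; q < n; q++) a[base + stride * q] = outl[q];
    }
}

// [[Rcpp::export(name = ".gauss_blur_cpp")]]
NumericVector gauss_blur_cpp(NumericVector values, IntegerVector dim,
                             NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(values.begin(), values.end());
  for (int axis = 0; axis < 3; axis++) {
    if (sigma_vox[axis] <= 0) continue;
    std::vector<double> kern = gauss_kernel(sigma_vox[axis]);
    conv_axis(a, nx, ny, nz, axis, kern);
  }
  NumericVector out(values.size());
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}
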