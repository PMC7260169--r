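#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : (period - 1 - i);
}

// Separable 3-D Gaussian smoothing, kernel truncated at `truncate` standard
// deviations (radius = ceil(truncate*sigma)), half-sample reflecting
// boundaries. Double precision throughout.
// [[Rcpp::export]]
NumericVector gaussian_smooth_cpp(NumericVector vol, IntegerVector dims,
                                  double sigma, double truncate) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  if (sigma <= 0) {
    NumericVector out = clone(vol);
    out.attr("dim") = dims;
    return out;
  }
  const int r = (int)std::ceil(truncate * sigma);
  std::vector<double> k(2 * r + 1);
  double ksum = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    ksum += k[i + r];
  }
  for (int i = 0; i <= 2 * r; ++i) k[i] /= ksum;

  std::vector<double> a(vol.begin(), vol.end()), b(n);
  const size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;
  const int dim3[3] = {nx, ny, nz};
  const size_t str[3] = {sx, sy, sz};

  for (int ax = 0; ax < 3; ++ax) {
    const int na = dim3[ax];
    const size_t sa = str[ax];
    // iterate over all lines along axis ax
    const int nb = dim3[(ax + 1) % 3], nc = dim3[(ax + 2) % 3];
    const size_t sb = str[(ax + 1) % 3], sc = str[(ax + 2) % 3];
    for (int c = 0; c < nc; ++c)
      for (int bidx = 0; bidx < nb; ++bidx) {
        const size_t base = (size_t)bidx * sb + (size_t)c * sc;
        for (int i = 0; i < na; ++i) {
          double acc = 0.0;
          for (int j = -r; j <= r; ++j)
            acc += k[j + r] * a[base + (size_t)reflect_idx(i + j, na) * sa];
          b[base + (size_t)i * sa] = acc;
        }
      }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}
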