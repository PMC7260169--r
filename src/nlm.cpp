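#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// exp(-e) for e in [0, 25] via a dense table with linear interpolation
// (absolute error < 1e-5); deterministic and much cheaper than expf.
static const int EXP_TAB_N = 4096;
static const float EXP_TAB_MAX = 25.0f;
static inline const float *exp_table() {
  static float tab[EXP_TAB_N + 2];
  static bool init = false;
  if (!init) {
    for (int i = 0; i <= EXP_TAB_N + 1; ++i)
      tab[i] = (float)std::exp(-(double)i * EXP_TAB_MAX / EXP_TAB_N);
    init = true;
  }
  return tab;
}
static inline float exp_neg(float e, const float *tab) {
  const float idx = e * (EXP_TAB_N / EXP_TAB_MAX);
  const int i = (int)idx;
  const float frac = idx - i;
  return tab[i] + frac * (tab[i + 1] - tab[i]);
}

// Half-sample symmetric reflection of index i into [0, n): ... 2 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : (period - 1 - i);
}

// 3-D (or slice-wise 2-D) non-local means denoising.
//
// Each voxel is replaced by a similarity-weighted average of voxels within
// `patch_distance` (Chebyshev) of it; the weight of a candidate q for voxel p is
//   w = exp(-max(d2 - 2*sigma^2, 0) / h^2)
// where d2 is the mean squared difference between the patches (edge length
// 2*patch_radius+1) centred on p and q. Weights smaller than exp(-25) are
// treated as exactly zero. The volume is reflect-padded so every patch sum is
// complete; per-voxel summation order is independent of the position of the
// volume in a larger array, which is what makes halo-chunked application
// bit-identical to monolithic application.
//
// Patch distances are computed with one separable box sum of the shifted
// squared-difference field per search offset; offset symmetry halves the work.
// [[Rcpp::export]]
NumericVector nlm_denoise_cpp(NumericVector vol, IntegerVector dims,
                              int patch_radius, int patch_distance,
                              double h, double sigma, bool slicewise) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (h <= 0) stop("nlm: filtering strength h must be > 0");
  const int prx = patch_radius, pry = patch_radius;
  const int prz = slicewise ? 0 : patch_radius;
  const int pdx = patch_distance, pdy = patch_distance;
  const int pdz = slicewise ? 0 : patch_distance;
  const int mx = pdx + prx, my = pdy + pry, mz = pdz + prz;
  const int Px = nx + 2 * mx, Py = ny + 2 * my, Pz = nz + 2 * mz;
  const size_t Pxy = (size_t)Px * Py, Pn = Pxy * Pz;

  std::vector<float> pv(Pn), s(Pn), b1(Pn), acc(Pn, 0.0f), wsum(Pn, 0.0f);

  // reflect-padded copy
  {
    std::vector<int> rx(Px), ry(Py), rz(Pz);
    for (int i = 0; i < Px; ++i) rx[i] = reflect_index(i - mx, nx);
    for (int i = 0; i < Py; ++i) ry[i] = reflect_index(i - my, ny);
    for (int i = 0; i < Pz; ++i) rz[i] = reflect_index(i - mz, nz);
    for (int z = 0; z < Pz; ++z)
      for (int y = 0; y < Py; ++y) {
        const double *src = &vol[(size_t)nx * (ry[y] + (size_t)ny * rz[z])];
        float *dst = &pv[(size_t)Px * y + Pxy * z];
        for (int x = 0; x < Px; ++x) dst[x] = (float)src[rx[x]];
      }
  }

  const float *etab = exp_table();
  const float inv_n = 1.0f / ((2 * prx + 1) * (2 * pry + 1) * (2 * prz + 1));
  const float two_sigma2 = 2.0f * (float)(sigma * sigma);
  const float inv_h2 = 1.0f / (float)(h * h);

  for (int tz = -pdz; tz <= pdz; ++tz)
    for (int ty = -pdy; ty <= pdy; ++ty)
      for (int tx = -pdx; tx <= pdx; ++tx) {
        // half-space of offsets: each unordered pair of voxels once
        if (!(tz > 0 || (tz == 0 && (ty > 0 || (ty == 0 && tx > 0))))) continue;
        const long toff = (long)tx + (long)Px * ty + (long)Pxy * tz;
        // ranges where p and p+t are both inside the padded array
        const int sx0 = std::max(0, -tx), sx1 = Px - std::max(0, tx);
        const int sy0 = std::max(0, -ty), sy1 = Py - std::max(0, ty);
        const int sz0 = std::max(0, -tz), sz1 = Pz - std::max(0, tz);

        // squared differences of the shifted volume
        for (int z = sz0; z < sz1; ++z)
          for (int y = sy0; y < sy1; ++y) {
            float *sp = &s[(size_t)Px * y + Pxy * z];
            const float *vp = &pv[(size_t)Px * y + Pxy * z];
            for (int x = sx0; x < sx1; ++x) {
              const float d = vp[x] - vp[x + toff];
              sp[x] = d * d;
            }
          }

        // separable box sums: x into b1, y back into s, z into b1
        const int bx0 = sx0 + prx, bx1 = sx1 - prx;
        for (int z = sz0; z < sz1; ++z)
          for (int y = sy0; y < sy1; ++y) {
            const float *sp = &s[(size_t)Px * y + Pxy * z];
            float *bp = &b1[(size_t)Px * y + Pxy * z];
            for (int x = bx0; x < bx1; ++x) {
              float acc0 = 0.0f;
              for (int k = -prx; k <= prx; ++k) acc0 += sp[x + k];
              bp[x] = acc0;
            }
          }
        const int by0 = sy0 + pry, by1 = sy1 - pry;
        for (int z = sz0; z < sz1; ++z)
          for (int y = by0; y < by1; ++y) {
            float *sp = &s[(size_t)Px * y + Pxy * z];
            const float *bp = &b1[(size_t)Px * y + Pxy * z];
            for (int x = bx0; x < bx1; ++x) {
              float acc0 = 0.0f;
              for (int k = -pry; k <= pry; ++k) acc0 += bp[x + (long)k * Px];
              sp[x] = acc0;
            }
          }
        const int bz0 = sz0 + prz, bz1 = sz1 - prz;
        for (int z = bz0; z < bz1; ++z)
          for (int y = by0; y < by1; ++y) {
            const float *sp = &s[(size_t)Px * y + Pxy * z];
            float *bp = &b1[(size_t)Px * y + Pxy * z];
            for (int x = bx0; x < bx1; ++x) {
              float acc0 = 0.0f;
              for (int k = -prz; k <= prz; ++k) acc0 += sp[x + (long)k * Pxy];
              bp[x] = acc0;
            }
          }

        // weights and symmetric accumulation
        for (int z = bz0; z < bz1; ++z)
          for (int y = by0; y < by1; ++y) {
            const size_t row = (size_t)Px * y + Pxy * z;
            for (int x = bx0; x < bx1; ++x) {
              const size_t p = row + x;
              float d2 = b1[p] * inv_n - two_sigma2;
              if (d2 <= 0.0f) {
                acc[p] += pv[p + toff];
                wsum[p] += 1.0f;
                acc[p + toff] += pv[p];
                wsum[p + toff] += 1.0f;
              } else {
                const float e = d2 * inv_h2;
                if (e > 25.0f) continue;
                const float w = exp_neg(e, etab);
                acc[p] += w * pv[p + toff];
                wsum[p] += w;
                acc[p + toff] += w * pv[p];
                wsum[p + toff] += w;
              }
            }
          }
      }

  NumericVector out(vol.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const size_t prow = (size_t)Px * (y + my) + Pxy * (z + mz) + mx;
      const size_t orow = (size_t)nx * (y + (size_t)ny * z);
      for (int x = 0; x < nx; ++x) {
        const size_t p = prow + x;
        out[orow + x] = (double)((acc[p] + pv[p]) / (wsum[p] + 1.0f));
      }
    }
  out.attr("dim") = dims;
  return out;
}
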