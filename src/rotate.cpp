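#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double catmull_rom(double u, int i) {
  // Keys cubic convolution weights (a = -1/2) for samples at offsets -1,0,1,2
  const double u2 = u * u, u3 = u2 * u;
  switch (i) {
  case 0: return -0.5 * u3 + u2 - 0.5 * u;
  case 1: return 1.5 * u3 - 2.5 * u2 + 1.0;
  case 2: return -1.5 * u3 + 2.0 * u2 + 0.5 * u;
  default: return 0.5 * u3 - 0.5 * u2;
  }
}

static inline int clampi(int i, int lo, int hi) {
  return i < lo ? lo : (i > hi ? hi : i);
}

// Rotate a volume about its centre by Euler angles (degrees) applied as
// R = Rz(az) %*% Ry(ay) %*% Rx(ax); each output voxel samples the input at the
// inverse-rotated position with nearest (order 0), trilinear (1) or cubic
// convolution (3) interpolation. Positions outside the input are filled.
// [[Rcpp::export]]
NumericVector rotate_volume_cpp(NumericVector vol, IntegerVector dims,
                                double ax_deg, double ay_deg, double az_deg,
                                int order, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double d2r = M_PI / 180.0;
  const double cx = std::cos(ax_deg * d2r), sx = std::sin(ax_deg * d2r);
  const double cy = std::cos(ay_deg * d2r), sy = std::sin(ay_deg * d2r);
  const double cz = std::cos(az_deg * d2r), sz = std::sin(az_deg * d2r);
  // R = Rz * Ry * Rx
  const double R[3][3] = {
    {cz * cy, cz * sy * sx - sz * cx, cz * sy * cx + sz * sx},
    {sz * cy, sz * sy * sx + cz * cx, sz * sy * cx - cz * sx},
    {-sy, cy * sx, cy * cx}};
  const double c0 = 0.5 * (nx - 1), c1 = 0.5 * (ny - 1), c2 = 0.5 * (nz - 1);
  const double eps = 1e-6;
  const size_t sxy = (size_t)nx * ny;
  NumericVector out(vol.size());

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const double p0 = x - c0, p1 = y - c1, p2 = z - c2;
        // inverse rotation = R transposed
        const double q0 = R[0][0] * p0 + R[1][0] * p1 + R[2][0] * p2 + c0;
        const double q1 = R[0][1] * p0 + R[1][1] * p1 + R[2][1] * p2 + c1;
        const double q2 = R[0][2] * p0 + R[1][2] * p1 + R[2][2] * p2 + c2;
        const size_t o = (size_t)x + (size_t)nx * y + sxy * z;
        if (q0 < -eps || q0 > nx - 1 + eps || q1 < -eps || q1 > ny - 1 + eps ||
            q2 < -eps || q2 > nz - 1 + eps) {
          out[o] = fill;
          continue;
        }
        if (order == 0) {
          const int i = clampi((int)std::lround(q0), 0, nx - 1);
          const int j = clampi((int)std::lround(q1), 0, ny - 1);
          const int k = clampi((int)std::lround(q2), 0, nz - 1);
          out[o] = vol[(size_t)i + (size_t)nx * j + sxy * k];
        } else if (order == 1) {
          const int i0 = clampi((int)std::floor(q0), 0, nx - 1);
          const int j0 = clampi((int)std::floor(q1), 0, ny - 1);
          const int k0 = clampi((int)std::floor(q2), 0, nz - 1);
          const int i1 = clampi(i0 + 1, 0, nx - 1);
          const int j1 = clampi(j0 + 1, 0, ny - 1);
          const int k1 = clampi(k0 + 1, 0, nz - 1);
          const double fx = q0 - std::floor(q0), fy = q1 - std::floor(q1),
                       fz = q2 - std::floor(q2);
          double v = 0.0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                const double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                                 (dk ? fz : 1 - fz);
                v += w * vol[(size_t)(di ? i1 : i0) +
                             (size_t)nx * (dj ? j1 : j0) + sxy * (dk ? k1 : k0)];
              }
          out[o] = v;
        } else {
          const int i0 = (int)std::floor(q0), j0 = (int)std::floor(q1),
                    k0 = (int)std::floor(q2);
          const double fx = q0 - i0, fy = q1 - j0, fz = q2 - k0;
          double wx[4], wy[4], wz[4];
          for (int i = 0; i < 4; ++i) {
            wx[i] = catmull_rom(fx, i);
            wy[i] = catmull_rom(fy, i);
            wz[i] = catmull_rom(fz, i);
          }
          double v = 0.0;
          for (int dk = 0; dk < 4; ++dk) {
            const int k = clampi(k0 - 1 + dk, 0, nz - 1);
            for (int dj = 0; dj < 4; ++dj) {
              const int j = clampi(j0 - 1 + dj, 0, ny - 1);
              const double wyz = wy[dj] * wz[dk];
              const size_t row = (size_t)nx * j + sxy * k;
              for (int di = 0; di < 4; ++di) {
                const int i = clampi(i0 - 1 + di, 0, nx - 1);
                v += wx[di] * wyz * vol[row + i];
              }
            }
          }
          out[o] = v;
        }
      }
  out.attr("dim") = dims;
  return out;
}
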