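#ifndef SSMSEG_COMMON_H
#define SSMSEG_COMMON_H

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

// Uniform cubic B-spline basis on [0,1).
inline void bspline_basis(double mu, double B[4]) {
  const double m = mu, m2 = m * m, m3 = m2 * m;
  B[0] = (1.0 - 3.0 * m + 3.0 * m2 - m3) / 6.0;
  B[1] = (3.0 * m3 - 6.0 * m2 + 4.0) / 6.0;
  B[2] = (-3.0 * m3 + 3.0 * m2 + 3.0 * m + 1.0) / 6.0;
  B[3] = m3 / 6.0;
}

// Trilinear sample of a volume stored x-fastest. Continuous 0-based index
// coordinates. Returns `background` outside the valid domain and sets
// *inside = false there.
inline double trilinear(const double *vox, const int *dim,
                        double cx, double cy, double cz,
                        double background, bool *inside) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if (cx < 0.0 || cy < 0.0 || cz < 0.0 ||
      cx > nx - 1.0 || cy > ny - 1.0 || cz > nz - 1.0) {
    if (inside) *inside = false;
    return background;
  }
  if (inside) *inside = true;
  int i0 = (int)std::floor(cx), j0 = (int)std::floor(cy), k0 = (int)std::floor(cz);
  if (i0 >= nx - 1) i0 = nx - 2;
  if (j0 >= ny - 1) j0 = ny - 2;
  if (k0 >= nz - 1) k0 = nz - 2;
  if (i0 < 0) i0 = 0;
  if (j0 < 0) j0 = 0;
  if (k0 < 0) k0 = 0;
  const double fx = cx - i0, fy = cy - j0, fz = cz - k0;
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const double *base = vox + i0 + (R_xlen_t)nx * j0 + nxy * k0;
  const double c000 = base[0], c100 = base[1];
  const double c010 = base[nx], c110 = base[nx + 1];
  const double c001 = base[nxy], c101 = base[nxy + 1];
  const double c011 = base[nxy + nx], c111 = base[nxy + nx + 1];
  const double c00 = c000 * (1 - fx) + c100 * fx;
  const double c10 = c010 * (1 - fx) + c110 * fx;
  const double c01 = c001 * (1 - fx) + c101 * fx;
  const double c11 = c011 * (1 - fx) + c111 * fx;
  const double c0 = c00 * (1 - fy) + c10 * fy;
  const double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

#endif
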