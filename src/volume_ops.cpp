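#include "ssmseg_common.h"
using namespace Rcpp;

// Trilinear samples of a volume at world points (rows of pts, mm).
// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector vox, IntegerVector dim,
                                   NumericVector spacing, NumericVector origin,
                                   NumericMatrix pts, double background) {
  const int n = pts.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double cx = (pts(p, 0) - origin[0]) / spacing[0];
    double cy = (pts(p, 1) - origin[1]) / spacing[1];
    double cz = (pts(p, 2) - origin[2]) / spacing[2];
    out[p] = trilinear(REAL(vox), INTEGER(dim), cx, cy, cz, background, nullptr);
  }
  return out;
}

// Resample `moving` onto the grid described by (odim, ospacing, oorigin):
// each output voxel center x is mapped to y = A x + b (affine, row-major 3x4)
// plus an optional dense displacement field (disp, nvox x 3, same output grid).
// [[Rcpp::export]]
List cpp_resample_affine(NumericVector mvox, IntegerVector mdim,
                         NumericVector mspacing, NumericVector morigin,
                         IntegerVector odim, NumericVector ospacing,
                         NumericVector oorigin, NumericMatrix affine,
                         Nullable<NumericMatrix> disp, double background,
                         bool nearest) {
  const int nx = odim[0], ny = odim[1], nz = odim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  LogicalVector inside(n);
  const double *mv = REAL(mvox);
  const int *md = INTEGER(mdim);
  NumericMatrix dmat;
  bool have_disp = disp.isNotNull();
  if (have_disp) dmat = NumericMatrix(disp);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    const double z = oorigin[2] + k * ospacing[2];
    for (int j = 0; j < ny; ++j) {
      const double y = oorigin[1] + j * ospacing[1];
      for (int i = 0; i < nx; ++i, ++idx) {
        const double x = oorigin[0] + i * ospacing[0];
        double tx = affine(0, 0) * x + affine(0, 1) * y + affine(0, 2) * z + affine(0, 3);
        double ty = affine(1, 0) * x + affine(1, 1) * y + affine(1, 2) * z + affine(1, 3);
        double tz = affine(2, 0) * x + affine(2, 1) * y + affine(2, 2) * z + affine(2, 3);
        if (have_disp) {
          tx += dmat(idx, 0);
          ty += dmat(idx, 1);
          tz += dmat(idx, 2);
        }
        double cx = (tx - morigin[0]) / mspacing[0];
        double cy = (ty - morigin[1]) / mspacing[1];
        double cz = (tz - morigin[2]) / mspacing[2];
        bool in = true;
        if (nearest) {
          int ii = (int)std::lround(cx), jj = (int)std::lround(cy), kk = (int)std::lround(cz);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= md[0] || jj >= md[1] || kk >= md[2]) {
            out[idx] = background;
            in = false;
          } else {
            out[idx] = mv[ii + (R_xlen_t)md[0] * jj + (R_xlen_t)md[0] * md[1] * kk];
          }
        } else {
          out[idx] = trilinear(mv, md, cx, cy, cz, background, &in);
        }
        inside[idx] = in;
      }
    }
  }
  return List::create(_["values"] = out, _["inside"] = inside);
}

// Separable Gaussian blur, sigma in voxels per axis; truncated at 3 sigma.
// Border handling: renormalized (kernel clipped at the edges).
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector vox, IntegerVector dim,
                                NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> cur(REAL(vox), REAL(vox) + n), nxt(n);
  const int nn[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0) continue;
    const int hw = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> ker(2 * hw + 1);
    for (int t = -hw; t <= hw; ++t) ker[t + hw] = std::exp(-0.5 * t * t / (s * s));
    const int na = nn[ax];
    const R_xlen_t st = stride[ax];
    // iterate over all lines along axis ax
    const int nb = nn[(ax + 1) % 3], nc = nn[(ax + 2) % 3];
    const R_xlen_t sb = stride[(ax + 1) % 3], sc = stride[(ax + 2) % 3];
    for (int c = 0; c < nc; ++c) {
      for (int b = 0; b < nb; ++b) {
        const R_xlen_t base = sb * b + sc * c;
        for (int a = 0; a < na; ++a) {
          double acc = 0.0, wsum = 0.0;
          const int lo = std::max(0, a - hw), hi = std::min(na - 1, a + hw);
          for (int t = lo; t <= hi; ++t) {
            const double w = ker[t - a + hw];
            acc += w * cur[base + st * t];
            wsum += w;
          }
          nxt[base + st * a] = acc / wsum;
        }
      }
    }
    cur.swap(nxt);
  }
  return NumericVector(cur.begin(), cur.end());
}
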