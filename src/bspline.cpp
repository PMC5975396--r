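#include "ssmseg_common.h"
using namespace Rcpp;

// Displacement of a cubic B-spline lattice at world points.
// Lattice: control point (a,b,c) sits at gor + (a,b,c)*gsp (0-based).
// A point has full support when its 4x4x4 control neighborhood exists.
// outside = 0 -> error, 1 -> zero displacement outside support.
// [[Rcpp::export]]
NumericMatrix cpp_bspline_disp(IntegerVector kdim, NumericVector gsp,
                               NumericVector gor, NumericMatrix d,
                               NumericMatrix pts, int outside) {
  const int Kx = kdim[0], Ky = kdim[1], Kz = kdim[2];
  const int n = pts.nrow();
  NumericMatrix out(n, 3);
  for (int p = 0; p < n; ++p) {
    double s[3], B[3][4];
    int i0[3];
    bool ok = true;
    for (int ax = 0; ax < 3; ++ax) {
      s[ax] = (pts(p, ax) - gor[ax]) / gsp[ax];
      const int fl = (int)std::floor(s[ax]);
      i0[ax] = fl - 1;
      bspline_basis(s[ax] - fl, B[ax]);
      const int K = ax == 0 ? Kx : (ax == 1 ? Ky : Kz);
      if (i0[ax] < 0 || i0[ax] + 3 > K - 1) ok = false;
    }
    if (!ok) {
      if (outside == 0) stop("point outside B-spline lattice support");
      continue; // zero displacement
    }
    double acc[3] = {0.0, 0.0, 0.0};
    for (int nk = 0; nk < 4; ++nk) {
      for (int nj = 0; nj < 4; ++nj) {
        const double wjk = B[1][nj] * B[2][nk];
        const R_xlen_t base = (R_xlen_t)i0[0] +
          (R_xlen_t)Kx * (i0[1] + nj) + (R_xlen_t)Kx * Ky * (i0[2] + nk);
        for (int ni = 0; ni < 4; ++ni) {
          const double w = B[0][ni] * wjk;
          const R_xlen_t cp = base + ni;
          acc[0] += w * d(cp, 0);
          acc[1] += w * d(cp, 1);
          acc[2] += w * d(cp, 2);
        }
      }
    }
    out(p, 0) = acc[0];
    out(p, 1) = acc[1];
    out(p, 2) = acc[2];
  }
  return out;
}
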