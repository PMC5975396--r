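#include "ssmseg_common.h"
using namespace Rcpp;

namespace {

struct MIHist {
  int bins;
  std::vector<double> joint; // bins x bins, fixed index fastest
  double n;
  MIHist(int b) : bins(b), joint((size_t)b * b, 0.0), n(0.0) {}
  inline void add(int fb, int mb, double w) {
    joint[fb + (size_t)bins * mb] += w;
    n += w;
  }
  // MI = H(F) + H(M) - H(F,M), natural log, from the joint over the overlap.
  double mi() const {
    if (n <= 0) return 0.0;
    std::vector<double> pf(bins, 0.0), pm(bins, 0.0);
    for (int mb = 0; mb < bins; ++mb)
      for (int fb = 0; fb < bins; ++fb) {
        const double p = joint[fb + (size_t)bins * mb] / n;
        pf[fb] += p;
        pm[mb] += p;
      }
    double hf = 0, hm = 0, hfm = 0;
    for (int b = 0; b < bins; ++b) {
      if (pf[b] > 0) hf -= pf[b] * std::log(pf[b]);
      if (pm[b] > 0) hm -= pm[b] * std::log(pm[b]);
    }
    for (size_t q = 0; q < joint.size(); ++q) {
      const double p = joint[q] / n;
      if (p > 0) hfm -= p * std::log(p);
    }
    return hf + hm - hfm;
  }
};

// intensity -> fractional bin coordinate v so that bin centers map to
// integers; linear (tent) weights between floor(v) and floor(v)+1.  Used
// for both images (partial-volume binning), which keeps MI symmetric.
inline void pv_bins(double m, double lo, double hi, int bins,
                    int *mb, double *frac, bool *interior) {
  double v = (m - lo) / (hi - lo) * bins - 0.5;
  if (v <= 0.0) { *mb = 0; *frac = 0.0; *interior = false; return; }
  if (v >= bins - 1.0) { *mb = bins - 1; *frac = 0.0; *interior = false; return; }
  const int b = (int)std::floor(v);
  *mb = b;
  *frac = v - b;
  *interior = true;
}

} // namespace

// Similarity/affine registration cost on the fixed grid.
// metric: 0 = SSD (mean squared difference), 1 = negated MI.
// range = c(fixed_lo, fixed_hi, moving_lo, moving_hi) used for MI binning.
// [[Rcpp::export]]
List cpp_affine_cost(NumericVector fvox, IntegerVector fdim,
                     NumericVector fsp, NumericVector forig,
                     NumericVector mvox, IntegerVector mdim,
                     NumericVector msp, NumericVector morig,
                     NumericMatrix affine, int metric, int bins,
                     NumericVector range) {
  const int nx = fdim[0], ny = fdim[1], nz = fdim[2];
  const double *fv = REAL(fvox), *mv = REAL(mvox);
  const int *md = INTEGER(mdim);
  R_xlen_t idx = 0, nin = 0;
  double ssd = 0.0;
  MIHist hist(bins > 0 ? bins : 1);
  for (int k = 0; k < nz; ++k) {
    const double z = forig[2] + k * fsp[2];
    for (int j = 0; j < ny; ++j) {
      const double y = forig[1] + j * fsp[1];
      for (int i = 0; i < nx; ++i, ++idx) {
        const double x = forig[0] + i * fsp[0];
        const double tx = affine(0,0)*x + affine(0,1)*y + affine(0,2)*z + affine(0,3);
        const double ty = affine(1,0)*x + affine(1,1)*y + affine(1,2)*z + affine(1,3);
        const double tz = affine(2,0)*x + affine(2,1)*y + affine(2,2)*z + affine(2,3);
        bool in;
        const double m = trilinear(mv, md,
                                   (tx - morig[0]) / msp[0],
                                   (ty - morig[1]) / msp[1],
                                   (tz - morig[2]) / msp[2], 0.0, &in);
        if (!in) continue;
        ++nin;
        const double f = fv[idx];
        if (metric == 0) {
          const double dd = m - f;
          ssd += dd * dd;
        } else {
          int mb, fb; double mfrac, ffrac; bool mint, fint;
          pv_bins(m, range[2], range[3], bins, &mb, &mfrac, &mint);
          pv_bins(f, range[0], range[1], bins, &fb, &ffrac, &fint);
          hist.add(fb, mb, (1.0 - ffrac) * (1.0 - mfrac));
          if (mfrac > 0) hist.add(fb, mb + 1, (1.0 - ffrac) * mfrac);
          if (ffrac > 0) {
            hist.add(fb + 1, mb, ffrac * (1.0 - mfrac));
            if (mfrac > 0) hist.add(fb + 1, mb + 1, ffrac * mfrac);
          }
        }
      }
    }
  }
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  const double overlap = ntot > 0 ? (double)nin / ntot : 0.0;
  double cost;
  if (metric == 0) cost = nin > 0 ? ssd / nin : R_PosInf;
  else cost = -hist.mi();
  return List::create(_["cost"] = cost, _["overlap"] = overlap,
                      _["n"] = (double)nin);
}

// FFD registration cost and analytic gradient with respect to the control
// point displacements.  Transform: y = A x + u(x), u the lattice displacement
// at the fixed-grid world point x; voxels without full lattice support or
// mapping outside the moving volume are excluded from the cost.
// [[Rcpp::export]]
List cpp_ffd_cost_grad(NumericVector fvox, IntegerVector fdim,
                       NumericVector fsp, NumericVector forig,
                       NumericVector mvox, IntegerVector mdim,
                       NumericVector msp, NumericVector morig,
                       NumericMatrix affine,
                       IntegerVector kdim, NumericVector gsp,
                       NumericVector gor, NumericMatrix d,
                       int metric, int bins, NumericVector range,
                       bool want_grad) {
  const int nx = fdim[0], ny = fdim[1], nz = fdim[2];
  const int Kx = kdim[0], Ky = kdim[1], Kz = kdim[2];
  const double *fv = REAL(fvox), *mv = REAL(mvox);
  const int *md = INTEGER(mdim);
  const double *dp = REAL(d);
  const R_xlen_t ncp = d.nrow();
  double aff[12];
  for (int r_ = 0; r_ < 3; ++r_)
    for (int c_ = 0; c_ < 4; ++c_) aff[r_ * 4 + c_] = affine(r_, c_);

  struct Rec {
    float w[3][4];      // per-axis basis weights
    int i0[3];          // lattice corner
    float g[3];         // moving gradient at y (d m / d world)
    float dfdm_aux;     // SSD: (m - f); MI: filled in pass 2
    int fb, mb;         // MI bins
    float frac, ffrac;
    bool interior;
  };
  std::vector<Rec> recs;
  recs.reserve((size_t)nx * ny * (size_t)nz / 4);

  R_xlen_t idx = 0, nin = 0;
  double ssd = 0.0;
  MIHist hist(bins > 0 ? bins : 1);

  for (int k = 0; k < nz; ++k) {
    const double z = forig[2] + k * fsp[2];
    for (int j = 0; j < ny; ++j) {
      const double y0 = forig[1] + j * fsp[1];
      for (int i = 0; i < nx; ++i, ++idx) {
        const double x = forig[0] + i * fsp[0];
        const double pw[3] = {x, y0, z};
        double B[3][4];
        int i0[3];
        bool ok = true;
        for (int ax = 0; ax < 3; ++ax) {
          const double s = (pw[ax] - gor[ax]) / gsp[ax];
          const int fl = (int)std::floor(s);
          i0[ax] = fl - 1;
          bspline_basis(s - fl, B[ax]);
          const int K = ax == 0 ? Kx : (ax == 1 ? Ky : Kz);
          if (i0[ax] < 0 || i0[ax] + 3 > K - 1) ok = false;
        }
        if (!ok) continue;
        double u[3] = {0, 0, 0};
        for (int nk = 0; nk < 4; ++nk)
          for (int nj = 0; nj < 4; ++nj) {
            const double wjk = B[1][nj] * B[2][nk];
            const R_xlen_t base = (R_xlen_t)i0[0] +
              (R_xlen_t)Kx * (i0[1] + nj) + (R_xlen_t)Kx * Ky * (i0[2] + nk);
            for (int ni = 0; ni < 4; ++ni) {
              const double w = B[0][ni] * wjk;
              u[0] += w * dp[base + ni];
              u[1] += w * dp[base + ni + ncp];
              u[2] += w * dp[base + ni + 2 * ncp];
            }
          }
        const double tx = aff[0]*x + aff[1]*y0 + aff[2]*z + aff[3] + u[0];
        const double ty = aff[4]*x + aff[5]*y0 + aff[6]*z + aff[7] + u[1];
        const double tz = aff[8]*x + aff[9]*y0 + aff[10]*z + aff[11] + u[2];
        const double cx = (tx - morig[0]) / msp[0];
        const double cy = (ty - morig[1]) / msp[1];
        const double cz = (tz - morig[2]) / msp[2];
        bool in;
        const double m = trilinear(mv, md, cx, cy, cz, 0.0, &in);
        if (!in) continue;
        ++nin;
        const double f = fv[idx];
        Rec r;
        for (int ax = 0; ax < 3; ++ax) {
          r.i0[ax] = i0[ax];
          for (int q = 0; q < 4; ++q) r.w[ax][q] = (float)B[ax][q];
        }
        if (want_grad) {
          // central differences in continuous index space, half-voxel step
          bool din;
          const double gx = (trilinear(mv, md, cx + 0.5, cy, cz, m, &din) -
                             trilinear(mv, md, cx - 0.5, cy, cz, m, &din)) / msp[0];
          const double gy = (trilinear(mv, md, cx, cy + 0.5, cz, m, &din) -
                             trilinear(mv, md, cx, cy - 0.5, cz, m, &din)) / msp[1];
          const double gz = (trilinear(mv, md, cx, cy, cz + 0.5, m, &din) -
                             trilinear(mv, md, cx, cy, cz - 0.5, m, &din)) / msp[2];
          r.g[0] = (float)gx; r.g[1] = (float)gy; r.g[2] = (float)gz;
        } else {
          r.g[0] = r.g[1] = r.g[2] = 0.f;
        }
        if (metric == 0) {
          const double dd = m - f;
          ssd += dd * dd;
          r.dfdm_aux = (float)dd;
          r.fb = r.mb = 0; r.frac = r.ffrac = 0.f; r.interior = false;
        } else {
          int mb, fb; double mfrac, ffrac; bool mint, fint;
          pv_bins(m, range[2], range[3], bins, &mb, &mfrac, &mint);
          pv_bins(f, range[0], range[1], bins, &fb, &ffrac, &fint);
          hist.add(fb, mb, (1.0 - ffrac) * (1.0 - mfrac));
          if (mfrac > 0) hist.add(fb, mb + 1, (1.0 - ffrac) * mfrac);
          if (ffrac > 0) {
            hist.add(fb + 1, mb, ffrac * (1.0 - mfrac));
            if (mfrac > 0) hist.add(fb + 1, mb + 1, ffrac * mfrac);
          }
          r.fb = fb; r.mb = mb; r.frac = (float)mfrac;
          r.ffrac = (float)ffrac; r.interior = mint;
        }
        if (want_grad) recs.push_back(r);
      }
    }
  }

  double cost;
  std::vector<double> logterm; // log(p/(pf pm)) per joint cell (MI)
  if (metric == 0) {
    cost = nin > 0 ? ssd / nin : R_PosInf;
  } else {
    cost = -hist.mi();
    if (want_grad && nin > 0) {
      logterm.assign((size_t)bins * bins, 0.0);
      std::vector<double> pf(bins, 0.0), pm(bins, 0.0);
      for (int mb = 0; mb < bins; ++mb)
        for (int fb = 0; fb < bins; ++fb) {
          const double p = hist.joint[fb + (size_t)bins * mb] / hist.n;
          pf[fb] += p; pm[mb] += p;
        }
      for (int mb = 0; mb < bins; ++mb)
        for (int fb = 0; fb < bins; ++fb) {
          const double p = hist.joint[fb + (size_t)bins * mb] / hist.n;
          logterm[fb + (size_t)bins * mb] =
            (p > 0 && pf[fb] > 0 && pm[mb] > 0)
              ? std::log(p / (pf[fb] * pm[mb])) : 0.0;
        }
    }
  }

  NumericMatrix grad(want_grad ? d.nrow() : 1, 3);
  double *gp = REAL(grad);
  const R_xlen_t gn = grad.nrow();
  if (want_grad && nin > 0) {
    const double binw_m = (range[3] - range[2]) / (bins > 0 ? bins : 1);
    for (const Rec &r : recs) {
      double dcdm;
      if (metric == 0) {
        dcdm = 2.0 * r.dfdm_aux / (double)nin;
      } else {
        if (!r.interior) continue;
        // cost = -MI; d(-MI)/dm, weighted over the two fixed-side bins
        const double wf0 = 1.0 - r.ffrac, wf1 = r.ffrac;
        double dmi = wf0 * (logterm[r.fb + (size_t)hist.bins * (r.mb + 1)] -
                            logterm[r.fb + (size_t)hist.bins * r.mb]);
        if (wf1 > 0)
          dmi += wf1 * (logterm[r.fb + 1 + (size_t)hist.bins * (r.mb + 1)] -
                        logterm[r.fb + 1 + (size_t)hist.bins * r.mb]);
        dcdm = -dmi / (binw_m * hist.n);
      }
      const double sx = dcdm * r.g[0], sy = dcdm * r.g[1], sz = dcdm * r.g[2];
      for (int nk = 0; nk < 4; ++nk)
        for (int nj = 0; nj < 4; ++nj) {
          const double wjk = (double)r.w[1][nj] * r.w[2][nk];
          const R_xlen_t base = (R_xlen_t)r.i0[0] +
            (R_xlen_t)Kx * (r.i0[1] + nj) + (R_xlen_t)Kx * Ky * (r.i0[2] + nk);
          for (int ni = 0; ni < 4; ++ni) {
            const double w = (double)r.w[0][ni] * wjk;
            gp[base + ni] += w * sx;
            gp[base + ni + gn] += w * sy;
            gp[base + ni + 2 * gn] += w * sz;
          }
        }
    }
  }

  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  return List::create(_["cost"] = cost,
                      _["grad"] = grad,
                      _["overlap"] = ntot > 0 ? (double)nin / ntot : 0.0,
                      _["n"] = (double)nin);
}
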