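#include "ssmseg_common.h"
using namespace Rcpp;

namespace {

// Raw intensities at 2k+3 positions along +-normal, 1 step apart, with the
// sample points clamped to the volume domain (edge-clamped sampling).
inline void raw_profile(const double *vox, const int *dim,
                        const double *sp, const double *orig,
                        double px, double py, double pz,
                        double nx, double ny, double nz,
                        double step, int k, double *raw) {
  const int L = 2 * k + 3;
  for (int t = 0; t < L; ++t) {
    const double off = (t - (k + 1)) * step;
    double cx = (px + off * nx - orig[0]) / sp[0];
    double cy = (py + off * ny - orig[1]) / sp[1];
    double cz = (pz + off * nz - orig[2]) / sp[2];
    cx = std::min(std::max(cx, 0.0), dim[0] - 1.0);
    cy = std::min(std::max(cy, 0.0), dim[1] - 1.0);
    cz = std::min(std::max(cz, 0.0), dim[2] - 1.0);
    raw[t] = trilinear(vox, dim, cx, cy, cz, 0.0, nullptr);
  }
}

// Normalized central-difference profile of length 2k+1 from raw samples.
inline void deriv_profile(const double *raw, int k, double *g) {
  const int L = 2 * k + 1;
  double s = 0.0;
  for (int j = 0; j < L; ++j) {
    g[j] = 0.5 * (raw[j + 2] - raw[j]);
    s += std::fabs(g[j]);
  }
  if (s > 1e-12)
    for (int j = 0; j < L; ++j) g[j] /= s;
  else
    for (int j = 0; j < L; ++j) g[j] = 0.0;
}

} // namespace

// Normalized derivative profiles at each landmark (rows of pts) along its
// unit normal; length 2k+1, sampling step `step` mm.
// [[Rcpp::export]]
NumericMatrix cpp_sample_profiles(NumericVector vox, IntegerVector dim,
                                  NumericVector spacing, NumericVector origin,
                                  NumericMatrix pts, NumericMatrix normals,
                                  int k, double step) {
  const int n = pts.nrow(), L = 2 * k + 1;
  NumericMatrix out(n, L);
  std::vector<double> raw(2 * k + 3), g(L);
  for (int p = 0; p < n; ++p) {
    raw_profile(REAL(vox), INTEGER(dim), REAL(spacing), REAL(origin),
                pts(p,0), pts(p,1), pts(p,2),
                normals(p,0), normals(p,1), normals(p,2), step, k, raw.data());
    deriv_profile(raw.data(), k, g.data());
    for (int j = 0; j < L; ++j) out(p, j) = g[j];
  }
  return out;
}

// Mahalanobis profile scores for every landmark at every candidate offset
// along the normal: score(p,o) = (g - gbar_p)' Sinv_p (g - gbar_p).
// invcov is landmark-major flat storage of the L x L inverse covariances.
// [[Rcpp::export]]
NumericMatrix cpp_classic_search(NumericVector vox, IntegerVector dim,
                                 NumericVector spacing, NumericVector origin,
                                 NumericMatrix pts, NumericMatrix normals,
                                 NumericVector offsets, int k, double step,
                                 NumericMatrix meanprof, NumericVector invcov) {
  const int n = pts.nrow(), L = 2 * k + 1, no = offsets.size();
  NumericMatrix out(n, no);
  std::vector<double> raw(2 * k + 3), g(L), dlt(L);
  for (int p = 0; p < n; ++p) {
    const double *Si = REAL(invcov) + (R_xlen_t)p * L * L;
    for (int o = 0; o < no; ++o) {
      const double off = offsets[o];
      raw_profile(REAL(vox), INTEGER(dim), REAL(spacing), REAL(origin),
                  pts(p,0) + off * normals(p,0),
                  pts(p,1) + off * normals(p,1),
                  pts(p,2) + off * normals(p,2),
                  normals(p,0), normals(p,1), normals(p,2), step, k, raw.data());
      deriv_profile(raw.data(), k, g.data());
      for (int j = 0; j < L; ++j) dlt[j] = g[j] - meanprof(p, j);
      double acc = 0.0;
      for (int a = 0; a < L; ++a) {
        double row = 0.0;
        for (int b = 0; b < L; ++b) row += Si[a + (R_xlen_t)L * b] * dlt[b];
        acc += dlt[a] * row;
      }
      out(p, o) = acc;
    }
  }
  return out;
}

// Per-position gray-level features for the optimal-feature classifier:
// at each of the 2k+1 profile positions, (I[-1], I[0], I[+1], dI-, dI+)
// from the raw (unnormalized) samples.
// Rows ordered landmark-major: (landmark 0: positions 0..2k), (landmark 1: ...)
// [[Rcpp::export]]
NumericMatrix cpp_profile_features(NumericVector vox, IntegerVector dim,
                                   NumericVector spacing, NumericVector origin,
                                   NumericMatrix pts, NumericMatrix normals,
                                   int k, double step) {
  const int n = pts.nrow(), L = 2 * k + 1;
  NumericMatrix out((R_xlen_t)n * L, 5);
  std::vector<double> raw(2 * k + 3);
  for (int p = 0; p < n; ++p) {
    raw_profile(REAL(vox), INTEGER(dim), REAL(spacing), REAL(origin),
                pts(p,0), pts(p,1), pts(p,2),
                normals(p,0), normals(p,1), normals(p,2), step, k, raw.data());
    for (int j = 0; j < L; ++j) {
      const R_xlen_t r = (R_xlen_t)p * L + j;
      out(r, 0) = raw[j];
      out(r, 1) = raw[j + 1];
      out(r, 2) = raw[j + 2];
      out(r, 3) = raw[j + 1] - raw[j];
      out(r, 4) = raw[j + 2] - raw[j + 1];
    }
  }
  return out;
}

// Optimal-feature search: for each landmark and candidate offset, classify
// every profile position with a per-landmark brute-force kNN on the training
// features and score the deviation from the ideal half-inside/half-outside
// pattern (inside on the negative-normal side).  Lower is better.
// train_start: per-landmark 0-based start rows into train_feat (length n+1);
// train_lab: 1 = inside, 0 = outside.
// [[Rcpp::export]]
NumericMatrix cpp_knn_search(NumericVector vox, IntegerVector dim,
                             NumericVector spacing, NumericVector origin,
                             NumericMatrix pts, NumericMatrix normals,
                             NumericVector offsets, int k, double step,
                             NumericMatrix train_feat, IntegerVector train_lab,
                             IntegerVector train_start, int kn,
                             NumericVector feat_center,
                             NumericVector feat_scale) {
  const int n = pts.nrow(), L = 2 * k + 1, no = offsets.size();
  NumericMatrix out(n, no);
  std::vector<double> raw(2 * k + 3);
  std::vector<std::pair<double,int>> dists;
  for (int p = 0; p < n; ++p) {
    const int t0 = train_start[p], t1 = train_start[p + 1];
    const int nt = t1 - t0;
    if (nt < 1) stop("landmark with no training samples");
    const int kuse = std::min(kn, nt);
    for (int o = 0; o < no; ++o) {
      const double off = offsets[o];
      raw_profile(REAL(vox), INTEGER(dim), REAL(spacing), REAL(origin),
                  pts(p,0) + off * normals(p,0),
                  pts(p,1) + off * normals(p,1),
                  pts(p,2) + off * normals(p,2),
                  normals(p,0), normals(p,1), normals(p,2), step, k, raw.data());
      double score = 0.0;
      for (int j = 0; j < L; ++j) {
        double feat[5] = {raw[j], raw[j + 1], raw[j + 2],
                          raw[j + 1] - raw[j], raw[j + 2] - raw[j + 1]};
        for (int q = 0; q < 5; ++q)
          feat[q] = (feat[q] - feat_center[q]) / feat_scale[q];
        dists.clear();
        dists.reserve(nt);
        for (int t = t0; t < t1; ++t) {
          double d2 = 0.0;
          for (int q = 0; q < 5; ++q) {
            const double dd = feat[q] - train_feat(t, q);
            d2 += dd * dd;
          }
          dists.emplace_back(d2, (int)train_lab[t]);
        }
        std::partial_sort(dists.begin(), dists.begin() + kuse, dists.end());
        // distance-weighted vote: smoother probabilities than a plain count
        double pin = 0.0, wsum = 0.0;
        for (int q = 0; q < kuse; ++q) {
          const double w = 1.0 / (dists[q].first + 1e-6);
          pin += w * dists[q].second;
          wsum += w;
        }
        pin /= wsum;
        const double ideal = j < k ? 1.0 : (j > k ? 0.0 : 0.5);
        score += (pin - ideal) * (pin - ideal);
      }
      out(p, o) = score;
    }
  }
  return out;
}
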