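#include "ssmseg_common.h"
using namespace Rcpp;

// Voxelize a closed triangle mesh: voxel = 1 iff its center lies inside the
// surface, decided by x-ray crossing parity.  Rays are jittered by a tiny
// irrational offset in y/z so they never hit edges/vertices exactly.
// Returns the mask and the number of rays with odd crossing parity (a
// diagnostic for non-closed or self-intersecting input).
// [[Rcpp::export]]
List cpp_voxelize_mesh(NumericMatrix vertices, IntegerMatrix faces,
                       IntegerVector dim, NumericVector spacing,
                       NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nf = faces.nrow();
  IntegerVector mask((R_xlen_t)nx * ny * nz);
  const double jy = 0.5 * spacing[1] * 1.23456789e-4;
  const double jz = 0.5 * spacing[2] * 2.34567891e-4;

  // bucket triangles by (j,k) ray cells covered by their y/z bbox
  std::vector<std::vector<int>> bucket((size_t)ny * nz);
  for (int f = 0; f < nf; ++f) {
    double ylo = R_PosInf, yhi = R_NegInf, zlo = R_PosInf, zhi = R_NegInf;
    for (int c = 0; c < 3; ++c) {
      const int v = faces(f, c);
      ylo = std::min(ylo, vertices(v, 1)); yhi = std::max(yhi, vertices(v, 1));
      zlo = std::min(zlo, vertices(v, 2)); zhi = std::max(zhi, vertices(v, 2));
    }
    int j0 = (int)std::ceil((ylo - jy - origin[1]) / spacing[1] - 1e-9);
    int j1 = (int)std::floor((yhi - jy - origin[1]) / spacing[1] + 1e-9);
    int k0 = (int)std::ceil((zlo - jz - origin[2]) / spacing[2] - 1e-9);
    int k1 = (int)std::floor((zhi - jz - origin[2]) / spacing[2] + 1e-9);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    k0 = std::max(k0, 0); k1 = std::min(k1, nz - 1);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        bucket[(size_t)j + (size_t)ny * k].push_back(f);
  }

  int n_odd = 0;
  std::vector<double> xs;
  for (int k = 0; k < nz; ++k) {
    const double rz = origin[2] + k * spacing[2] + jz;
    for (int j = 0; j < ny; ++j) {
      const double ry = origin[1] + j * spacing[1] + jy;
      const std::vector<int> &tris = bucket[(size_t)j + (size_t)ny * k];
      if (tris.empty()) continue;
      xs.clear();
      for (int f : tris) {
        const int a = faces(f, 0), b = faces(f, 1), c = faces(f, 2);
        const double e1y = vertices(b,1) - vertices(a,1), e1z = vertices(b,2) - vertices(a,2);
        const double e2y = vertices(c,1) - vertices(a,1), e2z = vertices(c,2) - vertices(a,2);
        const double det = e1y * e2z - e2y * e1z;
        if (std::fabs(det) < 1e-14) continue;
        const double py = ry - vertices(a,1), pz = rz - vertices(a,2);
        const double u = (py * e2z - e2y * pz) / det;
        const double v = (e1y * pz - py * e1z) / det;
        if (u < 0 || v < 0 || u + v > 1) continue;
        xs.push_back(vertices(a,0) + u * (vertices(b,0) - vertices(a,0)) +
                     v * (vertices(c,0) - vertices(a,0)));
      }
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      if (xs.size() % 2 == 1) { ++n_odd; continue; }
      for (size_t q = 0; q + 1 < xs.size(); q += 2) {
        int i0 = (int)std::ceil((xs[q] - origin[0]) / spacing[0]);
        int i1 = (int)std::floor((xs[q + 1] - origin[0]) / spacing[0]);
        i0 = std::max(i0, 0); i1 = std::min(i1, nx - 1);
        for (int i = i0; i <= i1; ++i)
          mask[(R_xlen_t)i + (R_xlen_t)nx * j + (R_xlen_t)nx * ny * k] = 1;
      }
    }
  }
  return List::create(_["mask"] = mask, _["n_odd_rays"] = n_odd);
}

// Foreground voxels with at least one background 6-neighbor (outside the
// grid counts as background).
// [[Rcpp::export]]
LogicalVector cpp_boundary_voxels(IntegerVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(mask.size());
  const int *m = INTEGER(mask);
  R_xlen_t idx = 0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        if (!m[idx]) continue;
        bool b =
          (i == 0      || !m[idx - sx]) || (i == nx - 1 || !m[idx + sx]) ||
          (j == 0      || !m[idx - sy]) || (j == ny - 1 || !m[idx + sy]) ||
          (k == 0      || !m[idx - sz]) || (k == nz - 1 || !m[idx + sz]);
        out[idx] = b;
      }
  return out;
}

// For each row of A, the exact Euclidean distance to the nearest row of B.
// Plane-sweep on x with pruning; exact (matches the brute-force minimum).
// [[Rcpp::export]]
NumericVector cpp_closest_dists(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  if (nb == 0) stop("empty point set");
  std::vector<int> ord(nb);
  for (int i = 0; i < nb; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return B(a,0) < B(b,0); });
  std::vector<double> bx(nb), by(nb), bz(nb);
  for (int i = 0; i < nb; ++i) {
    bx[i] = B(ord[i], 0); by[i] = B(ord[i], 1); bz[i] = B(ord[i], 2);
  }
  NumericVector out(na);
  for (int p = 0; p < na; ++p) {
    const double ax = A(p,0), ay = A(p,1), az = A(p,2);
    int lo = (int)(std::lower_bound(bx.begin(), bx.end(), ax) - bx.begin());
    double best = R_PosInf;
    int l = lo - 1, r = lo;
    while (l >= 0 || r < nb) {
      // advance the side whose x-gap is smaller
      bool take_r;
      if (l < 0) take_r = true;
      else if (r >= nb) take_r = false;
      else take_r = (ax - bx[l]) > (bx[r] - ax);
      const int q = take_r ? r : l;
      const double dx = bx[q] - ax;
      if (dx * dx >= best) {
        if (take_r) { r = nb; if (l < 0 || (ax-bx[l])*(ax-bx[l]) >= best) break; }
        else { l = -1; if (r >= nb || (bx[r]-ax)*(bx[r]-ax) >= best) break; }
        continue;
      }
      const double dy = by[q] - ay, dz = bz[q] - az;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
      if (take_r) ++r; else --l;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}
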