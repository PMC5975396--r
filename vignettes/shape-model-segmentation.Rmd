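---
title: "Shape-model segmentation of 3D volumes: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-model segmentation of 3D volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ssmseg` segments a smooth organ in a 3D scalar volume with three tiers of
shape prior, ordered by how much anatomical knowledge they encode:

1. **Single-atlas propagation.** One labeled image (the atlas) is registered
   to the target — a 7-parameter similarity transform first, then a cubic
   B-spline free-form deformation (FFD) — and its mask is resampled through
   the resulting transform.
2. **Active Shape Models (ASM).** A point distribution model (PDM) built by
   Procrustes alignment and PCA of corresponding landmarks is deformed
   iteratively: each landmark searches along its surface normal for the best
   match to a trained gray-profile model, then pose and shape coefficients
   are re-fit and clamped.
3. **Gaussian Process Morphable Models (GPMM).** Deformations `u` of a
   reference surface are a Gaussian process `u ~ GP(mu, k)` with a
   matrix-valued kernel, used through the low-rank Karhunen-Loeve (KL)
   expansion `u = mu + sum_i alpha_i sqrt(lambda_i) phi_i`.  Analytic
   (Gaussian) kernels give smooth priors for establishing correspondence;
   the empirical mean and covariance of the resulting training deformation
   fields define the statistical shape model used for segmentation.

All quality numbers come from three measures: Dice overlap (percent), the
symmetric mean surface distance (mm), and the Hausdorff distance (mm).

## The deformation models

**FFD.** The displacement at a point is a tensor product of uniform cubic
B-splines over the 4x4x4 neighborhood of control points,
`T(x) = sum_{l,m,n} B_l(u_x) B_m(u_y) B_n(u_z) d_{i+l, j+m, k+n}`.
The lattice is padded by one control spacing beyond the image so every voxel
has full support; the basis functions sum to one, so a constant control
displacement reproduces itself exactly (both are tested to 1e-12).
Registration minimizes either the mean squared intensity difference (SSD) or
negated mutual information (MI) from a 32-bin joint histogram with
intensities clamped to their 1st-99th percentile range.  The moving
intensity is spread linearly over adjacent bins (partial-volume binning), so
MI is differentiable in the control displacements; both costs are optimized
by gradient descent with step halving, coarse to fine over resolution
factors 0.25/0.5/1.  The similarity stage optimizes 3 Euler angles, 3
translations and log-scale with L-BFGS and numerical gradients, initialized
from the intensity centroids.

**PDM.** Shapes are `n x 3` landmark matrices in correspondence.  Generalized
Procrustes alignment (similarity transforms, reflections excluded, mean
normalized to unit Frobenius norm) precedes PCA.  The covariance uses the
`1/N` normalization; the empirical GP below uses `1/(N-1)` — both follow
their respective standard forms and each is tested against a direct
double-loop evaluation.  When `n*d > N` the eigenproblem is solved on the
`N x N` Gram matrix and mapped back, so models with tens of thousands of
landmarks remain tractable.  Mode signs are fixed (largest-magnitude
component positive) for reproducibility across linear-algebra backends.

**Gray profiles.** At each landmark, intensities are sampled at one-voxel
steps along the outward normal, differentiated centrally, and normalized by
the sum of absolute differences.  "Profile length 8 pixels" is read as
half-length `k = 4` (9 derivative samples); a config switch selects the
total-length reading.  The classic search minimizes the Mahalanobis distance
`(g - gbar)' S^-1 (g - gbar)` over 6 candidate offsets (the covariance is
regularized by `eps*I`, `eps = 1e-6 * trace/length`).  A symmetric set of 6
integer offsets cannot contain the current position, which must be a fixed
point when the image already matches the model; the offsets therefore run
from `-ceil((n-1)/2)` to `floor((n-1)/2)` — one step asymmetric for even
counts, always containing 0.  The best offset is refined to sub-voxel
precision by a parabola through the scores of its two neighbors (clamped to
half a step), the usual remedy for the half-voxel jitter a discrete search
leaves behind.

**Optimal-feature variant.** Instead of the Mahalanobis cost, a k-nearest-
neighbour classifier estimates, for each profile position, the probability
of being inside the organ (distance-weighted votes); the chosen offset
minimizes the squared deviation from the ideal half-inside/half-outside
pattern.  Features are the raw
intensities in a 3-sample window plus their first differences, globally
z-standardized per resolution level so both feature groups contribute
comparably to the distance.  With 10 training cases each landmark has about
80 labeled samples; `k = 11` follows the square-root-of-sample-size
heuristic.  Pilot runs showed `k = 5` to be noise-limited (the variant fell
below single-atlas accuracy on phantoms), while `k` between 11 and 21
performs equivalently.

**GPMM.** The shipped kernels are isotropic Gaussians
`k(x, y) = s exp(-||x-y||^2 / sigma^2) I3` (closed under addition and
positive scaling), so each scalar eigenfunction of the vertex Gram matrix
yields three basis fields sharing an eigenvalue.  The KL basis is computed
densely for small references and by the Nystrom approximation on `m`
uniformly sampled vertices otherwise; the stored inducing points let the
same expansion be evaluated at arbitrary points, which is how one set of
deformation coefficients defines consistent fields at several mesh
resolutions.  Correspondence between the reference and a training surface
minimizes the symmetric mean closest-point distance over the KL
coefficients: a gradient-free coordinate descent with step shrinking runs
first, followed by an iterated closest-point projection (match each
deformed vertex to its nearest target vertex, ridge-project the implied
field onto the KL basis).  The projection phase was added after the
coordinate descent alone proved prone to ICP-type local minima — on in-span
targets the combined optimizer recovers the true coefficients to numerical
precision, which coordinate steps alone do not achieve.  Segmentation of a
new case draws whole-shape candidates from the deformation distribution
around the current best state (perturbation scale annealed from 1 to 0.1
mode standard deviations), scores each by the summed per-vertex profile
Mahalanobis distance, keeps the best, and finishes with coordinate
pattern-search sweeps over the coefficients; every accepted state lies in
the model span by construction.

## The phantom generator

Real abdominal CT with expert liver outlines is not redistributable at this
scale, so the package ships a seeded generator of organ phantoms with known
ground truth.  The reference organ is a deterministic superellipsoid
(semi-axes 38/30/26 mm, exponent 2.5) with two Gaussian lobe bulges — smooth,
closed, genus 0, and asymmetric so registration cannot exploit accidental
symmetries.  Per-subject shape variation is drawn from a known rank-5
Gaussian-process deformation model (Gaussian kernel, bandwidth 0.35 x organ
diameter, fields scaled so the RMS vertex displacement is 6 percent of the
diameter).  Each case is voxelized on a 64^3 grid at 2 mm spacing
(ray-crossing parity; inconsistent cases are regenerated from the next
draws), rendered with interior mean 100 and exterior 0 (soft-tissue-like
CT contrast), additive Gaussian noise (sd 15), and a 1.5 mm Gaussian
smoothing that mimics partial-volume blur.

What the phantoms deliberately do **not** emulate: neighboring organs of
similar intensity, anisotropic slice spacing, contrast phases, breathing
motion, or deformations outside the generating GP span.  Passing phantom
tests therefore demonstrates correctness of the machinery (formulas,
optimizers, metrics, reproducibility) and the relative behavior of the
methods under controlled conditions — not clinical-grade accuracy on real
CT, where all absolute scores would be substantially lower.

## The comparison experiment

`run_experiment()` generates a cohort of 20 phantoms, splits it 10/10
(seeded shuffle), trains every requested method on the training split, and
scores each test case.  Defaults chosen once for desk-scale runtimes:
registration at levels 0.25/0.5/1 with per-level iteration caps 30/15/8, a
28 mm control spacing, and a minimum overlap fraction of 0.5 (volumes of one
cohort share a grid, and plain SSD otherwise has a spurious minimum where
the organ slides out of the overlap and only background is compared); ASM
with the multi-resolution schedule above; GPMM with 150 iterations x 15
candidates.  Oracle correspondence (the
generator's own fields, available by construction) is used for model
building, isolating model and search error from correspondence error; the
correspondence optimizer is exercised and validated separately.  The
atlas-MI versus atlas-SSD contrast is evaluated on test images passed
through a monotone square-root intensity remap, the regime MI is designed
for.  On this cohort the method ladder lands in the expected order (GPMM
above both ASM variants above single-atlas, MI above SSD under remapping),
with GPMM mean Dice around 98 percent.  Two caveats: phantoms are much
easier than real CT, so the ordering rather than the absolute level is the
meaningful outcome; and all methods sit close to the voxelization ceiling of
the 64^3 grid, which compresses the margins between them relative to what
real anatomical variability produces.

## Numerical choices and edge cases

- Voxel indices are 0-based internally; world position of index `(i,j,k)`
  is `origin + (i,j,k) * spacing` (node-centered).  The first array axis is
  x, as in MetaImage; NIfTI orientation beyond axis-aligned scaling is
  rejected.
- Masks are strictly binary; propagation uses nearest-neighbor resampling.
- `mask_to_surface` builds the closed boundary-face surface between
  foreground and background voxels (two triangles per exposed voxel face,
  placed at the 0.5 iso-level between centers; other levels offset vertices
  along their normals).  `surface_to_mask` uses x-ray crossing parity with
  jittered rays; rays with odd parity flag a non-closed surface.
- Surface metrics use boundary voxels (foreground with a background
  6-neighbor) at voxel centers; closest-point queries use an exact sorted
  sweep, unit-tested against the O(n^2) oracle.
- The mean surface distance is the standard symmetric mean
  `(sum_i d_i + sum_j d_j) / (n_X + n_Y)`.
- Degenerate inputs error early: empty masks, constant volumes in
  registration, coincident landmarks in Procrustes, fewer than 2 training
  cases, out-of-support lattice queries (configurable to zero).
- Two empty masks score Dice 100 by the 0/0 convention, with a message.
- Every seeded stage (cohort generation, splits, Nystrom sampling, GPMM
  candidates) is reproducible bit-for-bit given its seed; optimizers are
  deterministic.

## Known limitations

- Registration is not diffeomorphic and not inverse-consistent; large or
  folding deformations are out of scope.
- Only Gaussian (and sums of Gaussian) kernels ship; the kernel interface
  accepts others.
- GPMM fitting resamples the prior around the incumbent rather than
  updating a posterior after acceptance.
- The CLI `train`/`segment` path assumes the cohort layout written by
  `synth` (corresponding mesh vertices across cases).
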