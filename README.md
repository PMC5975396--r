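# ssmseg — statistical shape-model segmentation of 3D organ volumes

`ssmseg` is an R toolkit for segmenting a smooth organ (the motivating case
is the liver in abdominal CT) from 3D scalar volumes using three tiers of
shape prior, plus everything needed to compare them reproducibly:

- **Single-atlas propagation** — similarity registration (3 rotations, 3
  translations, isotropic scale) followed by cubic B-spline free-form
  deformation (FFD), driven by sum-of-squared-differences (SSD) or mutual
  information (MI); the atlas mask is propagated through the optimized
  transform.  The FFD displacement is the classic tensor-product form
  `T(x) = Σ_l Σ_m Σ_n B_l(μ_x) B_m(μ_y) B_n(μ_z) d_{i+l, j+m, k+n}` over a
  padded control lattice.
- **Active Shape Models** — a point distribution model (Procrustes
  alignment, PCA: mean shape `X̄`, modes `P`, variances `λ`, synthesis
  `s = X̄ + P b` with `|b_i| ≤ 3 √λ_i`) searched along landmark normals with
  either the classic Mahalanobis gray-profile cost
  `(g − ḡ)ᵀ S_g⁻¹ (g − ḡ)` or an optimal-feature k-nearest-neighbour
  boundary classifier, coarse to fine at resolutions 0.25 / 0.5 / 1 with 5
  iterations per level.
- **Gaussian Process Morphable Models** — surface deformations
  `u ~ GP(μ, k)` in low-rank Karhunen–Loève form
  `u = μ + Σ_i α_i √λ_i φ_i` (Nyström approximation for large references);
  GP-regularized correspondence; empirical deformation statistics
  `μ_SM(X) = (1/N) Σ u_i(X)`,
  `k_SM(X,Y) = (1/(N−1)) Σ (u_i(X) − μ_SM(X))(u_i(Y) − μ_SM(Y))ᵀ`;
  segmentation by stochastic whole-shape candidate search scored with the
  profile Mahalanobis cost.

Quality is reported as Dice overlap (percent), symmetric mean surface
distance (mm) and Hausdorff distance (mm).  Because public CT benchmarks
cannot ship with the package, a seeded phantom generator produces CT-like
organ volumes with known ground truth (shapes drawn from a known
Gaussian-process deformation model) on which the whole method ladder runs at
desk scale.

Supported formats: MetaImage (`.mhd`/`.mha` + raw) and NIfTI-1 volumes,
PLY (ascii/binary) and legacy VTK polydata meshes, JSON transforms, CSV
reports, YAML experiment configs.

## Worked example

Generate a small phantom cohort, segment one case with the single-atlas
method, and score it:

```r
library(ssmseg)

cohort <- generate_cohort(phantom_spec(seed = 11), 6)
atlas  <- atlas_case(cohort$cases[[1]]$image, cohort$cases[[1]]$mask)
target <- cohort$cases[[5]]$image

seg <- segment_single_atlas(atlas, target, metric = "ssd",
                            registration_config(metric = "ssd",
                                                max_iter = c(30, 15, 8),
                                                grid_spacing_mm = 28))
evaluate_case(seg$mask, cohort$cases[[5]]$mask, "case005")
#>   case_id dice_percent    msd_mm hausdorff_mm
#> 1 case005     97.94345 0.4882139            2
```

A Dice of 97.9 % means the propagated and true masks overlap almost
completely; the mean surface distance of 0.49 mm (about a quarter voxel) and
the 2 mm (one-voxel) Hausdorff worst case quantify the residual boundary
error.

The full five-method comparison (20 phantoms, 10 train / 10 test, fixed
seed) is one call:

```r
res <- run_experiment(experiment_config(spec = phantom_spec(seed = 1), seed = 1))
res$summary
#>        method dice_percent    msd_mm hausdorff_mm n_cases
#> 1   atlas-ssd     98.00080 0.4762249     2.000000      10
#> 2    atlas-mi     97.56444 0.5735910     2.579899      10
#> 3 asm-classic     98.33044 0.4067431     2.248528      10
#> 4     asm-knn     98.43191 0.3820217     2.248528      10
#> 5        gpmm     98.48193 0.3698690     2.165685      10
```

The ladder lands in the expected order — the GPMM above both ASM variants,
both above single-atlas propagation — and with a monotone intensity remap of
the test images (`remap_test = TRUE`) the MI-driven atlas (97.4 %) beats the
SSD-driven one (68.4 %) by a wide margin, the regime mutual information
exists for.
Phantoms are far easier than clinical CT, so the ordering rather than the
absolute level is the informative outcome; see the vignette
(`vignettes/shape-model-segmentation.Rmd`) for what the phantoms do and do
not emulate.

## Command line

A thin CLI wraps the same functions (see `inst/cli/ssmseg`):

```sh
Rscript inst/cli/ssmseg synth --spec spec.yaml --n 20 --out cohort/
Rscript inst/cli/ssmseg train --method gpmm --cohort cohort/ --cases 1,2,3,4,5 --out model/
Rscript inst/cli/ssmseg segment --method gpmm --model model/ --target cohort/case006_image.mhd --out seg.mhd
Rscript inst/cli/ssmseg evaluate --pred seg.mhd --ref cohort/case006_mask.mhd --out report.csv
Rscript inst/cli/ssmseg experiment --config config.yaml --out results/
```

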