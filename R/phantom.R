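#' Deterministic liver-like reference organ surface
#'
#' A smooth, asymmetric, closed genus-0 surface: a superellipsoid radial
#' profile with two Gaussian lobe bulges, triangulated as a UV sphere with
#' approximately `n_vertices` vertices.  Coordinates are mm, centered at
#' the origin; faces wind outward.
#'
#' @param n_vertices requested vertex count (>= 100).
#' @return a [surface_mesh()].
#' @export
make_reference_organ <- function(n_vertices = 1000L) {
  if (n_vertices < 100L) stop("reference organ needs at least 100 vertices")
  nt <- max(3L, round(sqrt((n_vertices - 2) / 2)))
  np <- max(3L, ceiling((n_vertices - 2) / nt))
  theta <- pi * seq_len(nt) / (nt + 1)
  phi <- 2 * pi * (seq_len(np) - 1) / np
  tt <- rep(theta, each = np) # ring-major layout: phi varies fastest
  pp <- rep(phi, nt)
  dirs <- rbind(c(0, 0, 1),
                c(0, 0, -1),
                cbind(sin(tt) * cos(pp), sin(tt) * sin(pp), cos(tt)))
  # superellipsoid radius with two lobes; semi-axes and bumps give an
  # asymmetric organ roughly 90 x 70 x 60 mm
  radial <- function(d) {
    a <- c(38, 30, 26)
    p <- 2.5
    rse <- (abs(d[, 1] / a[1])^p + abs(d[, 2] / a[2])^p +
              abs(d[, 3] / a[3])^p)^(-1 / p)
    u1 <- c(1, 0.35, 0.25); u1 <- u1 / sqrt(sum(u1^2))
    u2 <- c(-0.55, 0.75, -0.35); u2 <- u2 / sqrt(sum(u2^2))
    ang1 <- acos(pmin(1, pmax(-1, d %*% u1)))
    ang2 <- acos(pmin(1, pmax(-1, d %*% u2)))
    rse + 8 * exp(-(ang1 / 0.5)^2) + 6 * exp(-(ang2 / 0.45)^2)
  }
  verts <- dirs * as.numeric(radial(dirs))
  vid <- function(i, j) 2L + (i - 1L) * np + ((j - 1L) %% np) + 1L
  faces <- list()
  fn <- 0L
  for (j in seq_len(np)) {
    fn <- fn + 1L; faces[[fn]] <- c(1L, vid(1L, j), vid(1L, j + 1L))
    fn <- fn + 1L; faces[[fn]] <- c(2L, vid(nt, j + 1L), vid(nt, j))
  }
  if (nt > 1L) {
    for (i in seq_len(nt - 1L)) {
      for (j in seq_len(np)) {
        fn <- fn + 1L; faces[[fn]] <- c(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L))
        fn <- fn + 1L; faces[[fn]] <- c(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L))
      }
    }
  }
  mesh <- surface_mesh(verts, do.call(rbind, faces))
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

#' Phantom cohort specification
#'
#' Defaults emulate a CT-like abdominal phantom at desk scale: a 64^3 grid
#' at 2 mm spacing, interior mean 100 (soft-tissue HU), exterior 0,
#' additive Gaussian noise (sd 15), per-subject shape variation drawn from
#' a known rank-5 Gaussian-process deformation model with RMS amplitude 6
#' percent of the organ diameter, and a small partial-volume smoothing.
#'
#' @param grid_dim voxels per axis (scalar or length 3).
#' @param spacing_mm voxel spacing (mm).
#' @param intensity_in,intensity_out interior/exterior mean intensities.
#' @param noise_sd additive noise standard deviation.
#' @param amplitude deformation RMS as a fraction of the organ diameter.
#' @param deformation_rank number of true deformation basis fields.
#' @param kernel_sigma_mm bandwidth of the true deformation kernel
#'   (default 0.35 x organ diameter).
#' @param n_vertices reference mesh resolution.
#' @param smooth_sigma_mm partial-volume smoothing (mm).
#' @param seed RNG seed; a fixed seed makes cohorts byte-reproducible.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dim = 64L, spacing_mm = 2, intensity_in = 100,
                         intensity_out = 0, noise_sd = 15, amplitude = 0.06,
                         deformation_rank = 5L, kernel_sigma_mm = NULL,
                         n_vertices = 1000L, smooth_sigma_mm = 1.5,
                         seed = 1L) {
  if (intensity_in == intensity_out)
    stop("interior and exterior intensities must differ")
  if (amplitude < 0) stop("amplitude must be nonnegative")
  structure(list(grid_dim = rep_len(as.integer(grid_dim), 3L),
                 spacing_mm = rep_len(as.numeric(spacing_mm), 3L),
                 intensity_in = intensity_in, intensity_out = intensity_out,
                 noise_sd = noise_sd, amplitude = amplitude,
                 deformation_rank = as.integer(deformation_rank),
                 kernel_sigma_mm = kernel_sigma_mm,
                 n_vertices = as.integer(n_vertices),
                 smooth_sigma_mm = smooth_sigma_mm,
                 seed = as.integer(seed)), class = "phantom_spec")
}

mesh_diameter <- function(mesh) {
  bb <- apply(mesh$vertices, 2, range)
  sqrt(sum((bb[2, ] - bb[1, ])^2))
}

#' Generate a phantom cohort with known ground truth
#'
#' Per case: deformation coefficients are drawn from a standard normal
#' (seeded stream), the reference organ is deformed through the true
#' low-rank GP, voxelized to the ground-truth mask, and rendered as a
#' CT-like image (interior/exterior means plus noise, Gaussian-smoothed to
#' mimic partial volume).  Cases whose deformed mesh voxelizes
#' inconsistently (odd ray parity, e.g. self-intersection) are regenerated
#' from the next draws of the stream, with a message.
#'
#' @param spec a [phantom_spec()].
#' @param n_cases number of phantoms.
#' @return object of class `phantom_cohort`: `cases` (each with `image`,
#'   `mask`, `mesh`, `true_alpha`), `reference`, `true_gp`, `spec`.
#' @export
generate_cohort <- function(spec, n_cases) {
  stopifnot(inherits(spec, "phantom_spec"), n_cases >= 1)
  ref <- make_reference_organ(spec$n_vertices)
  diam <- mesh_diameter(ref)
  sigma <- if (is.null(spec$kernel_sigma_mm)) 0.35 * diam else spec$kernel_sigma_mm
  gp <- build_low_rank_gp(gaussian_kernel(1, sigma), ref,
                          r = spec$deformation_rank, seed = spec$seed)
  if (spec$amplitude > 0 && sum(gp$variances) > 0) {
    target_rms <- spec$amplitude * diam
    fct <- target_rms^2 * nrow(ref$vertices) / sum(gp$variances)
    gp$variances <- gp$variances * fct
    gp$scalar_values <- gp$scalar_values * fct
  }
  d <- spec$grid_dim
  origin <- -(d - 1) * spec$spacing_mm / 2
  grid <- vol3d(array(0, d), spec$spacing_mm, origin)
  set.seed(spec$seed)
  cases <- vector("list", n_cases)
  for (ci in seq_len(n_cases)) {
    repeat {
      alpha <- stats::rnorm(spec$deformation_rank)
      if (spec$amplitude == 0) alpha <- numeric(spec$deformation_rank)
      field <- sample_deformation(gp, alpha)
      mesh <- surface_mesh(ref$vertices + field, ref$faces)
      vx <- cpp_voxelize_mesh(mesh$vertices, mesh$faces - 1L, d,
                              spec$spacing_mm, origin)
      if (vx$n_odd_rays == 0L) break
      message(sprintf("case %d: inconsistent voxelization, redrawing", ci))
    }
    mask <- label_mask(array(vx$mask, d), spec$spacing_mm, origin)
    base <- ifelse(mask$voxels == 1L, spec$intensity_in, spec$intensity_out)
    noisy <- base + stats::rnorm(length(base), sd = spec$noise_sd)
    img <- vol3d(array(noisy, d), spec$spacing_mm, origin)
    if (spec$smooth_sigma_mm > 0) img <- smooth_volume(img, spec$smooth_sigma_mm)
    cases[[ci]] <- structure(list(image = img, mask = mask, mesh = mesh,
                                  true_alpha = alpha, id = sprintf("case%03d", ci)),
                             class = "phantom_case")
  }
  structure(list(cases = cases, reference = ref, true_gp = gp, spec = spec),
            class = "phantom_cohort")
}

#' True correspondence deformation fields of a cohort
#'
#' The oracle correspondence available by construction: the per-case true
#' deformation evaluated at the reference vertices, or (by Nystrom
#' extension of the true GP) at any other point set on the reference
#' surface.
#'
#' @param cohort a [generate_cohort()] result.
#' @param at optional n x 3 points; default the cohort reference vertices.
#' @param cases optional case indices.
#' @return list of n x 3 fields.
#' @export
cohort_true_fields <- function(cohort, at = NULL, cases = NULL) {
  if (is.null(cases)) cases <- seq_along(cohort$cases)
  lapply(cohort$cases[cases], function(cs) {
    if (is.null(at)) cs$mesh$vertices - cohort$reference$vertices
    else sample_deformation_at(cohort$true_gp, cs$true_alpha, at)
  })
}

#' Seeded train/test split of a cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @param n_train training cases (< cohort size).
#' @param seed shuffle seed.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   union = all cases).
#' @export
split_train_test <- function(cohort, n_train, seed = 1L) {
  n <- length(cohort$cases)
  if (n_train < 1 || n_train >= n) stop("n_train must be in [1, n_cases)")
  set.seed(seed)
  perm <- sample.int(n)
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[(n_train + 1):n]))
}
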