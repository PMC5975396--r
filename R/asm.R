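#' Active Shape Model configuration
#'
#' Defaults follow the standard multi-resolution ASM recipe: resolution
#' factors 0.25/0.5/1 with five iterations each, gray profiles of length 8
#' pixels (read as half-length 4, i.e. 9 derivative samples; set
#' `profile_interpretation = "total"` for 7 samples), 6 candidate positions
#' along the normal, and mode coefficients clamped at 3 standard deviations.
#'
#' @param resolutions ascending resolution factors in (0, 1].
#' @param iterations_per_level iterations at each resolution.
#' @param profile_length profile length in pixels.
#' @param profile_interpretation `"half"` (k = length/2 per side) or
#'   `"total"` (k = (length-1)/2).
#' @param candidate_positions candidate offsets evaluated along the normal
#'   (1-voxel steps, includes the current position).
#' @param b_limit shape coefficient clamp, in mode standard deviations.
#' @param knn_k neighbors for the optimal-feature classifier (odd; default
#'   follows the sqrt-of-sample-size heuristic for the ~80 profile samples
#'   per landmark a 10-case training set provides).
#' @return a list of settings of class `asm_config`.
#' @export
asm_config <- function(resolutions = c(0.25, 0.5, 1),
                       iterations_per_level = 5L,
                       profile_length = 8L,
                       profile_interpretation = c("half", "total"),
                       candidate_positions = 6L,
                       b_limit = 3,
                       knn_k = 11L) {
  profile_interpretation <- match.arg(profile_interpretation)
  stopifnot(all(diff(resolutions) > 0), all(resolutions > 0),
            all(resolutions <= 1), iterations_per_level >= 1,
            candidate_positions >= 1, knn_k %% 2 == 1)
  k <- if (profile_interpretation == "half") as.integer(profile_length / 2)
       else as.integer((profile_length - 1) / 2)
  structure(list(resolutions = resolutions,
                 iterations_per_level = as.integer(iterations_per_level),
                 profile_length = as.integer(profile_length),
                 profile_half_length = k,
                 candidate_positions = as.integer(candidate_positions),
                 b_limit = b_limit, knn_k = as.integer(knn_k)),
            class = "asm_config")
}

# candidate offsets in voxel units; contains 0 so the current position is
# always among the candidates (asymmetric by one step for even counts)
candidate_offsets <- function(n) {
  seq.int(-ceiling((n - 1) / 2), floor((n - 1) / 2))
}

#' Sample normalized derivative gray profiles
#'
#' Intensities are sampled at 1-voxel steps along the +-normal direction,
#' differentiated centrally, and normalized by the sum of absolute
#' differences (zero-safe), yielding `2k+1` values per landmark.  Sample
#' points beyond the volume are edge-clamped.
#'
#' @param vol a [vol3d()].
#' @param points n x 3 landmark positions (mm), or a single length-3 point.
#' @param normals matching unit normals.
#' @param half_length k; the profile has `2k+1` samples.
#' @param step_mm sampling step; default one (geometric mean) voxel.
#' @return n x (2k+1) matrix (a vector for a single point).
#' @export
sample_profile <- function(vol, points, normals, half_length = 4L,
                           step_mm = NULL) {
  single <- is.null(dim(points))
  points <- matrix(as.numeric(points), ncol = 3)
  normals <- matrix(as.numeric(normals), ncol = 3)
  nl <- sqrt(rowSums(normals^2))
  if (any(nl < 1e-12)) stop("zero-length normal")
  normals <- normals / nl
  if (is.null(step_mm)) step_mm <- exp(mean(log(vol$spacing)))
  out <- cpp_sample_profiles(as.numeric(vol$voxels), vol_dim(vol),
                             vol$spacing, vol$origin, points, normals,
                             as.integer(half_length), step_mm)
  if (single) as.numeric(out) else out
}

case_normals <- function(points, faces) {
  vertex_normals(surface_mesh(points, faces))
}

#' Build gray-level profile models
#'
#' For each landmark and each resolution level, the mean and covariance of
#' the normalized derivative profiles over the training cases, with the
#' covariance regularized by `eps * I` (`eps = 1e-6 * trace / length`,
#' floored at 1e-8) before inversion.
#'
#' @param volumes list of training [vol3d()] volumes.
#' @param landmarks list of n x 3 landmark matrices in correspondence
#'   (world mm), one per volume.
#' @param faces shared triangulation of the landmarks (for normals); may be
#'   `NULL` when `normals` is given.
#' @param config an [asm_config()].
#' @param normals optional list of per-case n x 3 unit normals overriding
#'   the mesh normals.
#' @return object of class `profile_model`: per level, `mean` (n x L),
#'   `invcov` (flat n*L*L), `step_mm`, plus `k`, `faces`.
#' @export
build_profile_model <- function(volumes, landmarks, faces, config = asm_config(),
                                normals = NULL) {
  if (length(volumes) < 2L) stop("need at least 2 training cases")
  if (length(volumes) != length(landmarks))
    stop("volumes and landmark sets must pair up")
  k <- config$profile_half_length
  L <- 2L * k + 1L
  n <- nrow(landmarks[[1]])
  levels <- vector("list", length(config$resolutions))
  names(levels) <- as.character(config$resolutions)
  for (li in seq_along(config$resolutions)) {
    fac <- config$resolutions[li]
    profs <- array(0, c(n, L, length(volumes)))
    step <- NULL
    for (ci in seq_along(volumes)) {
      vl <- resample_volume(volumes[[ci]], fac)
      if (is.null(step)) step <- exp(mean(log(vl$spacing)))
      nrm <- if (is.null(normals)) case_normals(landmarks[[ci]], faces)
             else normals[[ci]]
      profs[, , ci] <- sample_profile(vl, landmarks[[ci]], nrm, k, step)
    }
    mean_p <- apply(profs, c(1, 2), mean)
    invcov <- numeric(n * L * L)
    for (p in seq_len(n)) {
      P <- t(profs[p, , ]) # cases x L
      S <- crossprod(sweep(P, 2, colMeans(P))) / nrow(P)
      eps <- max(1e-6 * sum(diag(S)) / L, 1e-8)
      Si <- solve(S + diag(eps, L))
      invcov[((p - 1) * L * L + 1):(p * L * L)] <- as.vector(Si)
    }
    levels[[li]] <- list(mean = mean_p, invcov = invcov, step_mm = step,
                         n_cases = length(volumes))
  }
  structure(list(levels = levels, resolutions = config$resolutions,
                 k = k, faces = faces, n = n), class = "profile_model")
}

#' Build the optimal-feature appearance model
#'
#' For every landmark, gray-level feature vectors (raw intensities and
#' first differences in a 3-sample window) are collected at profile
#' positions around the true boundary in each training case and labeled
#' inside (negative-normal side) or outside; the boundary position itself
#' is excluded.  Classification at search time is k-nearest-neighbour.
#'
#' @inheritParams build_profile_model
#' @return object of class `feature_model` with per-level training features.
#' @export
build_feature_model <- function(volumes, landmarks, faces, config = asm_config(),
                                normals = NULL) {
  if (length(volumes) < 2L) stop("need at least 2 training cases")
  k <- config$profile_half_length
  L <- 2L * k + 1L
  n <- nrow(landmarks[[1]])
  levels <- vector("list", length(config$resolutions))
  names(levels) <- as.character(config$resolutions)
  keep <- rep(seq_len(L) != (k + 1L), times = 1) # drop the center position
  lab_one <- as.integer(seq_len(L) <= k)[keep]   # 1 = inside
  for (li in seq_along(config$resolutions)) {
    fac <- config$resolutions[li]
    feats <- vector("list", length(volumes))
    step <- NULL
    for (ci in seq_along(volumes)) {
      vl <- resample_volume(volumes[[ci]], fac)
      if (is.null(step)) step <- exp(mean(log(vl$spacing)))
      nrm <- if (is.null(normals)) case_normals(landmarks[[ci]], faces)
             else normals[[ci]]
      ft <- cpp_profile_features(as.numeric(vl$voxels), vol_dim(vl),
                                 vl$spacing, vl$origin, landmarks[[ci]], nrm,
                                 k, step)
      feats[[ci]] <- ft
    }
    # reorganize landmark-major: rows for landmark p from all cases
    per_lm <- L - 1L
    nt <- per_lm * length(volumes)
    train <- matrix(0, nt * n, 5)
    labs <- integer(nt * n)
    starts <- integer(n + 1L)
    row <- 0L
    for (p in seq_len(n)) {
      starts[p] <- row
      for (ci in seq_along(volumes)) {
        rows_in <- ((p - 1L) * L + 1L):(p * L)
        block <- feats[[ci]][rows_in, , drop = FALSE][keep, , drop = FALSE]
        train[(row + 1L):(row + per_lm), ] <- block
        labs[(row + 1L):(row + per_lm)] <- lab_one
        row <- row + per_lm
      }
    }
    starts[n + 1L] <- row
    # global per-dimension standardization so raw intensities and
    # differences contribute comparably to the kNN distance
    ctr <- colMeans(train)
    scl <- pmax(apply(train, 2, stats::sd), 1e-8)
    train_std <- sweep(sweep(train, 2, ctr), 2, scl, "/")
    levels[[li]] <- list(features = train_std, labels = labs, starts = starts,
                         step_mm = step, feat_center = ctr, feat_scale = scl)
  }
  structure(list(levels = levels, resolutions = config$resolutions,
                 k = k, faces = faces, n = n,
                 knn_k = config$knn_k), class = "feature_model")
}

# shared pose + shape regularization: fit a similarity pose from the model
# mean to the proposed points, project into the mode space, clamp, resynthesize
regularize_shape <- function(pdm, proposed, b_limit) {
  mean_mat <- matrix(pdm$mean_shape, pdm$n, pdm$d)
  fit <- procrustes_fit(mean_mat, proposed)
  # inverse pose: world -> model space (aligned = s * Xc %*% R + centroid(Y))
  inv_pts <- sweep(proposed, 2, colMeans(proposed))
  inv_pts <- (inv_pts %*% t(fit$rotation)) / fit$scale
  inv_pts <- sweep(inv_pts, 2, colMeans(mean_mat), "+")
  b <- project_shape(pdm, inv_pts)
  lim <- b_limit * sqrt(pdm$variances)
  b <- pmin(pmax(b, -lim), lim)
  model_pts <- synthesize_shape(pdm, b)
  mc <- colMeans(model_pts)
  out <- sweep(sweep(model_pts, 2, mc) %*% fit$rotation * fit$scale,
               2, colMeans(proposed), "+")
  list(points = out, b = b, pose = fit)
}

asm_search_step <- function(vl, points, profiles_or_features, pdm, config,
                            variant, level_key) {
  faces <- profiles_or_features$faces
  k <- profiles_or_features$k
  lvl <- profiles_or_features$levels[[level_key]]
  nrm <- case_normals(points, faces)
  offs <- candidate_offsets(config$candidate_positions) * lvl$step_mm
  scores <- if (variant == "classic") {
    cpp_classic_search(as.numeric(vl$voxels), vol_dim(vl), vl$spacing,
                       vl$origin, points, nrm, offs, k, lvl$step_mm,
                       lvl$mean, lvl$invcov)
  } else {
    cpp_knn_search(as.numeric(vl$voxels), vol_dim(vl), vl$spacing,
                   vl$origin, points, nrm, offs, k, lvl$step_mm,
                   lvl$features, lvl$labels, lvl$starts,
                   profiles_or_features$knn_k,
                   lvl$feat_center, lvl$feat_scale)
  }
  bi <- max.col(-scores, ties.method = "first")
  best <- offs[bi]
  # parabolic sub-voxel refinement around interior minima; a perfect match
  # (zero score) at the incumbent is left untouched so it stays a fixed point
  n_off <- length(offs)
  interior <- bi > 1L & bi < n_off
  if (any(interior)) {
    idx <- which(interior)
    s0 <- scores[cbind(idx, bi[idx] - 1L)]
    s1 <- scores[cbind(idx, bi[idx])]
    s2 <- scores[cbind(idx, bi[idx] + 1L)]
    denom <- s0 - 2 * s1 + s2
    delta <- ifelse(denom > 1e-12 & s1 > 1e-12, 0.5 * (s0 - s2) / denom, 0)
    delta <- pmin(pmax(delta, -0.5), 0.5)
    best[idx] <- best[idx] + delta * lvl$step_mm
  }
  points + best * nrm
}

#' One classic ASM update step
#'
#' Each landmark moves to the candidate offset along its normal minimizing
#' the Mahalanobis distance to the mean profile; the result is regularized
#' by a similarity pose fit plus projection onto the clamped mode space.
#'
#' @param vol a [vol3d()] at the resolution the profile model level was
#'   built for.
#' @param shape current n x 3 landmark matrix (world mm).
#' @param pdm the shape model ([build_pdm()]).
#' @param profiles a [build_profile_model()] appearance model.
#' @param config an [asm_config()].
#' @param level resolution level key (default full resolution).
#' @return updated n x 3 landmark matrix.
#' @export
classic_asm_step <- function(vol, shape, pdm, profiles, config = asm_config(),
                             level = as.character(1)) {
  proposed <- asm_search_step(vol, shape, profiles, pdm, config, "classic", level)
  regularize_shape(pdm, proposed, config$b_limit)$points
}

#' One optimal-feature ASM update step
#'
#' Candidate offsets are scored by how well the kNN inside-probabilities of
#' the profile positions match the ideal half-inside/half-outside pattern;
#' the pose/shape update is as in [classic_asm_step()].
#'
#' @inheritParams classic_asm_step
#' @param features a [build_feature_model()] appearance model.
#' @return updated n x 3 landmark matrix.
#' @export
optimal_feature_asm_step <- function(vol, shape, features, pdm,
                                     config = asm_config(),
                                     level = as.character(1)) {
  proposed <- asm_search_step(vol, shape, features, pdm, config, "knn", level)
  regularize_shape(pdm, proposed, config$b_limit)$points
}

#' Fit an Active Shape Model to a volume
#'
#' Multi-resolution search (coarse to fine, a fixed number of iterations
#' per level) starting from `init_shape`; the final landmark mesh is
#' voxelized onto the volume grid.
#'
#' @param vol target [vol3d()].
#' @param pdm shape model.
#' @param appearance [build_profile_model()] or [build_feature_model()]
#'   matching `variant`.
#' @param init_shape initial n x 3 landmarks (world mm).
#' @param config an [asm_config()].
#' @param variant `"classic"` or `"knn"`.
#' @return list with `shape` (landmarks), `mask` ([label_mask()]),
#'   `movement_trace` (mean landmark movement per iteration).
#' @export
fit_asm <- function(vol, pdm, appearance, init_shape, config = asm_config(),
                    variant = c("classic", "knn")) {
  variant <- match.arg(variant)
  ctrs <- voxel_centers(vol, c(1L, prod(vol_dim(vol))))
  if (any(apply(init_shape, 2, min) > ctrs[2, ] ) ||
      any(apply(init_shape, 2, max) < ctrs[1, ]))
    stop("initial shape lies outside the volume")
  points <- init_shape
  trace <- numeric(0)
  for (li in seq_along(config$resolutions)) {
    fac <- config$resolutions[li]
    key <- as.character(fac)
    vl <- resample_volume(vol, fac)
    for (it in seq_len(config$iterations_per_level)) {
      newp <- if (variant == "classic")
        classic_asm_step(vl, points, pdm, appearance, config, key)
      else
        optimal_feature_asm_step(vl, points, appearance, pdm, config, key)
      trace <- c(trace, mean(sqrt(rowSums((newp - points)^2))))
      points <- newp
    }
  }
  mesh <- surface_mesh(points, appearance$faces)
  mask <- surface_to_mask(mesh, vol, tol_frac = 0.05)
  list(shape = points, mask = mask, movement_trace = trace, variant = variant)
}

# crude histogram-valley (Otsu) threshold used for moment initialization
otsu_threshold <- function(v) {
  v <- as.numeric(v)
  h <- graphics::hist(v, breaks = 256, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w1 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sb <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

#' Moment-based initialization of a model shape in a target volume
#'
#' Thresholds the volume (Otsu), then translates and isotropically scales
#' the supplied model-mean landmarks so centroid and cube-root volume match
#' the thresholded foreground.  Rotation is left at identity.
#'
#' @param vol target [vol3d()].
#' @param mean_shape n x 3 model-mean landmarks (world mm).
#' @param faces triangulation of the landmarks.
#' @return list with `shape` (initialized landmarks) and `pose`
#'   ([similarity3d()] from model to volume space).
#' @export
init_shape_moments <- function(vol, mean_shape, faces) {
  thr <- otsu_threshold(vol$voxels)
  fg <- vol$voxels > thr
  if (sum(fg) < 10) stop("initialization failed: thresholded foreground empty")
  ctr_img <- colMeans(voxel_centers(vol, which(fg)))
  vol_img <- sum(fg) * prod(vol$spacing)
  mesh <- surface_mesh(mean_shape, faces)
  vol_model <- abs(mesh_volume(mesh))
  s <- (vol_img / vol_model)^(1 / 3)
  ctr_model <- colMeans(mean_shape)
  pose <- similarity3d(diag(3), ctr_img - ctr_model, s, ctr_model)
  list(shape = apply_transform(pose, mean_shape), pose = pose)
}

#' Signed volume enclosed by a surface mesh
#' @param mesh a closed [surface_mesh()].
#' @return scalar mm^3 (positive for outward-wound surfaces).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}
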