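#' @title Registration cost functions and optimizers
#' @description Intensity-based similarity and B-spline free-form-deformation
#'   registration.  Two cost functions are provided: mean squared intensity
#'   difference (SSD) and negated mutual information (MI) from a joint
#'   intensity histogram; both are evaluated over the overlap of the fixed
#'   grid with the transformed moving volume.
#' @name registration
NULL

# 1st-99th percentile intensity range used to clamp the MI histograms
mi_range <- function(fixed, moving, probs = c(0.01, 0.99)) {
  qf <- stats::quantile(fixed$voxels, probs, names = FALSE)
  qm <- stats::quantile(moving$voxels, probs, names = FALSE)
  if (qf[2] <= qf[1]) qf[2] <- qf[1] + 1
  if (qm[2] <= qm[1]) qm[2] <- qm[1] + 1
  c(qf, qm)
}

transform_parts <- function(transform) {
  if (inherits(transform, "similarity3d"))
    list(affine = as_affine(transform), grid = NULL)
  else if (inherits(transform, "bspline_grid"))
    list(affine = cbind(diag(3), c(0, 0, 0)), grid = transform)
  else if (inherits(transform, "ffd_transform"))
    list(affine = as_affine(transform$similarity), grid = transform$grid)
  else stop("unsupported transform class")
}

reg_cost <- function(fixed, moving, transform, metric, bins, range,
                     want_grad = FALSE) {
  tp <- transform_parts(transform)
  met <- match(metric, c("ssd", "mi")) - 1L
  if (is.na(met)) stop("metric must be 'ssd' or 'mi'")
  if (is.null(tp$grid)) {
    cpp_affine_cost(as.numeric(fixed$voxels), vol_dim(fixed), fixed$spacing,
                    fixed$origin, as.numeric(moving$voxels), vol_dim(moving),
                    moving$spacing, moving$origin, tp$affine, met,
                    32L, range)
  } else {
    g <- tp$grid
    cpp_ffd_cost_grad(as.numeric(fixed$voxels), vol_dim(fixed), fixed$spacing,
                      fixed$origin, as.numeric(moving$voxels), vol_dim(moving),
                      moving$spacing, moving$origin, tp$affine,
                      g$dims, g$spacing, g$origin, g$displacements,
                      met, bins, range, want_grad)
  }
}

#' Sum-of-squared-differences registration cost
#'
#' Mean squared intensity difference over the overlap region, with the
#' moving volume sampled by trilinear interpolation through the transform.
#'
#' @param fixed,moving [vol3d()] volumes.
#' @param transform a [similarity3d()], [bspline_grid()] or `ffd_transform`
#'   mapping fixed-world points into the moving volume.
#' @param min_overlap minimum tolerated overlap fraction of the fixed domain.
#' @return nonnegative scalar cost.
#' @export
ssd_cost <- function(fixed, moving, transform, min_overlap = 0.1) {
  res <- reg_cost(fixed, moving, transform, "ssd", 32L, c(0, 1, 0, 1))
  if (res$overlap < min_overlap)
    stop(sprintf("degenerate overlap: %.1f%% of fixed voxels", 100 * res$overlap))
  res$cost
}

#' Mutual-information registration cost (negated)
#'
#' Returns `-MI` where `MI = H(F) + H(M) - H(F, M)` with natural-log
#' entropies of the joint intensity histogram over the overlap region.
#' Intensities are clamped to their 1st-99th percentile range; the moving
#' intensity is spread linearly over adjacent bins (partial-volume binning)
#' so the cost is smooth.
#'
#' @inheritParams ssd_cost
#' @param bins histogram bins per axis.
#' @param range optional `c(fixed_lo, fixed_hi, moving_lo, moving_hi)`
#'   clamp range; default from percentiles.
#' @return scalar, `-MI` (lower = more similar).
#' @export
mi_cost <- function(fixed, moving, transform, bins = 32L, min_overlap = 0.1,
                    range = NULL) {
  if (is.null(range)) range <- mi_range(fixed, moving)
  res <- reg_cost(fixed, moving, transform, "mi", as.integer(bins), range)
  if (res$overlap < min_overlap)
    stop(sprintf("degenerate overlap: %.1f%% of fixed voxels", 100 * res$overlap))
  if (abs(res$cost) < 1e-12 &&
      (stats::sd(fixed$voxels) == 0 || stats::sd(moving$voxels) == 0))
    warning("constant image in overlap: MI is 0 (degenerate histogram)")
  res$cost
}

#' Default configuration for registration
#'
#' @param metric `"mi"` or `"ssd"`.
#' @param bins MI histogram bins.
#' @param levels multi-resolution schedule, ascending factors in (0, 1].
#' @param max_iter iteration cap per level (scalar, or one value per level).
#' @param grid_spacing_mm FFD control spacing (mm).
#' @param min_overlap degenerate-overlap threshold.
#' @param seed RNG seed recorded with results (the optimizers themselves are
#'   deterministic).
#' @return a list of settings.
#' @export
registration_config <- function(metric = "mi", bins = 32L,
                                levels = c(0.25, 0.5, 1), max_iter = 100L,
                                grid_spacing_mm = NULL, min_overlap = 0.1,
                                seed = 1L) {
  stopifnot(all(diff(levels) > 0), all(levels > 0), all(levels <= 1))
  list(metric = metric, bins = as.integer(bins), levels = levels,
       max_iter = rep_len(as.integer(max_iter), length(levels)),
       grid_spacing_mm = grid_spacing_mm,
       min_overlap = min_overlap, seed = as.integer(seed))
}

params_to_similarity <- function(theta, center) {
  similarity3d(euler_rotation(theta[1:3]), theta[4:6], exp(theta[7]), center)
}

# intensity centroid used to initialize the translation
intensity_centroid <- function(vol) {
  w <- as.vector(vol$voxels) - min(vol$voxels)
  s <- sum(w)
  if (s <= 0) return(vol$origin + (vol_dim(vol) - 1) * vol$spacing / 2)
  ctr <- numeric(3)
  d <- vol_dim(vol)
  idx <- list(
    rep.int(seq_len(d[1]), d[2] * d[3]),
    rep.int(rep(seq_len(d[2]), each = d[1]), d[3]),
    rep(seq_len(d[3]), each = d[1] * d[2]))
  for (ax in 1:3)
    ctr[ax] <- vol$origin[ax] + (sum(w * (idx[[ax]] - 1)) / s) * vol$spacing[ax]
  ctr
}

#' Similarity registration by multi-resolution cost minimization
#'
#' Optimizes a 7-parameter similarity transform (3 rotation angles, 3
#' translations, log-scale) over a coarse-to-fine resolution schedule with a
#' quasi-Newton optimizer and numerical gradients.  The translation is
#' initialized from the intensity centroids.  Deterministic given the
#' config.
#'
#' @param fixed,moving [vol3d()] volumes, both non-constant.
#' @param config a [registration_config()].
#' @param init optional initial [similarity3d()] overriding centroid init.
#' @return list with `transform` ([similarity3d()]) and `result`
#'   (cost trace, convergence flag, per-level costs).
#' @export
register_similarity <- function(fixed, moving, config = registration_config(),
                                init = NULL) {
  if (stats::sd(fixed$voxels) == 0 || stats::sd(moving$voxels) == 0)
    stop("constant volume cannot be registered")
  center <- fixed$origin + (vol_dim(fixed) - 1) * fixed$spacing / 2
  range <- mi_range(fixed, moving)
  theta <- if (is.null(init)) {
    c(0, 0, 0, intensity_centroid(moving) - intensity_centroid(fixed), 0)
  } else {
    ang <- c(atan2(init$rotation[3, 2], init$rotation[3, 3]),
             -asin(init$rotation[3, 1]),
             atan2(init$rotation[2, 1], init$rotation[1, 1]))
    c(ang, init$translation, log(init$scale))
  }
  trace <- numeric(0)
  per_level <- numeric(length(config$levels))
  for (li in seq_along(config$levels)) {
    fl <- resample_volume(fixed, config$levels[li])
    ml <- resample_volume(moving, config$levels[li])
    fn <- function(th) {
      tr <- params_to_similarity(th, center)
      res <- reg_cost(fl, ml, tr, config$metric, config$bins, range)
      if (res$overlap < config$min_overlap) return(1e6 * (1 + 1 - res$overlap))
      res$cost
    }
    vox <- mean(fl$spacing)
    opt <- stats::optim(theta, fn, method = "L-BFGS-B",
                        control = list(maxit = rep_len(config$max_iter,
                                                       length(config$levels))[li],
                                       parscale = c(rep(0.05, 3), rep(vox, 3), 0.05),
                                       factr = 1e7))
    theta <- opt$par
    per_level[li] <- opt$value
    trace <- c(trace, opt$value)
  }
  list(transform = params_to_similarity(theta, center),
       result = list(cost_trace = cummin(trace), per_level = per_level,
                     converged = TRUE, metric = config$metric))
}

#' B-spline FFD registration
#'
#' Starting from a similarity initialization, optimizes per-control-point
#' displacements of a cubic B-spline lattice by gradient descent with
#' backtracking (step halving), coarse-to-fine over the resolution schedule.
#' The analytic gradient of the chosen cost (SSD, or MI with partial-volume
#' histogram binning) with respect to the control displacements is used.
#'
#' @param fixed,moving [vol3d()] volumes.
#' @param init initial [similarity3d()] (e.g. from [register_similarity()]).
#' @param metric `"ssd"` or `"mi"`.
#' @param config a [registration_config()]; `grid_spacing_mm` defaults to
#'   1/5 of the fixed-volume extent.
#' @return list with `transform` (an `ffd_transform`: similarity + lattice)
#'   and `result` (cost trace per accepted step, convergence flag).
#' @export
register_ffd <- function(fixed, moving, init = similarity3d(),
                         metric = c("ssd", "mi"),
                         config = registration_config(metric = "ssd")) {
  metric <- match.arg(metric)
  extent <- (vol_dim(fixed) - 1) * fixed$spacing
  gsp <- config$grid_spacing_mm
  if (is.null(gsp)) gsp <- max(extent) / 5
  grid <- bspline_grid_for_volume(fixed, gsp)
  range <- mi_range(fixed, moving)
  level_trace <- vector("list", length(config$levels))
  names(level_trace) <- as.character(config$levels)
  converged <- TRUE
  tr_of <- function(g) structure(list(similarity = init, grid = g),
                                 class = "ffd_transform")
  for (li in seq_along(config$levels)) {
    fl <- resample_volume(fixed, config$levels[li])
    ml <- resample_volume(moving, config$levels[li])
    step <- 0.5 * mean(fl$spacing)
    cg <- reg_cost(fl, ml, tr_of(grid), metric, config$bins, range,
                   want_grad = TRUE)
    cost <- cg$cost
    trace <- cost
    iters <- rep_len(config$max_iter, length(config$levels))[li]
    step0 <- step
    for (it in seq_len(iters)) {
      g <- cg$grad
      gmax <- max(abs(g))
      if (gmax < 1e-14) break
      accepted <- FALSE
      for (half in 1:12) {
        cand <- grid
        cand$displacements <- grid$displacements - (step / gmax) * g
        cc <- reg_cost(fl, ml, tr_of(cand), metric, config$bins, range)
        if (cc$cost < cost - 1e-12) {
          grid <- cand
          cost <- cc$cost
          trace <- c(trace, cost)
          step <- step * 1.2
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted || step < 1e-3 * step0) break
      cg <- reg_cost(fl, ml, tr_of(grid), metric, config$bins, range,
                     want_grad = TRUE)
    }
    level_trace[[li]] <- trace
  }
  list(transform = structure(list(similarity = init, grid = grid),
                             class = "ffd_transform"),
       result = list(cost_trace = unlist(level_trace),
                     level_trace = level_trace, converged = converged,
                     metric = metric))
}

#' Propagate a binary mask through a transform
#'
#' Nearest-neighbor resampling of the mask onto `grid` through the transform
#' (which maps target-grid points into the mask's space); the output is
#' binary on the target grid.
#'
#' @param mask a [label_mask()].
#' @param transform [similarity3d()], [bspline_grid()] or `ffd_transform`.
#' @param grid target grid (`vol3d`); defaults to the mask's own grid.
#' @return a [label_mask()] on the target grid.
#' @export
warp_mask <- function(mask, transform, grid = mask) {
  tp <- transform_parts(transform)
  d <- vol_dim(grid)
  disp <- NULL
  if (!is.null(tp$grid)) {
    ctrs <- voxel_centers(grid)
    disp <- bspline_displacement(tp$grid, ctrs, outside = "zero")
  }
  res <- cpp_resample_affine(as.numeric(mask$voxels), vol_dim(mask),
                             mask$spacing, mask$origin, d, grid$spacing,
                             grid$origin, tp$affine, disp, 0, TRUE)
  label_mask(array(as.integer(res$values), d), grid$spacing, grid$origin)
}
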