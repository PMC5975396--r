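#' 3D scalar volume
#'
#' A `vol3d` is a 3D scalar grid (intensities in arbitrary units or HU) with
#' voxel spacing and world origin in millimetres.  Voxel indices are 1-based
#' in R; the world coordinate of voxel `(i, j, k)` is
#' `origin + (i - 1, j - 1, k - 1) * spacing` (node-centered convention).
#' The first array index is the x axis (fastest-varying, as in MetaImage).
#'
#' @param voxels 3D numeric array of intensities.
#' @param spacing numeric length-3, mm per axis, all positive.
#' @param origin numeric length-3, world position of voxel (1,1,1) in mm.
#' @return An object of class `vol3d`.
#' @export
vol3d <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (any(dim(voxels) < 2L)) stop("grid dimensions must be >= 2 per axis")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite reals")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite reals")
  if (any(!is.finite(voxels))) stop("all voxel values must be finite")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "vol3d")
}

#' Binary label mask on a voxel grid
#'
#' A `label_mask` is a `vol3d` whose voxels are restricted to \{0, 1\}.
#'
#' @inheritParams vol3d
#' @return An object of class `c("label_mask", "vol3d")`.
#' @export
label_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- vol3d(voxels, spacing, origin)
  vals <- unique(as.vector(v$voxels))
  if (!all(vals %in% c(0, 1))) stop("mask values must be exactly in {0, 1}")
  storage.mode(v$voxels) <- "integer"
  class(v) <- c("label_mask", "vol3d")
  v
}

#' @export
print.vol3d <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n",
              class(x)[1], paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

vol_dim <- function(vol) dim(vol$voxels)

#' Check that two volumes share grid metadata
#' @param a,b `vol3d` objects.
#' @param tol numeric tolerance on spacing/origin (mm).
#' @return logical
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' World coordinates of voxel centers
#'
#' @param vol a `vol3d` (only its grid metadata is used).
#' @param flat_idx optional 1-based flat voxel indices; default all voxels.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
voxel_centers <- function(vol, flat_idx = NULL) {
  d <- vol_dim(vol)
  if (is.null(flat_idx)) flat_idx <- seq_len(prod(d))
  idx0 <- arrayInd(flat_idx, d) - 1L
  sweep(idx0 %*% diag(vol$spacing), 2L, vol$origin, "+")
}

#' Sample a volume at world points by trilinear interpolation
#' @param vol a `vol3d`.
#' @param pts n x 3 matrix of world points (mm).
#' @param background value returned outside the grid.
#' @return numeric vector of length n.
#' @export
sample_volume <- function(vol, pts, background = 0) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  cpp_sample_trilinear(as.numeric(vol$voxels), vol_dim(vol),
                       vol$spacing, vol$origin, pts, background)
}

#' Gaussian-smooth a volume
#' @param vol a `vol3d`.
#' @param sigma_mm smoothing bandwidth in mm (scalar or length 3).
#' @return smoothed `vol3d`.
#' @export
smooth_volume <- function(vol, sigma_mm) {
  sig <- rep_len(sigma_mm, 3L) / vol$spacing
  out <- cpp_gaussian_blur(as.numeric(vol$voxels), vol_dim(vol), sig)
  vol3d(array(out, vol_dim(vol)), vol$spacing, vol$origin)
}

#' Resample a volume to a scaled resolution
#'
#' Used for the coarse-to-fine schedules: `factor = 0.25` yields a volume
#' with one quarter of the voxels per axis (spacing divided by the factor),
#' Gaussian-presmoothed against aliasing.
#'
#' @param vol a `vol3d`.
#' @param factor resolution factor in (0, 1].
#' @return resampled `vol3d` covering the same world extent.
#' @export
resample_volume <- function(vol, factor) {
  stopifnot(factor > 0, factor <= 1)
  if (factor == 1) return(vol)
  d <- vol_dim(vol)
  nd <- pmax(2L, as.integer(round(d * factor)))
  nsp <- vol$spacing * (d - 1L) / (nd - 1L)
  sm <- smooth_volume(vol, 0.5 * nsp)
  res <- cpp_resample_affine(as.numeric(sm$voxels), d, sm$spacing, sm$origin,
                             nd, nsp, vol$origin,
                             cbind(diag(3), c(0, 0, 0)), NULL, 0, FALSE)
  vol3d(array(res$values, nd), nsp, vol$origin)
}
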