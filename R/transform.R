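#' Similarity transform (rotation + translation + isotropic scale)
#'
#' Maps a world point x to `scale * R %*% (x - center) + center + translation`.
#' The rotation matrix must be proper orthonormal (det +1).
#'
#' @param rotation 3 x 3 orthonormal matrix.
#' @param translation length-3 numeric (mm).
#' @param scale positive scalar.
#' @param center rotation/scaling center (mm); default the origin.
#' @return an object of class `similarity3d`.
#' @export
similarity3d <- function(rotation = diag(3), translation = c(0, 0, 0),
                         scale = 1, center = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-10)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0) stop("rotation must be proper (det +1), not a reflection")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a positive scalar")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 scale = scale, center = as.numeric(center)),
            class = "similarity3d")
}

#' Rotation matrix from XYZ Euler angles (radians)
#' @param angles length-3 numeric, rotations about x, y, z applied in order.
#' @return 3 x 3 rotation matrix.
#' @export
euler_rotation <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' Rotation angle of a similarity transform, in degrees
#' @param tr a [similarity3d()].
#' @return scalar angle of the rotation component.
#' @export
rotation_angle_deg <- function(tr) {
  tr_r <- sum(diag(tr$rotation))
  acos(pmin(1, pmax(-1, (tr_r - 1) / 2))) * 180 / pi
}

# 3 x 4 affine [A | b] such that y = A x + b
as_affine <- function(tr) {
  A <- tr$scale * tr$rotation
  b <- tr$center + tr$translation - A %*% tr$center
  cbind(A, b)
}

#' Apply a transform to world points
#' @param tr a [similarity3d()], [bspline_grid()], or `ffd_transform`.
#' @param pts n x 3 matrix of world points (mm).
#' @param ... passed on (e.g. `outside` for B-spline lattices).
#' @return n x 3 matrix of mapped points.
#' @export
apply_transform <- function(tr, pts, ...) UseMethod("apply_transform")

#' @export
apply_transform.similarity3d <- function(tr, pts, ...) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  af <- as_affine(tr)
  sweep(pts %*% t(af[, 1:3]), 2, af[, 4], "+")
}

#' @export
apply_transform.bspline_grid <- function(tr, pts, outside = "zero", ...) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  pts + bspline_displacement(tr, pts, outside = outside)
}

#' @export
apply_transform.ffd_transform <- function(tr, pts, outside = "zero", ...) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  apply_transform(tr$similarity, pts) +
    bspline_displacement(tr$grid, pts, outside = outside)
}

#' Invert a similarity transform
#' @param tr a [similarity3d()].
#' @return the inverse [similarity3d()].
#' @export
invert_similarity <- function(tr) {
  af <- as_affine(tr)
  Ainv <- t(tr$rotation) / tr$scale
  binv <- -Ainv %*% af[, 4]
  similarity3d(t(tr$rotation), as.numeric(binv), 1 / tr$scale, c(0, 0, 0))
}

#' Cubic B-spline control-point lattice
#'
#' Control point `(a, b, c)` (0-based) sits at
#' `grid_origin + (a, b, c) * grid_spacing`; displacements are per-control-
#' point 3-vectors in mm.  A world point has full support when its 4x4x4
#' control neighborhood lies inside the lattice, which requires at least 4
#' control points per axis.
#'
#' @param dims integer length-3, control points per axis (>= 4).
#' @param spacing lattice spacing per axis (mm).
#' @param origin world position of control point (0,0,0).
#' @param displacements `prod(dims)` x 3 matrix (x-fastest order), default 0.
#' @return an object of class `bspline_grid`.
#' @export
bspline_grid <- function(dims, spacing, origin, displacements = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 4L))
    stop("lattice needs at least 4 control points per axis")
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- as.numeric(origin)
  ncp <- prod(dims)
  if (is.null(displacements)) displacements <- matrix(0, ncp, 3)
  displacements <- matrix(as.numeric(displacements), ncol = 3)
  if (nrow(displacements) != ncp) stop("displacements must be prod(dims) x 3")
  if (any(!is.finite(displacements))) stop("displacements must be finite")
  structure(list(dims = dims, spacing = spacing, origin = origin,
                 displacements = displacements), class = "bspline_grid")
}

#' Lattice covering a volume with one control point of padding
#'
#' The lattice extends one control spacing beyond the volume on every side
#' so each voxel has full 4x4x4 support.
#'
#' @param vol a [vol3d()].
#' @param spacing_mm requested control spacing (scalar or length 3, mm).
#' @return a zero-displacement [bspline_grid()].
#' @export
bspline_grid_for_volume <- function(vol, spacing_mm) {
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  lo <- vol$origin
  hi <- vol$origin + (vol_dim(vol) - 1L) * vol$spacing
  dims <- pmax(4L, as.integer(ceiling((hi - lo) / spacing_mm)) + 4L)
  bspline_grid(dims, spacing_mm, lo - 1.5 * spacing_mm)
}

#' Evaluate the B-spline displacement field
#'
#' The displacement at x is the tensor-product sum
#' `sum_l sum_m sum_n B_l(mu_x) B_m(mu_y) B_n(mu_z) d[i+l, j+m, k+n]`
#' over the 4x4x4 control neighborhood, with cubic B-spline basis functions.
#'
#' @param grid a [bspline_grid()].
#' @param pts n x 3 matrix of world points (mm).
#' @param outside `"error"` to reject points without full support, `"zero"`
#'   to return zero displacement there.
#' @return n x 3 matrix of displacements (mm).
#' @export
bspline_displacement <- function(grid, pts, outside = c("error", "zero")) {
  outside <- match.arg(outside)
  pts <- matrix(as.numeric(pts), ncol = 3)
  cpp_bspline_disp(grid$dims, grid$spacing, grid$origin, grid$displacements,
                   pts, if (outside == "error") 0L else 1L)
}

#' Serialize a transform to JSON
#'
#' Similarity transforms store 12 numbers (rotation row-major, translation,
#' scale, center offset folded into translation is not applied: center is
#' stored); B-spline grids store dims, spacing, origin and the flat
#' displacement list.
#'
#' @param tr a [similarity3d()] or [bspline_grid()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(tr, path) {
  obj <- if (inherits(tr, "similarity3d")) {
    list(type = "similarity", rotation = as.vector(t(tr$rotation)),
         translation = tr$translation, scale = tr$scale, center = tr$center)
  } else if (inherits(tr, "bspline_grid")) {
    list(type = "bspline", dims = tr$dims, spacing = tr$spacing,
         origin = tr$origin, displacements = as.vector(tr$displacements))
  } else if (inherits(tr, "ffd_transform")) {
    list(type = "ffd",
         similarity = list(rotation = as.vector(t(tr$similarity$rotation)),
                           translation = tr$similarity$translation,
                           scale = tr$similarity$scale,
                           center = tr$similarity$center),
         grid = list(dims = tr$grid$dims, spacing = tr$grid$spacing,
                     origin = tr$grid$origin,
                     displacements = as.vector(tr$grid$displacements)))
  } else stop("unsupported transform class")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a transform written by [write_transform()]
#' @param path JSON path.
#' @return a transform object.
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(obj$type,
    similarity = similarity3d(matrix(obj$rotation, 3, 3, byrow = TRUE),
                              obj$translation, obj$scale, obj$center),
    bspline = bspline_grid(obj$dims, obj$spacing, obj$origin,
                           matrix(obj$displacements, ncol = 3)),
    ffd = structure(list(
      similarity = similarity3d(matrix(obj$similarity$rotation, 3, 3, byrow = TRUE),
                                obj$similarity$translation, obj$similarity$scale,
                                obj$similarity$center),
      grid = bspline_grid(obj$grid$dims, obj$grid$spacing, obj$grid$origin,
                          matrix(obj$grid$displacements, ncol = 3))),
      class = "ffd_transform"),
    stop("unknown transform type: ", obj$type))
}
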