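#' Boundary-voxel point set of a mask
#'
#' Foreground voxels with at least one background 6-neighbor (the grid
#' border counts as background), positioned at voxel centers in world mm.
#'
#' @param mask a [label_mask()].
#' @return n x 3 matrix of world points.
#' @export
boundary_points <- function(mask) {
  b <- cpp_boundary_voxels(as.integer(mask$voxels), vol_dim(mask))
  idx <- which(b)
  if (length(idx) == 0) stop("empty surface: mask has no foreground voxels")
  voxel_centers(mask, idx)
}

as_point_set <- function(x) {
  if (inherits(x, "label_mask")) boundary_points(x)
  else if (inherits(x, "surface_mesh")) x$vertices
  else if (is.matrix(x) && ncol(x) == 3) x
  else stop("expected a label_mask, surface_mesh, or n x 3 point matrix")
}

#' Dice overlap coefficient, in percent
#'
#' `2 |A∩B| / (|A| + |B|) * 100`; two empty masks score 100 (0/0
#' convention).
#'
#' @param a,b [label_mask()] objects on identical grids.
#' @return scalar in \[0, 100\].
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "label_mask"), inherits(b, "label_mask"))
  if (!same_grid(a, b)) stop("masks are on different grids")
  na <- sum(a$voxels)
  nb <- sum(b$voxels)
  if (na + nb == 0) {
    message("both masks empty: Dice reported as 100 (0/0 convention)")
    return(100)
  }
  inter <- sum(a$voxels & b$voxels)
  200 * inter / (na + nb)
}

#' Symmetric mean surface distance (mm)
#'
#' `(sum_i d_i + sum_j d_j) / (n_X + n_Y)` where the `d` are closest
#' distances from each surface element of one input to the other surface,
#' in both directions.  Masks contribute their boundary voxel centers,
#' meshes their vertices.
#'
#' @param a,b [label_mask()], [surface_mesh()], or n x 3 point matrices.
#' @return nonnegative scalar (mm).
#' @export
mean_surface_distance <- function(a, b) {
  pa <- as_point_set(a)
  pb <- as_point_set(b)
  dab <- cpp_closest_dists(pa, pb)
  dba <- cpp_closest_dists(pb, pa)
  (sum(dab) + sum(dba)) / (nrow(pa) + nrow(pb))
}

#' Hausdorff distance (mm)
#'
#' Maximum of the two directed worst-case closest distances between the two
#' surface point sets.
#'
#' @inheritParams mean_surface_distance
#' @return nonnegative scalar (mm).
#' @export
hausdorff <- function(a, b) {
  pa <- as_point_set(a)
  pb <- as_point_set(b)
  max(max(cpp_closest_dists(pa, pb)), max(cpp_closest_dists(pb, pa)))
}

#' Evaluate a predicted segmentation against a reference
#'
#' Computes Dice (percent), mean surface distance and Hausdorff distance
#' (both mm, from boundary-voxel point sets) in one report row.
#'
#' @param predicted,reference [label_mask()] objects on the same grid.
#' @param case_id identifier recorded in the report.
#' @return one-row data.frame: `case_id`, `dice_percent`, `msd_mm`,
#'   `hausdorff_mm`.
#' @export
evaluate_case <- function(predicted, reference, case_id = "case") {
  d <- dice(predicted, reference)
  if (sum(predicted$voxels) == 0 || sum(reference$voxels) == 0) {
    msd <- NA_real_
    h <- NA_real_
  } else {
    pa <- boundary_points(predicted)
    pb <- boundary_points(reference)
    dab <- cpp_closest_dists(pa, pb)
    dba <- cpp_closest_dists(pb, pa)
    msd <- (sum(dab) + sum(dba)) / (length(dab) + length(dba))
    h <- max(max(dab), max(dba))
  }
  data.frame(case_id = case_id, dice_percent = d, msd_mm = msd,
             hausdorff_mm = h, stringsAsFactors = FALSE)
}
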