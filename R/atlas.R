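#' Atlas case: an image with its known segmentation
#'
#' @param image a [vol3d()].
#' @param mask a non-empty [label_mask()] on the same grid.
#' @return a list of class `atlas_case`.
#' @export
atlas_case <- function(image, mask) {
  stopifnot(inherits(image, "vol3d"), inherits(mask, "label_mask"))
  if (!same_grid(image, mask)) stop("image and mask must share grid metadata")
  if (sum(mask$voxels) == 0) stop("atlas mask is empty")
  structure(list(image = image, mask = mask), class = "atlas_case")
}

#' Single-atlas segmentation by registration and label propagation
#'
#' Registers the atlas image to the target (similarity first, then B-spline
#' free-form deformation, both driven by the chosen similarity metric) and
#' propagates the atlas mask through the resulting transform with
#' nearest-neighbor resampling.  Deterministic given the config.
#'
#' @param atlas an [atlas_case()].
#' @param target target [vol3d()] (non-constant).
#' @param metric `"ssd"` or `"mi"`.
#' @param config a [registration_config()].
#' @return list with `mask` (propagated [label_mask()] on the target grid),
#'   `transform`, and `result` (per-stage registration results).
#' @export
segment_single_atlas <- function(atlas, target, metric = c("ssd", "mi"),
                                 config = registration_config()) {
  metric <- match.arg(metric)
  stopifnot(inherits(atlas, "atlas_case"))
  config$metric <- metric
  sim <- register_similarity(target, atlas$image, config)
  ffd <- register_ffd(target, atlas$image, sim$transform, metric, config)
  out <- warp_mask(atlas$mask, ffd$transform, target)
  if (sum(out$voxels) == 0)
    warning("propagated mask is empty")
  list(mask = out, transform = ffd$transform,
       result = list(similarity = sim$result, ffd = ffd$result))
}
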