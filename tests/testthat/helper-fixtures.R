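# Shared fixtures.  Heavy objects are built once per test run and cached in
# this environment so several test files (and the acceptance checks) can
# reuse them.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# centered digital ball mask
ball_mask <- function(radius_vox = 10, dim = 32L, spacing = 2) {
  d <- rep(dim, 3)
  sp <- rep(spacing, 3)
  or <- -(d - 1) * sp / 2
  cc <- voxel_centers(vol3d(array(0, d), sp, or))
  label_mask(array(as.integer(sqrt(rowSums(cc^2)) <= radius_vox * spacing), d),
             sp, or)
}

# smooth synthetic volume with internal structure, for registration tests
smooth_test_volume <- function(d = c(32, 32, 32), sp = c(2, 2, 2)) {
  or <- -(d - 1) * sp / 2
  cc <- voxel_centers(vol3d(array(0, d), sp, or))
  r <- sqrt(rowSums(cc^2))
  v <- 100 / (1 + exp((r - 20) / 4)) + 10 * sin(cc[, 1] / 9) * cos(cc[, 2] / 11)
  vol3d(array(v, d), sp, or)
}

small_cohort <- function() {
  cached("small_cohort", generate_cohort(phantom_spec(seed = 42L), 6))
}

# the standard 20-phantom cohort used by the end-to-end checks
default_cohort <- function() {
  cached("default_cohort", generate_cohort(phantom_spec(seed = 1L), 20))
}

default_experiment <- function() {
  cached("default_experiment", {
    cfg <- experiment_config(spec = phantom_spec(seed = 1L), seed = 1L)
    run_experiment(cfg, cohort = default_cohort())
  })
}

remap_experiment <- function() {
  cached("remap_experiment", {
    cfg <- experiment_config(spec = phantom_spec(seed = 1L), seed = 1L,
                             methods = c("atlas-ssd", "atlas-mi"),
                             remap_test = TRUE)
    run_experiment(cfg, cohort = default_cohort())
  })
}
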