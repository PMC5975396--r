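test_that("reference organ is deterministic, closed, orientable, asymmetric", {
  m1 <- make_reference_organ(400)
  m2 <- make_reference_organ(400)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)
  expect_identical(euler_characteristic(m1), 2L)
  expect_gt(mesh_volume(m1), 0) # outward orientation
  expect_error(make_reference_organ(50), "at least 100")
  # asymmetry: no nontrivial rotation about a coordinate axis realigns it
  ctr <- colMeans(m1$vertices)
  vc <- sweep(m1$vertices, 2, ctr)
  diam <- ssmseg:::mesh_diameter(m1)
  for (ang in c(pi / 2, pi)) {
    for (ax in 1:3) {
      angs <- numeric(3)
      angs[ax] <- ang
      rot <- vc %*% t(euler_rotation(angs))
      d <- ssmseg:::cpp_closest_dists(rot, vc)
      expect_gt(sqrt(mean(d^2)), 0.01 * diam)
    }
  }
})

test_that("cohorts are seeded-reproducible with consistent ground truth", {
  spec <- phantom_spec(grid_dim = 48L, n_vertices = 400L, seed = 5L)
  c1 <- generate_cohort(spec, 3)
  c2 <- generate_cohort(spec, 3)
  for (i in 1:3) {
    expect_identical(c1$cases[[i]]$image$voxels, c2$cases[[i]]$image$voxels)
    expect_identical(c1$cases[[i]]$mask$voxels, c2$cases[[i]]$mask$voxels)
    expect_identical(c1$cases[[i]]$true_alpha, c2$cases[[i]]$true_alpha)
    # mask equals the voxelized mesh by construction
    expect_identical(dice(surface_to_mask(c1$cases[[i]]$mesh,
                                          c1$cases[[i]]$mask),
                          c1$cases[[i]]$mask), 100)
    expect_length(c1$cases[[i]]$true_alpha, spec$deformation_rank)
  }
})

test_that("zero amplitude gives identical masks across cases", {
  spec <- phantom_spec(grid_dim = 40L, n_vertices = 300L, amplitude = 0,
                       seed = 2L)
  co <- generate_cohort(spec, 3)
  expect_identical(dice(co$cases[[1]]$mask, co$cases[[2]]$mask), 100)
  expect_identical(dice(co$cases[[1]]$mask, co$cases[[3]]$mask), 100)
})

test_that("phantom intensities are bimodal at the specified levels", {
  co <- small_cohort()
  spec <- co$spec
  v <- co$cases[[1]]$image$voxels
  m <- co$cases[[1]]$mask$voxels == 1L
  # mode-finding oracle: density peaks of the two compartments
  d_in <- stats::density(v[m])
  d_out <- stats::density(v[!m])
  expect_lt(abs(d_in$x[which.max(d_in$y)] - spec$intensity_in), spec$noise_sd)
  expect_lt(abs(d_out$x[which.max(d_out$y)] - spec$intensity_out), spec$noise_sd)
})

test_that("generating deformations lie exactly in the true GP span", {
  co <- small_cohort()
  gp <- co$true_gp
  for (cs in co$cases[1:2]) {
    f <- cs$mesh$vertices - co$reference$vertices
    expect_equal(f, sample_deformation(gp, cs$true_alpha), tolerance = 1e-10)
  }
})

test_that("oracle fields extend consistently to other mesh resolutions", {
  co <- small_cohort()
  # at the reference vertices the Nystrom extension must agree exactly
  f_direct <- cohort_true_fields(co, cases = 1)[[1]]
  f_ext <- cohort_true_fields(co, at = co$reference$vertices, cases = 1)[[1]]
  expect_equal(f_ext, f_direct, tolerance = 1e-8)
})

test_that("empirical GP from true fields recovers the leading variance", {
  # rendering grid is irrelevant for this check; keep it small and cheap
  spec <- phantom_spec(grid_dim = 16L, spacing_mm = 8, n_vertices = 400L,
                       seed = 31L)
  co <- generate_cohort(spec, 50)
  fields <- cohort_true_fields(co)
  eg <- build_empirical_gp(fields)
  expect_lt(abs(eg$variances[1] - co$true_gp$variances[1]) /
              co$true_gp$variances[1], 0.3)
})

test_that("train/test splits are seeded, disjoint and exhaustive", {
  co <- small_cohort()
  s1 <- split_train_test(co, 3, seed = 4)
  s2 <- split_train_test(co, 3, seed = 4)
  expect_identical(s1, s2)
  expect_length(intersect(s1$train, s1$test), 0)
  expect_setequal(c(s1$train, s1$test), seq_along(co$cases))
  expect_error(split_train_test(co, 6, seed = 1), "n_train")
})
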