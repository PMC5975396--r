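test_that("SSD cost matches direct per-voxel computation", {
  f <- smooth_test_volume()
  expect_identical(ssd_cost(f, f, similarity3d()), 0)
  g <- f
  g$voxels <- f$voxels + 5
  expect_equal(ssd_cost(f, g, similarity3d()), 25, tolerance = 1e-12)
  set.seed(1)
  h <- f
  h$voxels <- f$voxels + array(rnorm(length(f$voxels)), dim(f$voxels))
  expect_equal(ssd_cost(f, h, similarity3d()),
               mean((h$voxels - f$voxels)^2), tolerance = 1e-10)
  expect_gte(ssd_cost(f, h, similarity3d()), 0)
})

test_that("self-MI equals the marginal histogram entropy", {
  set.seed(2)
  ints <- array(sample(0:31, 16^3, TRUE), c(16, 16, 16))
  v <- vol3d(ints, c(2, 2, 2), c(0, 0, 0))
  rng <- c(-0.5, 31.5, -0.5, 31.5) # bin centers exactly on the integers
  # independent oracle: histogram entropy
  p <- tabulate(as.vector(ints) + 1, 32) / length(ints)
  H <- -sum(p[p > 0] * log(p[p > 0]))
  expect_equal(mi_cost(v, v, similarity3d(), bins = 32, range = rng), -H,
               tolerance = 1e-10)
})

test_that("MI of independent noise volumes is near zero and symmetric", {
  set.seed(3)
  a <- vol3d(array(runif(16^3), c(16, 16, 16)))
  b <- vol3d(array(runif(16^3), c(16, 16, 16)))
  # permutation baseline for the small-sample MI bias of a 32^2 histogram
  perm <- replicate(20, {
    bp <- vol3d(array(sample(b$voxels), dim(b$voxels)))
    -mi_cost(a, bp, similarity3d())
  })
  mi_ab <- -mi_cost(a, b, similarity3d())
  expect_lt(abs(mi_ab - mean(perm)), 3 * stats::sd(perm))
  expect_equal(mi_cost(a, b, similarity3d()), mi_cost(b, a, similarity3d()),
               tolerance = 1e-10)
})

test_that("constant overlap degenerates MI to zero with a warning", {
  cst <- vol3d(array(7, c(8, 8, 8)))
  v <- vol3d(array(rnorm(512), c(8, 8, 8)))
  expect_warning(val <- mi_cost(cst, v, similarity3d()), "constant")
  expect_equal(val, 0, tolerance = 1e-12)
})

test_that("similarity registration recovers a known translation", {
  f <- smooth_test_volume()
  mov <- f
  mov$origin <- f$origin - c(5, 0, 0) # world shift of +5 mm
  for (metric in c("ssd", "mi")) {
    reg <- register_similarity(f, mov,
                               registration_config(metric = metric,
                                                   max_iter = 50))
    err <- sqrt(sum((reg$transform$translation - c(-5, 0, 0))^2))
    expect_lt(err, 2) # one voxel
    expect_lt(abs(reg$transform$scale - 1), 0.02)
  }
})

test_that("registering a volume to itself stays at the identity", {
  f <- smooth_test_volume()
  reg <- register_similarity(f, f, registration_config(metric = "ssd",
                                                       max_iter = 40))
  expect_lt(sqrt(sum(reg$transform$translation^2)), 1) # 0.5 voxel
  expect_lt(rotation_angle_deg(reg$transform), 0.5)
  expect_error(register_similarity(vol3d(array(1, c(8, 8, 8))), f), "constant")
})

test_that("FFD registration leaves identical volumes nearly undeformed", {
  f <- smooth_test_volume(c(24, 24, 24))
  reg <- register_ffd(f, f, similarity3d(), "ssd",
                      registration_config(metric = "ssd", max_iter = 10,
                                          grid_spacing_mm = 16))
  dmag <- sqrt(rowSums(reg$transform$grid$displacements^2))
  expect_lte(mean(dmag), 0.5) # <= 0.25 voxel of 2 mm
  # accepted-step cost trace is non-increasing within each level
  for (tr in reg$result$level_trace) expect_true(all(diff(tr) <= 1e-9))
})

test_that("FFD recovers a known smooth synthetic warp", {
  f <- smooth_test_volume(c(48, 48, 48))
  gt <- bspline_grid_for_volume(f, 40)
  set.seed(4)
  gt$displacements <- matrix(rnorm(nrow(gt$displacements) * 3, sd = 4), ncol = 3)
  ctrs <- voxel_centers(f)
  disp <- bspline_displacement(gt, ctrs, outside = "zero")
  warped <- vol3d(array(sample_volume(f, ctrs + disp), dim(f$voxels)),
                  f$spacing, f$origin)
  reg <- register_ffd(warped, f, similarity3d(), "ssd",
                      registration_config(metric = "ssd", max_iter = 30,
                                          grid_spacing_mm = 20))
  rec <- bspline_displacement(reg$transform$grid, ctrs, outside = "zero")
  sel <- sqrt(rowSums(ctrs^2)) < 30 # interior, away from boundary effects
  err <- sqrt(rowSums((rec[sel, ] - disp[sel, ])^2))
  expect_lt(mean(err), 4) # 2 voxels of 2 mm
})

test_that("warp_mask is exact for identity and integer-voxel translations", {
  m <- ball_mask(6, 24L, 2)
  expect_identical(warp_mask(m, similarity3d())$voxels, m$voxels)
  tr <- similarity3d(translation = c(4, -6, 2)) # 2,3,1 voxels
  shifted <- warp_mask(m, tr)
  # oracle: shift the array by the integer voxel offsets
  d <- dim(m$voxels)
  oracle <- array(0L, d)
  oracle[1:(d[1] - 2), 4:d[2], 1:(d[3] - 1)] <-
    m$voxels[3:d[1], 1:(d[2] - 3), 2:d[3]]
  expect_identical(shifted$voxels, oracle)
})

test_that("warp then approximate inverse warp preserves a ball mask", {
  m <- ball_mask(8, 32L, 2)
  g <- bspline_grid_for_volume(m, 24)
  set.seed(5)
  g$displacements <- matrix(rnorm(nrow(g$displacements) * 3, sd = 1.5), ncol = 3)
  fwd <- warp_mask(m, g)
  # approximate inverse displacement by fixed-point iteration on the grid
  ginv <- g
  for (it in 1:10) {
    cp_pos <- voxel_centers(vol3d(array(0, g$dims), g$spacing, g$origin))
    d_at <- bspline_displacement(g, cp_pos + ginv$displacements, outside = "zero")
    ginv$displacements <- -d_at
  }
  back <- warp_mask(fwd, ginv)
  expect_gte(dice(back, m), 95)
})
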