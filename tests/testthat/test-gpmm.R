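test_that("Gaussian kernels are symmetric, positive semidefinite, composable", {
  k <- gaussian_kernel(2, 15)
  x <- c(1, 2, 3)
  y <- c(4, 0, -2)
  expect_equal(kernel_eval(k, x, x), 2 * diag(3), tolerance = 1e-12)
  ys <- x + c(15, 0, 0) # ||x - y|| = sigma
  expect_equal(kernel_eval(k, x, ys)[1, 1], 2 * exp(-1), tolerance = 1e-12)
  expect_equal(kernel_eval(k, x, y), t(kernel_eval(k, y, x)), tolerance = 1e-12)
  set.seed(1)
  P <- matrix(rnorm(150), 50, 3) * 10
  G <- ssmseg:::kernel_gram(k, P, P)
  expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  ks <- k + gaussian_kernel(1, 40)
  G2 <- ssmseg:::kernel_gram(ks, P, P)
  expect_gte(min(eigen(G2, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  k3 <- 2 * gaussian_kernel(1, 15)
  expect_equal(kernel_eval(k3, x, x), 2 * diag(3), tolerance = 1e-12)
  expect_error(gaussian_kernel(-1, 5), "positive")
})

test_that("Nystrom with all vertices reproduces the dense decomposition", {
  ref <- make_reference_organ(250)
  k <- gaussian_kernel(1, 0.5 * ssmseg:::mesh_diameter(ref))
  dense <- build_low_rank_gp(k, ref, r = 30, m = nrow(ref$vertices),
                             dense_limit = 0)
  full <- build_low_rank_gp(k, ref, r = 30)
  expect_equal(dense$scalar_values[1:10], full$scalar_values[1:10],
               tolerance = 1e-8)
})

test_that("Nystrom at half the vertices matches dense eigenvalues within 10%", {
  ref <- make_reference_organ(300)
  diam <- ssmseg:::mesh_diameter(ref)
  for (k in list(gaussian_kernel(1, diam),
                 gaussian_kernel(1, diam) + gaussian_kernel(0.5, 0.4 * diam))) {
    dense <- build_low_rank_gp(k, ref, r = 12, dense_limit = 0,
                               m = nrow(ref$vertices))
    nyst <- build_low_rank_gp(k, ref, r = 12, dense_limit = 0,
                              m = ceiling(nrow(ref$vertices) / 2), seed = 7)
    q <- length(unique(dense$field_scalar[1:12]))
    rel <- abs(nyst$scalar_values[1:q] - dense$scalar_values[1:q]) /
      dense$scalar_values[1:q]
    expect_lt(max(rel), 0.10)
  }
})

test_that("a vanishing kernel yields vanishing variances", {
  ref <- make_reference_organ(150)
  gp <- build_low_rank_gp(gaussian_kernel(1e-30, 30), ref, r = 5)
  expect_lte(max(gp$variances), 1e-20)
})

test_that("KL sampling is linear with the correct analytic covariance", {
  ref <- make_reference_organ(200)
  gp <- build_low_rank_gp(gaussian_kernel(1, 40), ref, r = 21)
  expect_equal(sample_deformation(gp, numeric(gp$r)), gp$mean_field,
               tolerance = 1e-14)
  set.seed(2)
  a <- rnorm(gp$r)
  b <- rnorm(gp$r)
  expect_equal(sample_deformation(gp, a + b) - gp$mean_field,
               (sample_deformation(gp, a) - gp$mean_field) +
                 (sample_deformation(gp, b) - gp$mean_field),
               tolerance = 1e-10)
  expect_error(sample_deformation(gp, numeric(gp$r + 2)), "length")
  # orthonormal basis fields under the discrete vertex inner product
  Fm <- sapply(gp_basis_fields(gp), as.vector)
  expect_lt(max(abs(crossprod(Fm) - diag(gp$r))), 1e-6)
})

test_that("correspondence recovers in-span targets and stays monotone", {
  ref <- make_reference_organ(300)
  prior <- correspondence_prior(ref, r = 30, seed = 3)
  # self-correspondence: zero field is optimal
  self <- establish_correspondence(prior, ref, max_sweeps = 10)
  expect_lte(mean(sqrt(rowSums(self$field^2))), 1e-6)
  set.seed(6)
  atrue <- rnorm(30) * 0.8
  target <- surface_mesh(ref$vertices + sample_deformation(prior, atrue),
                         ref$faces)
  cor <- establish_correspondence(prior, target, max_sweeps = 40)
  expect_lt(sqrt(sum((cor$alpha - atrue)^2)) / sqrt(sum(atrue^2)), 0.05)
  # residual below the typical mesh edge length
  e1 <- ref$vertices[ref$faces[, 1], ] - ref$vertices[ref$faces[, 2], ]
  expect_lt(cor$residual, stats::median(sqrt(rowSums(e1^2))))
  expect_true(all(diff(cor$trace) <= 1e-12))
})

test_that("empirical GP reproduces the direct mean and covariance", {
  ref <- make_reference_organ(150)
  gp <- build_low_rank_gp(gaussian_kernel(1, 40), ref, r = 9)
  set.seed(5)
  fields <- lapply(1:12, function(i) sample_deformation(gp, rnorm(9)))
  eg <- build_empirical_gp(fields, ref)
  mu <- Reduce(`+`, fields) / 12
  expect_lt(max(abs(eg$mean_field - mu)), 1e-12)
  expect_lte(eg$r, 11) # rank <= N - 1
  dev <- lapply(fields, function(f) f - mu)
  set.seed(6)
  for (pair in 1:10) {
    i <- sample(150, 1)
    j <- sample(150, 1)
    blk <- matrix(0, 3, 3)
    for (f in dev) blk <- blk + f[i, ] %*% t(f[j, ])
    blk <- blk / 11 # 1/(N-1)
    expect_lt(max(abs(empirical_cov_block(eg, i, j) - blk)), 1e-10)
  }
  expect_error(build_empirical_gp(fields[1]), "at least 2")
})

test_that("empirical variances estimate the truth and improve with N", {
  ref <- make_reference_organ(150)
  gp <- build_low_rank_gp(gaussian_kernel(1, 50), ref, r = 3)
  errs <- sapply(1:5, function(rep) {
    set.seed(100 + rep)
    sapply(c(10, 200), function(N) {
      fields <- lapply(seq_len(N), function(i) sample_deformation(gp, rnorm(3)))
      eg <- build_empirical_gp(fields)
      abs(eg$variances[1] - gp$variances[1]) / gp$variances[1]
    })
  })
  # at N = 50 the leading variance is within 30% (median over reps)
  set.seed(7)
  fields50 <- lapply(1:50, function(i) sample_deformation(gp, rnorm(3)))
  expect_lt(abs(build_empirical_gp(fields50)$variances[1] - gp$variances[1]) /
              gp$variances[1], 0.3)
  # error shrinks from N = 10 to N = 200 (median over 5 repetitions)
  expect_lt(stats::median(errs[2, ]), stats::median(errs[1, ]))
})

test_that("GPMM fitting is seeded-deterministic and span-confined", {
  cohort <- small_cohort()
  tr <- 1:4
  lms <- lapply(cohort$cases[tr], function(x) x$mesh$vertices)
  fields <- lapply(lms, function(lm) lm - cohort$reference$vertices)
  eg <- build_empirical_gp(fields, cohort$reference)
  prof <- build_profile_model(lapply(cohort$cases[tr], `[[`, "image"), lms,
                              cohort$reference$faces,
                              asm_config(resolutions = 1))
  target <- cohort$cases[[5]]$image
  init <- init_shape_moments(target,
                             cohort$reference$vertices + eg$mean_field,
                             cohort$reference$faces)
  pose <- similarity3d(diag(3), init$pose$translation, 1, init$pose$center)
  # zero iterations return the posed mean shape
  f0 <- fit_gpmm(target, eg, prof, pose, iterations = 0, refine_sweeps = 0)
  expect_equal(f0$mesh$vertices,
               apply_transform(pose, cohort$reference$vertices + eg$mean_field),
               tolerance = 1e-12)
  f1 <- fit_gpmm(target, eg, prof, pose, iterations = 15, candidates = 5,
                 refine_sweeps = 1, seed = 9)
  f2 <- fit_gpmm(target, eg, prof, pose, iterations = 15, candidates = 5,
                 refine_sweeps = 1, seed = 9)
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$mask$voxels, f2$mask$voxels)
  f3 <- fit_gpmm(target, eg, prof, pose, iterations = 15, candidates = 5,
                 refine_sweeps = 1, seed = 10)
  expect_false(identical(f1$alpha, f3$alpha))
  # accepted state lies in the model span: reconstruct from alpha exactly
  rec <- apply_transform(pose, cohort$reference$vertices +
                           sample_deformation(eg, f1$alpha))
  expect_equal(f1$mesh$vertices, rec, tolerance = 1e-12)
})

test_that("self-consistent recovery: fitting a shape drawn from the model", {
  cohort <- small_cohort()
  tr <- 1:4
  lms <- lapply(cohort$cases[tr], function(x) x$mesh$vertices)
  fields <- lapply(lms, function(lm) lm - cohort$reference$vertices)
  eg <- build_empirical_gp(fields, cohort$reference)
  prof <- build_profile_model(lapply(cohort$cases[tr], `[[`, "image"), lms,
                              cohort$reference$faces,
                              asm_config(resolutions = 1))
  target <- cohort$cases[[6]]$image
  truth <- cohort$cases[[6]]$mask
  init <- init_shape_moments(target,
                             cohort$reference$vertices + eg$mean_field,
                             cohort$reference$faces)
  pose <- similarity3d(diag(3), init$pose$translation, 1, init$pose$center)
  fit <- fit_gpmm(target, eg, prof, pose, iterations = 100, candidates = 10,
                  seed = 1)
  expect_gte(dice(fit$mask, truth), 90)
})
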