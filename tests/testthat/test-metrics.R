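test_that("Dice handles identity, disjoint and hand-built overlap cases", {
  m <- ball_mask(6, 24L, 2)
  expect_identical(dice(m, m), 100)
  a <- label_mask(array(0L, c(4, 4, 4)))
  b <- label_mask(array(0L, c(4, 4, 4)))
  a$voxels[1:2, 1, 1] <- 1L
  b$voxels[3:4, 4, 4] <- 1L
  expect_identical(dice(a, b), 0)
  # |a| = 4, |b| = 4, overlap 2 -> 50%
  a2 <- label_mask(array(0L, c(4, 4, 2)))
  b2 <- label_mask(array(0L, c(4, 4, 2)))
  a2$voxels[1:2, 1:2, 1] <- 1L
  b2$voxels[2:3, 1:2, 1] <- 1L
  expect_identical(dice(a2, b2), 50)
  expect_message(val <- dice(label_mask(array(0L, c(3, 3, 3))),
                             label_mask(array(0L, c(3, 3, 3)))), "empty")
  expect_identical(val, 100)
  expect_error(dice(m, a), "different grids")
})

test_that("surface distances match the brute-force all-pairs oracle", {
  set.seed(1)
  for (rep in 1:3) {
    A <- matrix(rnorm(600), 200, 3)
    B <- matrix(rnorm(600), 200, 3) + 0.5
    D <- as.matrix(dist(rbind(A, B)))[1:200, 201:400]
    msd_oracle <- (sum(apply(D, 1, min)) + sum(apply(D, 2, min))) / 400
    h_oracle <- max(max(apply(D, 1, min)), max(apply(D, 2, min)))
    expect_equal(mean_surface_distance(A, B), msd_oracle, tolerance = 1e-10)
    expect_equal(hausdorff(A, B), h_oracle, tolerance = 1e-10)
  }
})

test_that("closed-form distance cases hold", {
  A <- as.matrix(expand.grid(seq(0, 10), seq(0, 10), 0))
  B <- cbind(A[, 1:2], 3) # parallel planar patches 3 mm apart
  expect_equal(mean_surface_distance(A, B), 3, tolerance = 1e-12)
  expect_equal(hausdorff(matrix(c(0, 0, 0), 1), matrix(c(0, 0, 5), 1)), 5,
               tolerance = 1e-12)
  expect_identical(mean_surface_distance(A, A), 0)
  expect_identical(hausdorff(A, A), 0)
})

test_that("hausdorff is symmetric and satisfies the triangle inequality", {
  set.seed(2)
  for (rep in 1:5) {
    A <- matrix(rnorm(60), 20, 3)
    B <- matrix(rnorm(60), 20, 3)
    C <- matrix(rnorm(60), 20, 3)
    expect_equal(hausdorff(A, B), hausdorff(B, A), tolerance = 1e-12)
    expect_lte(hausdorff(A, C), hausdorff(A, B) + hausdorff(B, C) + 1e-12)
  }
})

test_that("distances are translation-invariant; dice symmetric on random pairs", {
  set.seed(3)
  A <- matrix(rnorm(300), 100, 3)
  B <- matrix(rnorm(300), 100, 3)
  t <- c(7, -3, 11)
  expect_equal(mean_surface_distance(A, B),
               mean_surface_distance(sweep(A, 2, t, "+"), sweep(B, 2, t, "+")),
               tolerance = 1e-10)
  expect_equal(hausdorff(A, B),
               hausdorff(sweep(A, 2, t, "+"), sweep(B, 2, t, "+")),
               tolerance = 1e-10)
  for (rep in 1:20) {
    d <- c(6, 6, 6)
    m1 <- label_mask(array(as.integer(runif(216) > 0.5), d))
    m2 <- label_mask(array(as.integer(runif(216) > 0.5), d))
    expect_identical(dice(m1, m2), dice(m2, m1))
  }
})

test_that("evaluate_case reports all three measures coherently", {
  m <- ball_mask(8, 32L, 2)
  rep0 <- evaluate_case(m, m, "self")
  expect_identical(rep0$dice_percent, 100)
  expect_identical(rep0$msd_mm, 0)
  expect_identical(rep0$hausdorff_mm, 0)
  # dilate by one voxel
  d <- dim(m$voxels)
  dil <- m$voxels
  for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))) {
    shifted <- array(0L, d)
    src <- list(1:d[1] - sh[1], 1:d[2] - sh[2], 1:d[3] - sh[3])
    ok <- lapply(src, function(ix) ix[ix >= 1 & ix <= d[1]])
    shifted[(1:d[1])[src[[1]] %in% ok[[1]]],
            (1:d[2])[src[[2]] %in% ok[[2]]],
            (1:d[3])[src[[3]] %in% ok[[3]]]] <-
      m$voxels[ok[[1]], ok[[2]], ok[[3]]]
    dil <- pmax(dil, shifted)
  }
  dm <- label_mask(dil, m$spacing, m$origin)
  repd <- evaluate_case(dm, m, "dilated")
  expect_lt(repd$dice_percent, 100)
  expect_lte(repd$msd_mm, repd$hausdorff_mm)
  # serializes as one CSV row
  td <- withr::local_tempdir()
  utils::write.csv(repd, file.path(td, "r.csv"), row.names = FALSE)
  back <- utils::read.csv(file.path(td, "r.csv"))
  expect_identical(nrow(back), 1L)
  expect_identical(names(back),
                   c("case_id", "dice_percent", "msd_mm", "hausdorff_mm"))
})
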