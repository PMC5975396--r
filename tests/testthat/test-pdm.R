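random_shape <- function(n = 25, seed = 1) {
  set.seed(seed)
  cbind(rnorm(n), rnorm(n), rnorm(n))
}

test_that("Procrustes alignment collapses similarity-transformed copies", {
  base <- random_shape()
  set.seed(2)
  shapes <- lapply(1:5, function(i)
    sweep(runif(1, 0.5, 2) * base %*% t(euler_rotation(runif(3, -0.5, 0.5))),
          2, rnorm(3, 0, 5), "+"))
  al <- procrustes_align(shapes)
  for (i in 2:5)
    expect_lt(sqrt(mean((al$aligned[[i]] - al$aligned[[1]])^2)), 1e-8)
  expect_true(all(diff(al$ss_trace) <= 1e-12))
})

test_that("mirror images align without reflection and keep residual", {
  base <- random_shape(40, 3)
  mirror <- base %*% diag(c(-1, 1, 1))
  al <- procrustes_align(list(base, mirror))
  # no reflection allowed, so the mirrored shape cannot be matched exactly
  expect_gt(sum((al$aligned[[1]] - al$aligned[[2]])^2), 1e-4)
  fit <- ssmseg:::procrustes_fit(mirror, base)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
})

test_that("degenerate shapes are rejected", {
  pt <- matrix(1, 5, 3)
  expect_error(procrustes_align(list(pt, random_shape(5))), "degenerate")
})

test_that("PDM covariance matches the direct double-sum and its spectrum", {
  set.seed(4)
  base <- random_shape(20, 5)
  shapes <- lapply(1:8, function(i) base + matrix(rnorm(60, sd = 0.2), 20, 3))
  al <- procrustes_align(shapes)
  pdm <- build_pdm(al$aligned, list(type = "fixed", t = 7))
  # direct Eq-style oracle: (1/N) sum dX dX'
  X <- vapply(al$aligned, as.vector, numeric(60))
  D <- X - rowMeans(X)
  S <- matrix(0, 60, 60)
  for (i in 1:8) S <- S + D[, i] %*% t(D[, i])
  S <- S / 8
  recon <- pdm$modes %*% diag(pdm$variances) %*% t(pdm$modes)
  expect_lt(max(abs(S - recon)), 1e-10)
  expect_lt(max(abs(crossprod(pdm$modes) - diag(pdm$t))), 1e-8)
  expect_true(all(diff(pdm$variances) <= 1e-12))
  expect_true(all(pdm$variances >= 0))
  expect_lte(sum(pdm$variances > 1e-12 * pdm$variances[1]), 7) # <= N - 1
  expect_lt(abs(sum(pdm$variances) - sum(diag(S))), 1e-8 * sum(diag(S)))
})

test_that("identical shapes give zero variance and the shape as mean", {
  s <- random_shape(15, 6)
  pdm <- build_pdm(list(s, s, s))
  expect_equal(matrix(pdm$mean_shape, 15, 3), s, tolerance = 1e-12)
  expect_identical(pdm$t, 0L)
})

test_that("synthesis, projection and clamping behave as a linear model", {
  set.seed(7)
  base <- random_shape(20, 8)
  shapes <- lapply(1:6, function(i) base + matrix(rnorm(60, sd = 0.3), 20, 3))
  al <- procrustes_align(shapes)
  pdm <- build_pdm(al$aligned, list(type = "fixed", t = 5))
  expect_equal(synthesize_shape(pdm, numeric(pdm$t)),
               matrix(pdm$mean_shape, 20, 3), tolerance = 1e-12)
  expect_equal(project_shape(pdm, matrix(pdm$mean_shape, 20, 3)),
               numeric(pdm$t), tolerance = 1e-12)
  # full-rank reconstruction of a training shape
  b <- project_shape(pdm, al$aligned[[3]])
  expect_lt(max(abs(synthesize_shape(pdm, b) - al$aligned[[3]])), 1e-8)
  # clamping at 3 sd
  b2 <- numeric(pdm$t)
  b2[1] <- 10 * sqrt(pdm$variances[1])
  b3 <- numeric(pdm$t)
  b3[1] <- 3 * sqrt(pdm$variances[1])
  expect_equal(synthesize_shape(pdm, b2, clamp = TRUE),
               synthesize_shape(pdm, b3), tolerance = 1e-12)
  expect_error(synthesize_shape(pdm, numeric(pdm$t + 1)), "length")
  # out-of-span residual equals the orthogonal complement norm
  s_out <- al$aligned[[1]] + matrix(rnorm(60, sd = 0.1), 20, 3)
  res <- s_out - synthesize_shape(pdm, project_shape(pdm, s_out))
  v <- as.vector(s_out) - pdm$mean_shape
  orth <- v - pdm$modes %*% crossprod(pdm$modes, v)
  expect_equal(sqrt(sum(res^2)), sqrt(sum(orth^2)), tolerance = 1e-10)
})

test_that("landmark tables round-trip through CSV and JSON", {
  td <- withr::local_tempdir()
  pts <- random_shape(12, 11)
  rownames(pts) <- sprintf("L%02d", 1:12)
  for (f in c("lm.csv", "lm.json")) {
    write_landmarks(pts, file.path(td, f))
    back <- read_landmarks(file.path(td, f))
    expect_equal(unname(back), unname(pts), tolerance = 1e-12)
    expect_identical(rownames(back), rownames(pts))
  }
  utils::write.csv(data.frame(a = 1), file.path(td, "bad.csv"),
                   row.names = FALSE)
  expect_error(read_landmarks(file.path(td, "bad.csv")), "columns")
})

test_that("parameter recovery: eigenvalues of a known 3-mode model", {
  # eigenvalue estimates at N = 50 fluctuate with sd ~ sqrt(2/N) = 20%, so
  # a single draw of the worst of three modes exceeds 25% regularly; the
  # bound is checked on the median over repetitions
  n <- 40
  mean_s <- random_shape(n, 10)
  errs <- sapply(1:5, function(rep) {
    set.seed(100 + rep)
    modes <- qr.Q(qr(matrix(rnorm(3 * n * 3), 3 * n, 3)))
    lam <- c(4, 2, 1)
    shapes <- lapply(1:50, function(i) {
      b <- rnorm(3) * sqrt(lam)
      matrix(as.vector(mean_s) + modes %*% b, n, 3)
    })
    pdm <- build_pdm(shapes, list(type = "fixed", t = 3))
    max(abs(pdm$variances - lam) / lam)
  })
  expect_lt(stats::median(errs), 0.25)
})
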