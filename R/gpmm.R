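#' @title Gaussian Process Morphable Models
#' @description Deformations of a reference surface are modeled as a
#'   Gaussian process `u ~ GP(mu, k)` with a matrix-valued kernel, used
#'   through its low-rank Karhunen-Loeve expansion
#'   `u = mu + sum_i alpha_i sqrt(lambda_i) phi_i`.  Analytic (Gaussian)
#'   kernels define smooth priors for correspondence; empirical deformation
#'   statistics over a training set define the shape model used for
#'   segmentation.
#' @name gpmm
NULL

#' Gaussian (radial) deformation kernel
#'
#' `k(x, y) = s * exp(-||x - y||^2 / sigma^2) * I3`.  Kernels can be added
#' with `+` and scaled with `*`.
#'
#' @param s positive scale (variance units, mm^2).
#' @param sigma positive bandwidth (mm).
#' @return object of class `gp_kernel`.
#' @export
gaussian_kernel <- function(s, sigma) {
  if (!is.numeric(s) || s <= 0 || !is.numeric(sigma) || sigma <= 0)
    stop("kernel parameters must be positive")
  structure(list(terms = list(list(s = s, sigma = sigma))), class = "gp_kernel")
}

#' @export
`+.gp_kernel` <- function(e1, e2) {
  stopifnot(inherits(e1, "gp_kernel"), inherits(e2, "gp_kernel"))
  structure(list(terms = c(e1$terms, e2$terms)), class = "gp_kernel")
}

#' @export
`*.gp_kernel` <- function(e1, e2) {
  if (is.numeric(e1)) { k <- e2; f <- e1 } else { k <- e1; f <- e2 }
  stopifnot(inherits(k, "gp_kernel"), is.numeric(f), f > 0)
  k$terms <- lapply(k$terms, function(t) { t$s <- t$s * f; t })
  k
}

# scalar part of the (isotropic) kernel on point sets: n x m matrix
kernel_gram <- function(kernel, X, Y) {
  X <- matrix(as.numeric(X), ncol = 3)
  Y <- matrix(as.numeric(Y), ncol = 3)
  d2 <- outer(rowSums(X^2), rep(1, nrow(Y))) +
    outer(rep(1, nrow(X)), rowSums(Y^2)) - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  G <- matrix(0, nrow(X), nrow(Y))
  for (t in kernel$terms) G <- G + t$s * exp(-d2 / t$sigma^2)
  G
}

#' Evaluate the matrix-valued kernel at a point pair
#' @param kernel a [gaussian_kernel()] (or sum of them).
#' @param x,y length-3 world points (mm).
#' @return 3 x 3 matrix.
#' @export
kernel_eval <- function(kernel, x, y) {
  as.numeric(kernel_gram(kernel, matrix(x, 1), matrix(y, 1))) * diag(3)
}

#' Low-rank Karhunen-Loeve expansion of a GP on a reference surface
#'
#' Eigendecomposition of the kernel restricted to the reference vertices.
#' Exact (dense) when `3 * nvertex <= dense_limit` or when `m` covers all
#' vertices; otherwise the Nystrom approximation on `m` uniformly sampled
#' vertices (seeded).  Because the shipped kernels are isotropic, each
#' scalar eigenfunction yields three basis fields (one per axis) sharing an
#' eigenvalue; fields are orthonormal under the discrete vertex inner
#' product.
#'
#' @param kernel a [gaussian_kernel()] (or sum).
#' @param reference a [surface_mesh()].
#' @param r rank: number of basis fields retained.
#' @param m Nystrom sample count (default: all vertices = dense).
#' @param seed RNG seed for the Nystrom sample.
#' @param mean_field optional n x 3 mean deformation (default zero).
#' @param dense_limit size cutoff for the dense path.
#' @return object of class `lowrank_gp` with `reference`, `mean_field`,
#'   scalar eigvectors `U` (n x q), `scalar_values`, per-field `variances`
#'   and index maps, rank `r`, and Nystrom extension data.
#' @export
build_low_rank_gp <- function(kernel, reference, r, m = NULL, seed = 1L,
                              mean_field = NULL, dense_limit = 1000L) {
  V <- reference$vertices
  n <- nrow(V)
  if (is.null(m) || m >= n) m <- n
  if (3L * n <= dense_limit) m <- n
  q_need <- ceiling(r / 3) + 1L
  if (m < q_need) stop("Nystrom sample count too small for requested rank")
  set.seed(seed)
  sel <- if (m == n) seq_len(n) else sort(sample.int(n, m))
  Xm <- V[sel, , drop = FALSE]
  Kmm <- kernel_gram(kernel, Xm, Xm)
  eg <- eigen((Kmm + t(Kmm)) / 2, symmetric = TRUE)
  keep <- eg$values > max(eg$values, 0) * 1e-12
  vals_m <- eg$values[keep]
  U_m <- eg$vectors[, keep, drop = FALSE]
  # Nystrom extension to all vertices, then renormalize over the n vertices
  Knm <- kernel_gram(kernel, V, Xm)
  U <- Knm %*% sweep(U_m, 2, vals_m, "/")
  nrms <- sqrt(colSums(U^2))
  ok <- nrms > 1e-12
  U <- sweep(U[, ok, drop = FALSE], 2, nrms[ok], "/")
  scalar_vals <- (n / m) * vals_m[ok]
  # extension coefficients: phi_j(x) = k(x, Xm) %*% ext[, j]
  ext <- sweep(U_m[, ok, drop = FALSE], 2, vals_m[ok] * nrms[ok], "/")
  q <- ncol(U)
  avail <- 3L * q
  if (r > avail) {
    warning(sprintf("rank truncated to available spectrum: %d", avail))
    r <- avail
  }
  # interleave axes: field i -> (scalar ceil(i/3), axis (i-1) %% 3 + 1)
  field_scalar <- rep(seq_len(q), each = 3)[seq_len(r)]
  field_axis <- rep(1:3, q)[seq_len(r)]
  variances <- scalar_vals[field_scalar]
  if (is.null(mean_field)) mean_field <- matrix(0, n, 3)
  structure(list(reference = reference, mean_field = mean_field,
                 U = U, scalar_values = scalar_vals,
                 field_scalar = field_scalar, field_axis = field_axis,
                 variances = variances, r = r,
                 kernel = kernel, inducing = Xm, ext = ext,
                 m = m, seed = seed),
            class = "lowrank_gp")
}

#' Materialize the basis fields of a low-rank GP
#' @param gp a [build_low_rank_gp()] model.
#' @return list of r n x 3 matrices (orthonormal over vertices).
#' @export
gp_basis_fields <- function(gp) {
  lapply(seq_len(gp$r), function(i) {
    f <- matrix(0, nrow(gp$U), 3)
    f[, gp$field_axis[i]] <- gp$U[, gp$field_scalar[i]]
    f
  })
}

#' Draw a deformation field from KL coefficients
#'
#' `field = mu + sum_i alpha_i sqrt(lambda_i) phi_i`.
#'
#' @param gp a [build_low_rank_gp()] (or empirical) model.
#' @param alpha coefficient vector of length `gp$r`.
#' @return n x 3 deformation field (mm).
#' @export
sample_deformation <- function(gp, alpha) UseMethod("sample_deformation")

#' @export
sample_deformation.lowrank_gp <- function(gp, alpha) {
  if (length(alpha) != gp$r) stop("alpha must have length r")
  f <- gp$mean_field
  if (gp$r == 0) return(f)
  w <- alpha * sqrt(gp$variances)
  for (ax in 1:3) {
    sel <- gp$field_axis == ax
    if (any(sel))
      f[, ax] <- f[, ax] +
        gp$U[, gp$field_scalar[sel], drop = FALSE] %*% w[sel]
  }
  f
}

#' Evaluate a low-rank GP deformation at arbitrary surface points
#'
#' Nystrom extension of the eigenfunctions: the same KL coefficients
#' produce a consistent field at any point set (used to carry known
#' deformations across mesh resolutions).
#'
#' @param gp a [build_low_rank_gp()] model.
#' @param alpha coefficient vector of length `gp$r`.
#' @param pts n x 3 points (mm).
#' @return n x 3 deformation field.
#' @export
sample_deformation_at <- function(gp, alpha, pts) {
  if (length(alpha) != gp$r) stop("alpha must have length r")
  pts <- matrix(as.numeric(pts), ncol = 3)
  Phi <- kernel_gram(gp$kernel, pts, gp$inducing) %*% gp$ext # npts x q scalar
  f <- matrix(0, nrow(pts), 3)
  w <- alpha * sqrt(gp$variances)
  for (ax in 1:3) {
    sel <- gp$field_axis == ax
    if (any(sel))
      f[, ax] <- Phi[, gp$field_scalar[sel], drop = FALSE] %*% w[sel]
  }
  f
}

#' GP-regularized correspondence between a reference and a target surface
#'
#' Minimizes the symmetric mean closest-point distance between the deformed
#' reference vertices and the target vertices over the KL coefficients of
#' the prior (the low-rank expansion itself acting as the regularizer, plus
#' a mild quadratic penalty), by coordinate descent with step shrinking.
#'
#' @param prior a [build_low_rank_gp()] on the reference surface.
#' @param target a [surface_mesh()].
#' @param max_sweeps coordinate-descent sweeps over all coefficients.
#' @param step0 initial coefficient step.
#' @param tol stop when a full sweep improves the objective by less.
#' @param penalty weight of the `||alpha||^2` regularizer.
#' @return list with `field` (per-reference-vertex u_i), `alpha`,
#'   `residual` (mean symmetric distance, mm), `trace`, `converged`.
#' @export
establish_correspondence <- function(prior, target, max_sweeps = 30L,
                                     step0 = 1, tol = 1e-6, penalty = 1e-6) {
  ref <- prior$reference$vertices
  tv <- target$vertices
  obj <- function(alpha) {
    def <- ref + sample_deformation(prior, alpha)
    d1 <- cpp_closest_dists(def, tv)
    d2 <- cpp_closest_dists(tv, def)
    (sum(d1) + sum(d2)) / (length(d1) + length(d2)) +
      penalty * sum(alpha^2)
  }
  alpha <- numeric(prior$r)
  cur <- obj(alpha)
  trace <- cur
  steps <- rep(step0, prior$r)
  converged <- FALSE
  for (sw in seq_len(max_sweeps)) {
    prev <- cur
    for (i in seq_len(prior$r)) {
      improved <- FALSE
      for (dir in c(1, -1)) {
        cand <- alpha
        cand[i] <- cand[i] + dir * steps[i]
        v <- obj(cand)
        # continue in an improving direction while it keeps paying off
        while (v < cur - 1e-12) {
          alpha <- cand
          cur <- v
          improved <- TRUE
          cand[i] <- cand[i] + dir * steps[i]
          v <- obj(cand)
        }
        if (improved) break
      }
      if (improved) steps[i] <- steps[i] * 1.5
      else steps[i] <- max(steps[i] * 0.5, 1e-5)
    }
    trace <- c(trace, cur)
    if (prev - cur < tol) {
      converged <- TRUE
      break
    }
  }
  # closest-point projection polish: match each deformed vertex to its
  # nearest target vertex and ridge-project the implied field onto the KL
  # basis (iterated); escapes the flat regions coordinate steps cannot
  # cross.  The best state by the original objective is kept.
  Phi <- matrix(0, 3L * nrow(ref), prior$r)
  for (i in seq_len(prior$r)) {
    f <- matrix(0, nrow(ref), 3)
    f[, prior$field_axis[i]] <- prior$U[, prior$field_scalar[i]]
    Phi[, i] <- as.vector(f) * sqrt(prior$variances[i])
  }
  shrink <- prior$variances / (prior$variances + penalty)
  acur <- alpha
  for (it in seq_len(2L * max_sweeps)) {
    def <- ref + sample_deformation(prior, acur)
    nn <- apply_nn_match(def, tv)
    u <- as.vector(tv[nn, , drop = FALSE] - ref)
    anew <- shrink * as.numeric(crossprod(Phi, u)) / prior$variances
    if (max(abs(anew - acur)) < 1e-10) break
    acur <- anew
    v <- obj(acur)
    if (v < cur - 1e-12) {
      alpha <- acur
      cur <- v
      trace <- c(trace, cur)
    }
  }
  field <- sample_deformation(prior, alpha)
  def <- ref + field
  d1 <- cpp_closest_dists(def, tv)
  d2 <- cpp_closest_dists(tv, def)
  list(field = field, alpha = alpha,
       residual = (sum(d1) + sum(d2)) / (length(d1) + length(d2)),
       trace = trace, converged = converged)
}

# index of the nearest row of B for each row of A
apply_nn_match <- function(A, B) {
  d <- cpp_closest_dists(A, B)
  # recover indices by matching distances is fragile; do a direct search in
  # blocks (sizes here are small)
  idx <- integer(nrow(A))
  bs <- 512L
  for (start in seq(1L, nrow(A), by = bs)) {
    end <- min(start + bs - 1L, nrow(A))
    cross <- outer(rowSums(A[start:end, , drop = FALSE]^2), rep(1, nrow(B))) +
      outer(rep(1, end - start + 1L), rowSums(B^2)) -
      2 * tcrossprod(A[start:end, , drop = FALSE], B)
    idx[start:end] <- max.col(-cross, ties.method = "first")
  }
  idx
}

#' Default correspondence prior for a reference surface
#'
#' Gaussian kernel with bandwidth 0.3 x the reference bounding-box diagonal
#' and scale chosen so the expected per-vertex displacement magnitude (RMS
#' of the 3-vector) is 5 percent of the diagonal.
#'
#' @param reference a [surface_mesh()].
#' @param r rank (default `min(100, spectrum)`).
#' @param seed Nystrom seed.
#' @return a [build_low_rank_gp()] model.
#' @export
correspondence_prior <- function(reference, r = 100L, seed = 1L) {
  bb <- apply(reference$vertices, 2, range)
  diag_len <- sqrt(sum((bb[2, ] - bb[1, ])^2))
  target_sd <- 0.05 * diag_len
  gp <- build_low_rank_gp(gaussian_kernel(1, 0.3 * diag_len), reference,
                          r = min(r, 3L * nrow(reference$vertices)),
                          seed = seed)
  n <- nrow(reference$vertices)
  fct <- target_sd^2 * n / sum(gp$variances)
  gp$variances <- gp$variances * fct
  gp$scalar_values <- gp$scalar_values * fct
  gp
}

#' Empirical deformation GP from a set of correspondence fields
#'
#' Mean field as the arithmetic mean and covariance with 1/(N-1)
#' normalization, stored as a rank-(N-1) factorization via the Gram-matrix
#' eigendecomposition.
#'
#' @param fields list of N per-reference-vertex n x 3 deformation fields.
#' @param reference optional [surface_mesh()] the fields live on.
#' @return object of class `empirical_gp` with `mean_field`, `basis`
#'   (3n x q, orthonormal columns), `variances`, rank `r`.
#' @export
build_empirical_gp <- function(fields, reference = NULL) {
  N <- length(fields)
  if (N < 2L) stop("need at least 2 deformation fields (covariance undefined)")
  n <- nrow(fields[[1]])
  X <- vapply(fields, as.vector, numeric(3 * n)) # 3n x N
  mu <- rowMeans(X)
  A <- (X - mu) / sqrt(N - 1)
  G <- crossprod(A)
  eg <- eigen(G, symmetric = TRUE)
  keep <- eg$values > max(eg$values, 0) * 1e-10
  vals <- eg$values[keep]
  basis <- A %*% eg$vectors[, keep, drop = FALSE]
  basis <- sweep(basis, 2, sqrt(vals), "/")
  for (qi in seq_len(ncol(basis))) {
    j <- which.max(abs(basis[, qi]))
    if (basis[j, qi] < 0) basis[, qi] <- -basis[, qi]
  }
  structure(list(mean_field = matrix(mu, n, 3), basis = basis,
                 variances = vals, r = length(vals), n = n,
                 reference = reference), class = "empirical_gp")
}

#' @export
sample_deformation.empirical_gp <- function(gp, alpha) {
  if (length(alpha) != gp$r) stop("alpha must have length r")
  f <- as.vector(gp$mean_field)
  if (gp$r > 0) f <- f + gp$basis %*% (alpha * sqrt(gp$variances))
  matrix(f, gp$n, 3)
}

#' Empirical covariance function k_SM(X, Y) at two reference vertices
#' @param gp a [build_empirical_gp()] model.
#' @param i,j vertex indices.
#' @return 3 x 3 covariance block.
#' @export
empirical_cov_block <- function(gp, i, j) {
  ri <- c(i, i + gp$n, i + 2L * gp$n)
  rj <- c(j, j + gp$n, j + 2L * gp$n)
  Bi <- gp$basis[ri, , drop = FALSE]
  Bj <- gp$basis[rj, , drop = FALSE]
  Bi %*% (gp$variances * t(Bj))
}

#' Fit a GPMM to a new volume by stochastic candidate search
#'
#' Segmentation candidates are whole-shape samples from the Gaussian
#' deformation distribution: at every iteration, `candidates` coefficient
#' vectors are drawn around the current best (perturbation scale annealed
#' from `tau0` to `tau1`), each deformed reference is scored by the summed
#' per-vertex Mahalanobis distance of its gray profiles to the trained
#' profile model, and the best is kept.  Every accepted state lies exactly
#' in the model span.
#'
#' @param vol target [vol3d()].
#' @param model a [build_empirical_gp()] with a `reference` mesh.
#' @param profiles a full-resolution [build_profile_model()] level in
#'   correspondence with the reference vertices.
#' @param init a [similarity3d()] posing the model in the volume.
#' @param iterations,candidates search budget.
#' @param tau0,tau1 initial/final perturbation scale (units of mode sd).
#' @param refine_sweeps coordinate pattern-search sweeps over the
#'   coefficients after the stochastic phase (still within the model span).
#' @param seed RNG seed; runs are reproducible given the seed.
#' @return list with `mesh`, `mask`, `alpha`, `score_trace`.
#' @export
fit_gpmm <- function(vol, model, profiles, init = similarity3d(),
                     iterations = 200L, candidates = 20L,
                     tau0 = 1, tau1 = 0.1, refine_sweeps = 6L, seed = 1L) {
  stopifnot(inherits(model, "empirical_gp"), !is.null(model$reference))
  set.seed(seed)
  faces <- model$reference$faces
  lvl <- profiles$levels[[length(profiles$levels)]]
  k <- profiles$k
  score <- function(alpha) {
    pts <- model$reference$vertices + sample_deformation(model, alpha)
    pts <- apply_transform(init, pts)
    nrm <- case_normals(pts, faces)
    s <- cpp_classic_search(as.numeric(vol$voxels), vol_dim(vol), vol$spacing,
                            vol$origin, pts, nrm, 0, k, lvl$step_mm,
                            lvl$mean, lvl$invcov)
    sum(s)
  }
  alpha <- numeric(model$r)
  ctr <- voxel_centers(vol, c(1L, prod(vol_dim(vol))))
  pts0 <- apply_transform(init, model$reference$vertices +
                            sample_deformation(model, alpha))
  if (any(colMeans(pts0) < ctr[1, ]) || any(colMeans(pts0) > ctr[2, ]))
    stop("initial pose places the model outside the volume")
  best <- score(alpha)
  trace <- best
  if (iterations > 0) {
    taus <- tau0 * (tau1 / tau0)^(seq_len(iterations) / iterations)
    for (it in seq_len(iterations)) {
      Z <- matrix(stats::rnorm(candidates * model$r), candidates, model$r)
      for (ci in seq_len(candidates)) {
        cand <- alpha + taus[it] * Z[ci, ]
        v <- score(cand)
        if (v < best) {
          best <- v
          alpha <- cand
        }
      }
      trace <- c(trace, best)
    }
  }
  if (refine_sweeps > 0 && model$r > 0) {
    steps <- rep(0.5, model$r)
    for (sw in seq_len(refine_sweeps)) {
      for (i in seq_len(model$r)) {
        improved <- FALSE
        for (dir in c(1, -1)) {
          cand <- alpha
          cand[i] <- cand[i] + dir * steps[i]
          v <- score(cand)
          while (v < best - 1e-12) {
            alpha <- cand
            best <- v
            improved <- TRUE
            cand[i] <- cand[i] + dir * steps[i]
            v <- score(cand)
          }
          if (improved) break
        }
        steps[i] <- if (improved) steps[i] * 1.5 else max(steps[i] * 0.5, 0.01)
      }
      trace <- c(trace, best)
    }
  }
  pts <- apply_transform(init, model$reference$vertices +
                           sample_deformation(model, alpha))
  mesh <- surface_mesh(pts, faces)
  mask <- surface_to_mask(mesh, vol, tol_frac = 0.05)
  list(mesh = mesh, mask = mask, alpha = alpha, score_trace = trace)
}
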