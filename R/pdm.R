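#' @title Point distribution models
#' @description Procrustes alignment of corresponding landmark sets and PCA
#'   shape statistics: mean shape, covariance (1/N normalization),
#'   eigenmodes, and shape synthesis/projection.  Shapes are n x d matrices
#'   of corresponding landmarks; flattening is column-wise (all x, then all
#'   y, then all z).
#' @name pdm
NULL

check_shape_set <- function(shapes) {
  if (!is.list(shapes) || length(shapes) < 1L) stop("expected a list of shapes")
  shapes <- lapply(shapes, function(s) matrix(as.numeric(s), nrow = nrow(s)))
  n <- nrow(shapes[[1]])
  d <- ncol(shapes[[1]])
  if (n < 3L) stop("shapes need at least 3 landmarks")
  for (s in shapes) {
    if (nrow(s) != n || ncol(s) != d) stop("all shapes must share n and d")
    if (any(!is.finite(s))) stop("landmark coordinates must be finite")
  }
  shapes
}

# least-squares similarity (rotation + scale + translation, det +1) mapping
# X onto Y; returns the transformed X and the parameters
procrustes_fit <- function(X, Y) {
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx)
  Yc <- sweep(Y, 2, cy)
  nx2 <- sum(Xc^2)
  if (nx2 < 1e-24) stop("degenerate shape: all landmarks coincide")
  sv <- svd(crossprod(Xc, Yc))
  sgn <- c(rep(1, ncol(X) - 1), sign(det(sv$u %*% t(sv$v))))
  R <- sv$u %*% diag(sgn, ncol(X)) %*% t(sv$v)
  s <- sum(sv$d * sgn) / nx2
  list(rotation = R, scale = s, aligned = sweep(s * Xc %*% R, 2, cy, "+"))
}

#' Generalized Procrustes alignment of a landmark set
#'
#' Iteratively aligns every shape to the running mean by a least-squares
#' similarity transform (scaling, rotation, translation; reflections
#' excluded), re-estimates the mean, and normalizes the mean to centroid 0
#' and unit Frobenius norm, until the mean changes by less than `tol` or
#' `max_iter` iterations.
#'
#' @param shapes list of n x d landmark matrices in correspondence.
#' @param tol convergence tolerance on the mean update.
#' @param max_iter iteration cap.
#' @return list with `aligned` (list of shapes), `mean` (n x d), and
#'   `ss_trace` (total Procrustes sum of squares per iteration).
#' @export
procrustes_align <- function(shapes, tol = 1e-8, max_iter = 100L) {
  shapes <- check_shape_set(shapes)
  if (length(shapes) < 2L) stop("need at least 2 shapes")
  for (s in shapes)
    if (sum(scale(s, scale = FALSE)^2) < 1e-24)
      stop("degenerate shape: all landmarks coincide")
  normalize <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  mn <- normalize(shapes[[1]])
  aligned <- shapes
  ss_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    aligned <- lapply(shapes, function(s) procrustes_fit(s, mn)$aligned)
    newmn <- normalize(Reduce(`+`, aligned) / length(aligned))
    ss_trace <- c(ss_trace, sum(vapply(aligned,
                                       function(a) sum((a - newmn)^2), 0)))
    if (sqrt(sum((newmn - mn)^2)) < tol) {
      mn <- newmn
      break
    }
    mn <- newmn
  }
  list(aligned = aligned, mean = mn, ss_trace = ss_trace)
}

#' Build a point distribution model from aligned shapes
#'
#' Mean shape, deviations, covariance with 1/N normalization, and its
#' leading eigenmodes.  When `n*d` exceeds the sample count the
#' eigendecomposition is done on the N x N Gram matrix and mapped back to
#' full-space eigenvectors.  Eigenvector signs are fixed so each mode's
#' largest-magnitude component is positive.
#'
#' @param aligned list of n x d aligned shapes (from [procrustes_align()]).
#' @param mode_rule either `list(type = "fixed", t = k)` or
#'   `list(type = "variance", frac = f)` keeping the smallest t explaining
#'   fraction `f` of total variance.
#' @return an object of class `pdm`: `mean_shape` (length n*d), `modes`
#'   (n*d x t, orthonormal), `variances` (descending), `t`, `n`, `d`.
#' @export
build_pdm <- function(aligned, mode_rule = list(type = "variance", frac = 0.98)) {
  aligned <- check_shape_set(aligned)
  N <- length(aligned)
  n <- nrow(aligned[[1]])
  d <- ncol(aligned[[1]])
  X <- vapply(aligned, as.vector, numeric(n * d)) # nd x N
  mn <- rowMeans(X)
  D <- X - mn
  if (N == 1L) {
    warning("single shape: covariance is identically zero")
    return(structure(list(mean_shape = mn, modes = matrix(0, n * d, 0),
                          variances = numeric(0), t = 0L, n = n, d = d),
                     class = "pdm"))
  }
  if (n * d <= N) {
    S <- tcrossprod(D) / N
    eg <- eigen(S, symmetric = TRUE)
    vals <- pmax(eg$values, 0)
    vecs <- eg$vectors
  } else {
    G <- crossprod(D) / N # N x N Gram
    eg <- eigen(G, symmetric = TRUE)
    keep <- eg$values > max(eg$values, 0) * 1e-12
    vals <- eg$values[keep]
    vecs <- D %*% eg$vectors[, keep, drop = FALSE]
    vecs <- sweep(vecs, 2, sqrt(N * vals), "/")
  }
  ord <- order(vals, decreasing = TRUE)
  vals <- vals[ord]
  vecs <- vecs[, ord, drop = FALSE]
  pos <- vals > max(vals, 0) * 1e-12
  vals <- vals[pos]
  vecs <- vecs[, pos, drop = FALSE]
  t <- if (identical(mode_rule$type, "fixed")) {
    min(as.integer(mode_rule$t), length(vals))
  } else {
    if (sum(vals) == 0) 0L
    else which(cumsum(vals) / sum(vals) >= mode_rule$frac)[1]
  }
  vecs <- vecs[, seq_len(t), drop = FALSE]
  vals <- vals[seq_len(t)]
  for (q in seq_len(t)) {
    j <- which.max(abs(vecs[, q]))
    if (vecs[j, q] < 0) vecs[, q] <- -vecs[, q]
  }
  structure(list(mean_shape = mn, modes = vecs, variances = vals,
                 t = t, n = n, d = d), class = "pdm")
}

#' @export
print.pdm <- function(x, ...) {
  cat(sprintf("<pdm> %d landmarks x %dD, %d modes\n", x$n, x$d, x$t))
  invisible(x)
}

#' Read and write landmark tables
#'
#' CSV tables have columns `id, x, y, z` (id is the correspondence label,
#' shared across a set); JSON files store the same records.
#'
#' @param path file ending in `.csv` or `.json`.
#' @return n x 3 matrix of landmark coordinates ordered by id, with the ids
#'   as rownames.
#' @export
read_landmarks <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
               csv = utils::read.csv(path),
               json = as.data.frame(jsonlite::read_json(path,
                                                        simplifyVector = TRUE)),
               stop("unknown landmark format: .", ext))
  if (!all(c("id", "x", "y", "z") %in% names(df)))
    stop("landmark table needs columns id, x, y, z")
  df <- df[order(df$id), ]
  m <- as.matrix(df[, c("x", "y", "z")])
  rownames(m) <- df$id
  m
}

#' @rdname read_landmarks
#' @param points n x 3 landmark matrix (rownames used as ids if present).
#' @export
write_landmarks <- function(points, path) {
  ids <- rownames(points)
  if (is.null(ids)) ids <- seq_len(nrow(points))
  df <- data.frame(id = ids, x = points[, 1], y = points[, 2], z = points[, 3])
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         csv = utils::write.csv(df, path, row.names = FALSE),
         json = jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA),
         stop("unknown landmark format: .", ext))
  invisible(path)
}

#' Synthesize a shape from mode coefficients
#'
#' Returns `mean + P b` reshaped to landmarks.  With `clamp = TRUE` each
#' coefficient is limited to `b_limit * sqrt(lambda_i)` before synthesis.
#'
#' @param pdm a [build_pdm()] model.
#' @param b coefficient vector of length `pdm$t`.
#' @param clamp limit coefficients to the model's plausible range.
#' @param b_limit clamp bound in units of mode standard deviations.
#' @return n x d landmark matrix.
#' @export
synthesize_shape <- function(pdm, b, clamp = FALSE, b_limit = 3) {
  if (length(b) != pdm$t) stop("coefficient vector must have length t")
  if (clamp && pdm$t > 0) {
    lim <- b_limit * sqrt(pdm$variances)
    b <- pmin(pmax(b, -lim), lim)
  }
  v <- pdm$mean_shape + if (pdm$t > 0) pdm$modes %*% b else 0
  matrix(v, pdm$n, pdm$d)
}

#' Project a shape onto the model modes
#'
#' `b = P' (flatten(shape) - mean)`.
#'
#' @param pdm a [build_pdm()] model.
#' @param shape n x d landmark matrix matching the model.
#' @return coefficient vector of length `pdm$t`.
#' @export
project_shape <- function(pdm, shape) {
  shape <- as.matrix(shape)
  if (nrow(shape) != pdm$n || ncol(shape) != pdm$d)
    stop("shape dimensions do not match the model")
  as.numeric(crossprod(pdm$modes, as.vector(shape) - pdm$mean_shape))
}
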