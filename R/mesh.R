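#' Triangulated surface mesh
#'
#' Vertices are world coordinates in mm; faces are 1-based triples of vertex
#' indices with consistent (outward) orientation.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (any(!is.finite(vertices))) stop("vertex coordinates must be finite")
  if (nrow(faces) > 0) {
    if (max(faces) > nrow(vertices) || min(faces) < 1L)
      stop("face index out of range")
    if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
              faces[, 2] == faces[, 3]))
      stop("degenerate face repeats a vertex")
  }
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Area-weighted per-vertex normals
#'
#' Face normals (by the right-hand rule on the stored winding) are
#' accumulated at their vertices weighted by face area, then normalized.
#'
#' @param mesh a [surface_mesh()].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) # |fn| = 2 * area
  grp <- c(f[, 1], f[, 2], f[, 3])
  acc <- rowsum(rbind(fn, fn, fn), grp)
  n <- matrix(0, nrow(v), 3)
  n[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Euler characteristic V - E + F
#' @param mesh a [surface_mesh()].
#' @return integer; 2 for a closed genus-0 surface.
#' @export
euler_characteristic <- function(mesh) {
  f <- mesh$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  nrow(mesh$vertices) - length(unique(ekey)) + nrow(f)
}

#' Extract an isosurface mesh from a binary mask
#'
#' Builds the closed boundary surface separating foreground from background
#' voxels: one quad (two triangles) per foreground/background voxel-face
#' pair, placed where linear interpolation between the two voxel centers
#' crosses `iso` (at 0.5, the midpoint).  Vertices are in world mm and faces
#' wind outward.
#'
#' @param mask a [label_mask()].
#' @param iso iso level in (0, 1); vertex positions are offset along their
#'   normals for levels other than 0.5.
#' @param pad if `TRUE`, masks whose foreground touches the grid border are
#'   padded by one background layer instead of raising an error.
#' @return a [surface_mesh()].
#' @export
mask_to_surface <- function(mask, iso = 0.5, pad = FALSE) {
  stopifnot(inherits(mask, "label_mask"), iso > 0, iso < 1)
  m <- mask$voxels
  if (sum(m) == 0) stop("empty mask: no foreground voxels")
  d <- dim(m)
  touches <- any(m[1, , ] > 0) || any(m[d[1], , ] > 0) ||
    any(m[, 1, ] > 0) || any(m[, d[2], ] > 0) ||
    any(m[, , 1] > 0) || any(m[, , d[3]] > 0)
  if (touches) {
    if (!pad) stop("foreground touches the grid border; set pad = TRUE")
    mp <- array(0L, d + 2L)
    mp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
    return(mask_to_surface(label_mask(mp, mask$spacing,
                                      mask$origin - mask$spacing), iso))
  }
  # pad with background so every boundary face is found by shifting
  dp <- d + 2L
  mp <- array(0L, dp)
  mp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  fg <- which(mp == 1L)
  ind <- arrayInd(fg, dp)
  sx <- 1L; sy <- dp[1]; sz <- dp[1] * dp[2]
  strides <- c(sx, sy, sz)
  quads <- list()
  qn <- 0L
  # corner key lattice: corner (a,b,c) with a in 0..dp[1] etc.
  ck <- function(a, b, c) a + (dp[1] + 1L) * (b + (dp[2] + 1L) * c)
  for (ax in 1:3) {
    for (dir in c(-1L, 1L)) {
      nb <- fg + dir * strides[ax]
      face <- mp[nb] == 0L
      if (!any(face)) next
      fi <- ind[face, , drop = FALSE] - 1L # 0-based voxel index in padded grid
      a <- fi[, 1]; b <- fi[, 2]; c <- fi[, 3]
      # quad corners (0-based corner lattice), wound so normals point to `dir`
      co <- switch(ax,
        { x <- a + (dir + 1L) / 2L
          list(ck(x, b, c), ck(x, b + 1L, c), ck(x, b + 1L, c + 1L), ck(x, b, c + 1L)) },
        { y <- b + (dir + 1L) / 2L
          list(ck(a, y, c), ck(a, y, c + 1L), ck(a + 1L, y, c + 1L), ck(a + 1L, y, c)) },
        { z <- c + (dir + 1L) / 2L
          list(ck(a, b, z), ck(a + 1L, b, z), ck(a + 1L, b + 1L, z), ck(a, b + 1L, z)) })
      if (dir == -1L) co <- co[c(1, 4, 3, 2)]
      qn <- qn + 1L
      quads[[qn]] <- do.call(cbind, co)
    }
  }
  q <- do.call(rbind, quads)
  keys <- sort(unique(as.vector(q)))
  vmap <- match(as.vector(q), keys)
  qi <- matrix(vmap, nrow(q), 4)
  faces <- rbind(qi[, c(1, 2, 3)], qi[, c(1, 3, 4)])
  # corner (a,b,c) in padded grid -> world on the original grid
  a <- keys %% (dp[1] + 1L)
  rest <- keys %/% (dp[1] + 1L)
  b <- rest %% (dp[2] + 1L)
  c <- rest %/% (dp[2] + 1L)
  corner0 <- cbind(a, b, c) - 1L # back to original-grid voxel indexing
  verts <- sweep((corner0 - 0.5) %*% diag(mask$spacing), 2, mask$origin, "+")
  mesh <- surface_mesh(verts, faces)
  if (iso != 0.5) {
    nrm <- vertex_normals(mesh)
    shift <- (0.5 - iso) * mean(mask$spacing)
    mesh$vertices <- mesh$vertices + shift * nrm
  }
  mesh
}

#' Voxelize a closed surface mesh onto a grid
#'
#' A voxel is foreground iff its center lies inside the closed surface
#' (x-ray crossing parity).
#'
#' @param mesh a closed [surface_mesh()].
#' @param grid a [vol3d()] or [label_mask()] supplying the target grid.
#' @param tol_frac maximum tolerated fraction of rays with inconsistent
#'   (odd) crossing parity before the mesh is declared non-closed.
#' @return a [label_mask()] on the grid of `grid`.
#' @export
surface_to_mask <- function(mesh, grid, tol_frac = 0.002) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(grid, "vol3d"))
  d <- vol_dim(grid)
  res <- cpp_voxelize_mesh(mesh$vertices, mesh$faces - 1L, d,
                           grid$spacing, grid$origin)
  nrays <- prod(d[2:3])
  if (res$n_odd_rays > tol_frac * nrays)
    stop(sprintf("mesh is not closed: %d/%d rays crossed an odd number of faces",
                 res$n_odd_rays, nrays))
  label_mask(array(res$mask, d), grid$spacing, grid$origin)
}
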