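#' Read a triangle mesh from PLY or legacy VTK polydata
#'
#' PLY is supported in `ascii` and `binary_little_endian` flavors; legacy
#' VTK files must be ASCII `POLYDATA` with triangular `POLYGONS`.
#'
#' @param path file path ending in `.ply` or `.vtk`.
#' @return a [surface_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         vtk = read_vtk_polydata(path),
         stop("unknown mesh format: .", ext))
}

#' Write a triangle mesh to PLY or legacy VTK polydata
#'
#' @param mesh a [surface_mesh()].
#' @param path output path ending in `.ply` or `.vtk`.
#' @param binary write binary little-endian PLY (ignored for VTK).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(mesh, path, binary),
         vtk = write_vtk_polydata(mesh, path),
         stop("unknown mesh format: .", ext))
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL
  elements <- list() # name -> list(count, props = list(name, type, is_list, count_type, item_type))
  curr <- NULL
  repeat {
    line <- trimws(readLines(con, n = 1L, warn = FALSE))
    if (length(line) == 0L) stop("truncated PLY header")
    tok <- strsplit(line, "\\s+")[[1]]
    if (tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      curr <- tok[2]
      elements[[curr]] <- list(count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      p <- if (tok[2] == "list")
        list(name = tok[5], is_list = TRUE, count_type = tok[3], item_type = tok[4])
      else list(name = tok[3], is_list = FALSE, type = tok[2])
      elements[[curr]]$props <- c(elements[[curr]]$props, list(p))
    } else if (tok[1] == "end_header") break
  }
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)
  ply_rtype <- function(t)
    switch(t,
           char = , int8 = , uchar = , uint8 = list("integer", 1L, t %in% c("char", "int8")),
           short = , int16 = list("integer", 2L, TRUE),
           ushort = , uint16 = list("integer", 2L, FALSE),
           int = , int32 = , uint = , uint32 = list("integer", 4L, TRUE),
           float = , float32 = list("numeric", 4L, TRUE),
           double = , float64 = list("numeric", 8L, TRUE),
           stop("unknown PLY type: ", t))
  verts <- NULL
  faces <- NULL
  if (fmt == "ascii") {
    lines <- readLines(con, warn = FALSE)
    pos <- 0L
    for (en in names(elements)) {
      el <- elements[[en]]
      chunk <- lines[(pos + 1L):(pos + el$count)]
      pos <- pos + el$count
      if (en == "vertex") {
        nm <- vapply(el$props, `[[`, "", "name")
        vm <- do.call(rbind, lapply(strsplit(trimws(chunk), "\\s+"), as.numeric))
        verts <- vm[, match(c("x", "y", "z"), nm), drop = FALSE]
      } else if (en == "face") {
        fl <- lapply(strsplit(trimws(chunk), "\\s+"), as.integer)
        if (any(vapply(fl, `[[`, 0L, 1L) != 3L))
          stop("only triangular PLY faces are supported")
        faces <- do.call(rbind, lapply(fl, function(r) r[2:4])) + 1L
      }
    }
  } else {
    for (en in names(elements)) {
      el <- elements[[en]]
      if (en == "vertex") {
        nprop <- length(el$props)
        vm <- matrix(0, el$count, nprop)
        types <- lapply(el$props, function(p) ply_rtype(p$type))
        for (r in seq_len(el$count))
          for (q in seq_len(nprop))
            vm[r, q] <- readBin(con, types[[q]][[1]], 1L, types[[q]][[2]],
                                signed = types[[q]][[3]], endian = "little")
        nm <- vapply(el$props, `[[`, "", "name")
        verts <- vm[, match(c("x", "y", "z"), nm), drop = FALSE]
      } else if (en == "face") {
        p <- el$props[[1]]
        ct <- ply_rtype(p$count_type)
        it <- ply_rtype(p$item_type)
        faces <- matrix(0L, el$count, 3)
        for (r in seq_len(el$count)) {
          cnt <- readBin(con, ct[[1]], 1L, ct[[2]], signed = ct[[3]], endian = "little")
          if (cnt != 3L) stop("only triangular PLY faces are supported")
          faces[r, ] <- readBin(con, it[[1]], 3L, it[[2]], signed = it[[3]],
                                endian = "little") + 1L
        }
      }
    }
  }
  if (is.null(verts) || is.null(faces)) stop("PLY missing vertex or face element")
  surface_mesh(verts, faces)
}

write_ply <- function(mesh, path, binary = FALSE) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  hdr <- c("ply",
           paste("format", if (binary) "binary_little_endian" else "ascii", "1.0"),
           paste("element vertex", nv),
           "property double x", "property double y", "property double z",
           paste("element face", nf),
           "property list uchar int vertex_indices",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (binary) {
    writeBin(as.numeric(t(mesh$vertices)), con, size = 8L, endian = "little")
    f0 <- mesh$faces - 1L
    for (r in seq_len(nf)) {
      writeBin(3L, con, size = 1L, endian = "little")
      writeBin(as.integer(f0[r, ]), con, size = 4L, endian = "little")
    }
  } else {
    writeLines(apply(mesh$vertices, 1, function(v)
      paste(sprintf("%.17g", v), collapse = " ")), con)
    writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
  }
  invisible(path)
}

read_vtk_polydata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^# vtk DataFile", lines[1])) stop("not a legacy VTK file: ", path)
  if (toupper(trimws(lines[3])) != "ASCII") stop("only ASCII VTK is supported")
  if (!grepl("POLYDATA", toupper(lines[4]))) stop("only POLYDATA VTK is supported")
  ptline <- grep("^POINTS", lines)[1]
  np <- as.integer(strsplit(trimws(lines[ptline]), "\\s+")[[1]][2])
  nums <- numeric(0)
  i <- ptline + 1L
  while (length(nums) < 3L * np) {
    nums <- c(nums, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1L
  }
  verts <- matrix(nums[1:(3 * np)], ncol = 3, byrow = TRUE)
  pl <- grep("^POLYGONS", lines)[1]
  hdr <- as.integer(strsplit(trimws(lines[pl]), "\\s+")[[1]][2:3])
  ints <- integer(0)
  i <- pl + 1L
  while (length(ints) < hdr[2]) {
    ints <- c(ints, as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1L
  }
  fm <- matrix(ints[1:hdr[2]], ncol = 4, byrow = TRUE)
  if (any(fm[, 1] != 3L)) stop("only triangular VTK polygons are supported")
  surface_mesh(verts, fm[, 2:4] + 1L)
}

write_vtk_polydata <- function(mesh, path) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "ssmseg surface", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nv)), con)
  writeLines(apply(mesh$vertices, 1, function(v)
    paste(sprintf("%.17g", v), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", nf, 4L * nf), con)
  writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
  invisible(path)
}
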