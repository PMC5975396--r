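#' Read a 3D volume from MetaImage or NIfTI
#'
#' Supported formats are MetaImage (`.mhd` header + raw file, or `.mha` with
#' embedded data) and NIfTI-1 (`.nii`, `.nii.gz`).  Spacing and origin are
#' taken from the header; intensities are returned unmodified.  NIfTI files
#' whose orientation matrix is not an axis-aligned scaling are rejected.
#'
#' @param path file path; the extension selects the format.
#' @param as_mask if `TRUE`, validate and return a [label_mask()].
#' @return a [vol3d()] (or [label_mask()]).
#' @export
read_volume <- function(path, as_mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(sub("^.*?(\\.[a-zA-Z0-9.]+)$", "\\1", basename(path)))
  vol <- if (grepl("\\.mhd$|\\.mha$", ext)) {
    read_metaimage(path)
  } else if (grepl("\\.nii$|\\.nii\\.gz$", ext)) {
    read_nifti_volume(path)
  } else {
    stop("unknown volume format: ", ext)
  }
  if (as_mask) label_mask(vol$voxels, vol$spacing, vol$origin) else vol
}

#' Write a 3D volume to MetaImage or NIfTI
#'
#' MetaImage element type is chosen by `type`: `"auto"` stores \{0,1\} masks
#' and small-integer images as unsigned 8-bit and everything else as 64-bit
#' float, so round-trips are lossless at stored precision.
#'
#' @param vol a [vol3d()] or [label_mask()].
#' @param path output path (`.mhd`, `.mha`, `.nii`, `.nii.gz`).
#' @param type one of `"auto"`, `"uint8"`, `"int16"`, `"uint16"`,
#'   `"float32"`, `"float64"` (MetaImage only).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, type = "auto") {
  stopifnot(inherits(vol, "vol3d"))
  if (!dir.exists(dirname(path))) stop("directory not writable: ", dirname(path))
  ext <- tolower(basename(path))
  if (grepl("\\.mhd$|\\.mha$", ext)) {
    write_metaimage(vol, path, type)
  } else if (grepl("\\.nii$|\\.nii\\.gz$", ext)) {
    write_nifti_volume(vol, path)
  } else {
    stop("unknown volume format: ", basename(path))
  }
  invisible(path)
}

meta_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

read_metaimage <- function(path) {
  # header is plain "Key = Value" text; for .mha the raw block follows
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated MetaImage header: ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed MetaImage header line: ", line)
    key <- trimws(kv[1])
    hdr[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (is.null(hdr$NDims) || as.integer(hdr$NDims) != 3L || length(dims) != 3L)
    stop("only 3D MetaImage volumes are supported")
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]])
  else if (!is.null(hdr$Position))
    as.numeric(strsplit(hdr$Position, "\\s+")[[1]]) else c(0, 0, 0)
  tp <- meta_types[[hdr$ElementType]]
  if (is.null(tp)) stop("unsupported ElementType: ", hdr$ElementType)
  msb <- identical(hdr$ElementByteOrderMSB, "True") ||
    identical(hdr$BinaryDataByteOrderMSB, "True")
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw <- readBin(con, tp$what, n = n, size = tp$size, signed = tp$signed,
                   endian = if (msb) "big" else "little")
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawpath)) stop("raw data file not found: ", rawpath)
    expect_bytes <- n * tp$size
    if (file.info(rawpath)$size != expect_bytes)
      stop(sprintf("corrupt MetaImage: %s has %d bytes, header implies %d",
                   rawpath, file.info(rawpath)$size, expect_bytes))
    rcon <- file(rawpath, "rb")
    on.exit(close(rcon), add = TRUE)
    raw <- readBin(rcon, tp$what, n = n, size = tp$size, signed = tp$signed,
                   endian = if (msb) "big" else "little")
  }
  if (length(raw) != n) stop("corrupt MetaImage: short read in ", path)
  vol3d(array(as.numeric(raw), dims), spacing, origin)
}

pick_meta_type <- function(vol, type) {
  if (type != "auto") {
    return(switch(type,
                  uint8 = "MET_UCHAR", int16 = "MET_SHORT",
                  uint16 = "MET_USHORT", float32 = "MET_FLOAT",
                  float64 = "MET_DOUBLE",
                  stop("unknown element type: ", type)))
  }
  v <- vol$voxels
  if (inherits(vol, "label_mask")) return("MET_UCHAR")
  if (is.integer(v) || all(v == round(v))) {
    if (all(v >= 0 & v <= 255)) return("MET_UCHAR")
    if (all(v >= -32768 & v <= 32767)) return("MET_SHORT")
  }
  "MET_DOUBLE"
}

write_metaimage <- function(vol, path, type = "auto") {
  mtype <- pick_meta_type(vol, type)
  tp <- meta_types[[mtype]]
  local_data <- grepl("\\.mha$", tolower(path))
  rawname <- paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste("DimSize =", paste(vol_dim(vol), collapse = " ")),
    paste("ElementSpacing =", paste(sprintf("%.17g", vol$spacing), collapse = " ")),
    paste("Offset =", paste(sprintf("%.17g", vol$origin), collapse = " ")),
    paste("ElementType =", mtype),
    paste("ElementDataFile =", if (local_data) "LOCAL" else rawname)
  )
  vals <- as.vector(vol$voxels)
  payload <- if (tp$what == "integer") as.integer(round(vals)) else as.numeric(vals)
  con <- file(path, "wb")
  writeLines(hdr, con)
  if (local_data) {
    writeBin(payload, con, size = tp$size, endian = "little")
    close(con)
  } else {
    close(con)
    rcon <- file(file.path(dirname(path), rawname), "wb")
    writeBin(payload, rcon, size = tp$size, endian = "little")
    close(rcon)
  }
  invisible(path)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  offdiag <- rot - diag(diag(rot))
  if (any(abs(offdiag) > 1e-6 * max(abs(diag(rot)))))
    stop("NIfTI orientation beyond axis-aligned scaling is not supported")
  vox <- as.array(img)
  if (length(dim(vox)) != 3L) stop("only 3D NIfTI volumes are supported")
  vox <- array(as.numeric(vox), dim(vox)) # drop RNifti attributes
  spacing <- abs(diag(rot))
  origin <- xf[1:3, 4]
  # flip negatively-oriented axes so spacing is positive with ascending world
  for (ax in 1:3) {
    if (diag(rot)[ax] < 0) {
      idx <- rev(seq_len(dim(vox)[ax]))
      vox <- switch(ax, vox[idx, , , drop = FALSE],
                    vox[, idx, , drop = FALSE], vox[, , idx, drop = FALSE])
      origin[ax] <- origin[ax] + diag(rot)[ax] * (dim(vox)[ax] - 1L)
    }
  }
  vol3d(vox, spacing, origin)
}

write_nifti_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$voxels)
  RNifti::`pixdim<-`(img, vol$spacing) -> img
  mat <- diag(c(vol$spacing, 1))
  mat[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(mat, code = 2L))
  img <- RNifti::`qform<-`(img, structure(mat, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
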