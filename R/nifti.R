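# Minimal NIFTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Only what the enrichment workflows need: one 3D volume per file, the
# common datatypes, scl_slope/scl_inter scaling, and the sform affine for
# voxel -> MNI mm coordinates. Surface formats (GIFTI/CIFTI), multi-frame
# volumes, extensions and .hdr/.img pairs are out of scope.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "numeric", size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "numeric", size = 8L, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

#' Read a NIFTI-1 volume
#'
#' Reads a single-file NIFTI-1 image (optionally gzip-compressed) and
#' returns the voxel array together with the voxel-to-mm affine (sform if
#' set, otherwise qform, otherwise a pixdim diagonal). Voxel values are
#' rescaled by `scl_slope`/`scl_inter` when the header requests it.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `data` (3D numeric array) and `affine` (4x4 matrix
#'   mapping 0-based voxel indices to mm).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  raw_hdr <- readBin(con, "raw", n = 348L)
  if (length(raw_hdr) < 348L) stop("truncated NIFTI header", call. = FALSE)
  endian <- "little"
  if (readBin(raw_hdr[1:4], "integer", size = 4L, endian = endian) != 348L) {
    endian <- "big"
    if (readBin(raw_hdr[1:4], "integer", size = 4L, endian = endian) != 348L) {
      stop("not a NIFTI-1 file (bad sizeof_hdr)", call. = FALSE)
    }
  }
  magic <- rawToChar(raw_hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    stop("not a NIFTI-1 file (bad magic)", call. = FALSE)
  }
  int16 <- function(off, n = 1L)
    readBin(raw_hdr[(off + 1L):(off + 2L * n)], "integer", n = n, size = 2L,
            endian = endian)
  flt32 <- function(off, n = 1L)
    readBin(raw_hdr[(off + 1L):(off + 4L * n)], "numeric", n = n, size = 4L,
            endian = endian)
  dim0 <- int16(40L, 8L)
  ndim <- dim0[1L]
  if (ndim < 3L) stop("expected a 3D volume", call. = FALSE)
  dims <- pmax(dim0[2L:(1L + ndim)], 1L)
  if (length(dims) > 3L && any(dims[-(1:3)] > 1L)) {
    stop("multi-frame NIFTI volumes are not supported", call. = FALSE)
  }
  dims <- dims[1:3]
  datatype <- int16(70L)
  spec <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(spec)) {
    stop("unsupported NIFTI datatype code: ", datatype, call. = FALSE)
  }
  pixdim <- flt32(76L, 8L)
  vox_offset <- flt32(108L)
  scl_slope <- flt32(112L)
  scl_inter <- flt32(116L)
  qform_code <- int16(252L)
  sform_code <- int16(254L)

  nvox <- prod(dims)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  vals <- readBin(con, spec$what, n = nvox, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) < nvox) stop("truncated NIFTI data", call. = FALSE)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  data <- array(vals, dim = dims)

  affine <- diag(c(pixdim[2:4], 1))
  if (sform_code > 0L) {
    affine <- rbind(flt32(280L, 4L), flt32(296L, 4L), flt32(312L, 4L),
                    c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    b <- flt32(256L); c_ <- flt32(260L); d <- flt32(264L)
    a2 <- max(0, 1 - b^2 - c_^2 - d^2); a <- sqrt(a2)
    R <- matrix(c(
      a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d),   2 * (b * d + a * c_),
      2 * (b * c_ + a * d),   a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b),
      2 * (b * d - a * c_),   2 * (c_ * d + a * b),   a^2 + d^2 - b^2 - c_^2),
      nrow = 3, byrow = TRUE)
    qfac <- if (pixdim[1L] < 0) -1 else 1
    R <- R %*% diag(c(pixdim[2:3], qfac * pixdim[4L]))
    affine <- rbind(cbind(R, c(flt32(268L), flt32(272L), flt32(276L))),
                    c(0, 0, 0, 1))
  }
  list(data = data, affine = affine)
}

#' Write a NIFTI-1 volume
#'
#' Writes a 3D array as a single-file NIFTI-1 image. Integer-valued arrays
#' are stored as int32, everything else as float32. The affine is stored in
#' the sform (code 1).
#'
#' @param data 3D numeric array.
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @param affine 4x4 voxel-to-mm matrix (default: identity spacing).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = diag(4)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("data must be a 3D array", call. = FALSE)
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  integral <- is.integer(data) ||
    (is.numeric(data) && all(data == round(data)) &&
       max(abs(data)) < .Machine$integer.max)
  datatype <- if (integral) 8L else 16L
  bitpix <- if (integral) 32L else 32L
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wI4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wI2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wF4 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wPad <- function(n) writeBin(raw(n), con)

  wI4(348L)                              # sizeof_hdr
  wPad(35L)                              # data_type, db_name, extents, ...
  writeBin(as.raw(0L), con)              # dim_info
  wI2(c(3L, dim(data), 1L, 1L, 1L, 1L))  # dim[8]
  wF4(c(0, 0, 0)); wI2(0L)               # intent_p1..p3, intent_code
  wI2(datatype); wI2(bitpix); wI2(0L)    # datatype, bitpix, slice_start
  wF4(c(1, spacing, 1, 1, 1, 1))         # pixdim[8], qfac = 1
  wF4(352)                               # vox_offset
  wF4(1); wF4(0)                         # scl_slope, scl_inter
  wI2(0L); writeBin(as.raw(c(0L, 10L)), con)  # slice_end/code, xyzt = mm|s
  wF4(c(0, 0, 0, 0))                     # cal_max, cal_min, slice_dur, toffset
  wI4(c(0L, 0L))                         # glmax, glmin
  wPad(80L + 24L)                        # descrip, aux_file
  wI2(0L); wI2(1L)                       # qform_code, sform_code
  wF4(c(0, 0, 0))                        # quatern b, c, d
  wF4(affine[1:3, 4L])                   # qoffset x, y, z
  wF4(affine[1L, ]); wF4(affine[2L, ]); wF4(affine[3L, ])  # srow_x/y/z
  wPad(16L)                              # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)  # magic
  wPad(4L)                               # no extensions
  if (integral) {
    writeBin(as.integer(data), con, size = 4L, endian = "little")
  } else {
    writeBin(as.numeric(data), con, size = 4L, endian = "little")
  }
  invisible(path)
}
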