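# Minimal NIfTI-1 I/O.
#
# No NIfTI-capable package is available in the target library, so the small
# subset of NIfTI-1 needed here (single-file .nii / .nii.gz, 3D/4D, float32,
# float64 or int16, scl_slope/inter honoured, affine via srow) is implemented
# directly. Data are written as float32 by default.

NIFTI_HDR_SIZE <- 348L

#' Write a 3D or 4D array as a NIfTI-1 file
#'
#' @param img numeric array, 3 or 4 dimensions.
#' @param path output file; a ".gz" suffix triggers gzip compression.
#' @param voxdim voxel dimensions in mm, length 3 (a 4th value, the echo/time
#'   step, is written as 1 if absent).
#' @param affine optional 4x4 voxel-to-world matrix (RAS, mm); defaults to a
#'   diagonal scaling by `voxdim`.
#' @param datatype one of "float32", "float64".
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, voxdim = c(1, 1, 1), affine = NULL,
                        datatype = "float32") {
  stopifnot(is.array(img), length(dim(img)) %in% c(3L, 4L))
  nd <- length(dim(img))
  dims <- rep(1L, 7L)
  dims[seq_len(nd)] <- dim(img)
  if (is.null(affine)) {
    affine <- diag(c(voxdim[1], voxdim[2], voxdim[3], 1))
  }
  dt <- match.arg(datatype, c("float32", "float64"))
  code <- if (dt == "float32") 16L else 64L
  bitpix <- if (dt == "float32") 32L else 64L

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_str <- function(s, n) {
    b <- charToRaw(s)
    if (length(b) > n) b <- b[seq_len(n)]
    writeBin(c(b, raw(n - length(b))), con)
  }

  w_i32(NIFTI_HDR_SIZE)              # sizeof_hdr
  w_raw(10L)                         # data_type (unused)
  w_str("watermap", 18L)             # db_name
  w_i32(0L); w_raw(2L); w_raw(1L)    # extents, session_error, regular
  w_raw(1L)                          # dim_info
  w_i16(c(nd, dims))                 # dim[8]
  w_f32(c(0, 0, 0))                  # intent_p1..p3
  w_i16(0L)                          # intent_code
  w_i16(code)                        # datatype
  w_i16(bitpix)                      # bitpix
  w_i16(0L)                          # slice_start
  pd <- rep(1, 8); pd[1] <- 1        # pixdim[0]=qfac
  pd[2:4] <- voxdim[1:3]
  w_f32(pd)                          # pixdim[8]
  w_f32(352)                         # vox_offset
  w_f32(1); w_f32(0)                 # scl_slope, scl_inter
  w_i16(0L)                          # slice_end
  writeBin(as.raw(c(0L, 2L)), con)   # slice_code, xyzt_units (2 = mm)
  w_f32(c(0, 0))                     # cal_max, cal_min
  w_f32(c(0, 0))                     # slice_duration, toffset
  w_i32(c(0L, 0L))                   # glmax, glmin
  w_str("", 80L)                     # descrip
  w_str("", 24L)                     # aux_file
  w_i16(0L)                          # qform_code
  w_i16(1L)                          # sform_code
  w_f32(c(0, 0, 0, 0, 0, 0))         # quatern b,c,d / qoffset x,y,z
  w_f32(affine[1, ])                 # srow_x
  w_f32(affine[2, ])                 # srow_y
  w_f32(affine[3, ])                 # srow_z
  w_str("", 16L)                     # intent_name
  w_str("n+1", 4L)                   # magic
  w_raw(4L)                          # extension flag
  size <- if (dt == "float32") 4L else 8L
  writeBin(as.numeric(img), con, size = size, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 file written by this package (or any single-file NIfTI-1)
#'
#' Supports datatypes uint8, int16, int32, float32, float64 and applies
#' scl_slope/scl_inter when set.
#'
#' @param path .nii or .nii.gz file.
#' @return numeric array with attributes `voxdim` (mm) and `affine` (4x4).
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  r_i32 <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  r_i16 <- function(n) readBin(con, "integer", n, size = 2L, endian = "little")
  r_f32 <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  hdr_size <- r_i32(1)
  if (hdr_size != NIFTI_HDR_SIZE) stop("not a little-endian NIfTI-1 file: ", path)
  readBin(con, "raw", 36L)                     # data_type..regular + dim_info
  dim8 <- r_i16(8)
  r_f32(3); r_i16(1)                           # intent_p*, intent_code
  datatype <- r_i16(1); r_i16(1)               # bitpix
  r_i16(1)                                     # slice_start
  pixdim <- r_f32(8)
  vox_offset <- r_f32(1)
  scl_slope <- r_f32(1); scl_inter <- r_f32(1)
  r_i16(1); readBin(con, "raw", 2L)            # slice_end, slice_code, xyzt
  r_f32(4); r_i32(2)                           # cal/slice_duration/toffset, glmax/glmin
  readBin(con, "raw", 104L)                    # descrip + aux_file
  r_i16(2)                                     # qform_code, sform_code
  r_f32(6)
  srow <- rbind(r_f32(4), r_f32(4), r_f32(4))
  readBin(con, "raw", 20L)                     # intent_name + magic
  # the reads above total 348 bytes exactly; skip any extension bytes
  if (vox_offset > 348) readBin(con, "raw", as.integer(vox_offset - 348))
  nd <- dim8[1]
  dims <- dim8[2:(1 + nd)]
  n <- prod(dims)
  dat <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n, size = 2L, endian = "little")),
    "8"  = as.numeric(readBin(con, "integer", n, size = 4L, endian = "little")),
    "16" = readBin(con, "numeric", n, size = 4L, endian = "little"),
    "64" = readBin(con, "numeric", n, size = 8L, endian = "little"),
    stop("unsupported NIfTI datatype code: ", datatype))
  if (length(dat) != n) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    dat <- dat * scl_slope + scl_inter
  }
  arr <- array(dat, dim = dims)
  attr(arr, "voxdim") <- pixdim[2:4]
  attr(arr, "affine") <- rbind(srow, c(0, 0, 0, 1))
  arr
}
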