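# Minimal single-file NIfTI-1 reader/writer (.nii and .nii.gz).
#
# Only the subset needed for voxel-map analysis is supported: 3-D or 4-D
# arrays, datatypes uint8/int16/int32/float32/float64, sform affines, and
# scl_slope/scl_inter rescaling. Quaternion (qform-only) orientation is
# reduced to the pixdim diagonal.

NIFTI_DATATYPES <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`) into an R array.
#' Handles byte order automatically and applies `scl_slope`/`scl_inter`
#' rescaling when set.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (numeric array, 3-D or 4-D),
#'   `affine` (4x4 grid-to-world matrix), `voxel_size` (length-3, mm) and
#'   `dim` (grid dimensions).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop_mmfuse(paste0("file not found: ", path), "mmfuse_io_error")
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop_mmfuse("truncated NIfTI header", "mmfuse_io_error")
  endian <- "little"
  if (readBin(hdr[1:4], "integer", 1, 4, endian = endian) != 348L) {
    endian <- "big"
    if (readBin(hdr[1:4], "integer", 1, 4, endian = endian) != 348L)
      stop_mmfuse("not a NIfTI-1 file (bad sizeof_hdr)", "mmfuse_io_error")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop_mmfuse("not a NIfTI-1 file (bad magic)", "mmfuse_io_error")
  rd_i16 <- function(off, n) readBin(hdr[(off + 1):(off + 2 * n)], "integer", n, 2, endian = endian)
  rd_i32 <- function(off, n) readBin(hdr[(off + 1):(off + 4 * n)], "integer", n, 4, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr[(off + 1):(off + 4 * n)], "double", n, 4, endian = endian)

  dims <- rd_i16(40, 8)
  ndim <- dims[1]
  if (!ndim %in% 1:4)
    stop_mmfuse(paste0("unsupported NIfTI dimensionality: ", ndim), "mmfuse_io_error")
  shape <- dims[2:(1 + ndim)]
  dtcode <- rd_i16(70, 1)
  dt <- Filter(function(d) d$code == dtcode, NIFTI_DATATYPES)
  if (length(dt) == 0)
    stop_mmfuse(paste0("unsupported NIfTI datatype code: ", dtcode), "mmfuse_io_error")
  dt <- dt[[1]]
  pixdim <- rd_f32(76, 8)
  vox_offset <- rd_f32(108, 1)
  scl_slope <- rd_f32(112, 1)
  scl_inter <- rd_f32(116, 1)
  sform_code <- rd_i16(254, 1)
  affine <- diag(c(pixdim[2:4], 1))
  if (sform_code > 0) {
    affine <- rbind(rd_f32(280, 4), rd_f32(296, 4), rd_f32(312, 4), c(0, 0, 0, 1))
  }

  # skip from end of header to vox_offset (extensions), then read voxels
  to_skip <- round(vox_offset) - 348L
  if (to_skip > 0) readBin(con, "raw", n = to_skip)
  n_vox <- prod(shape)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < n_vox) stop_mmfuse("truncated NIfTI data section", "mmfuse_io_error")
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = shape),
       affine = affine,
       voxel_size = abs(pixdim[2:4]),
       dim = shape)
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3-D or 4-D numeric array as a single-file NIfTI-1 image with an
#' sform affine. Compression is chosen from the file extension
#' (`.nii.gz` compresses).
#'
#' @param data Numeric array (3-D volume or 4-D stack).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine 4x4 grid-to-world matrix; defaults to a diagonal affine
#'   built from `voxel_size`.
#' @param voxel_size Length-3 voxel edge lengths in mm.
#' @param datatype One of `"float32"`, `"float64"`, `"uint8"`, `"int16"`,
#'   `"int32"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = NULL,
                        voxel_size = c(1, 1, 1), datatype = "float32") {
  if (!is.array(data) || !length(dim(data)) %in% c(3L, 4L))
    stop_mmfuse("data must be a 3-D or 4-D array", "mmfuse_argument_error")
  dt <- NIFTI_DATATYPES[[datatype]]
  if (is.null(dt)) stop_mmfuse(paste0("unsupported datatype: ", datatype),
                               "mmfuse_argument_error")
  shape <- dim(data)
  ndim <- length(shape)
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  stopifnot(identical(dim(affine), c(4L, 4L)))

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                               # sizeof_hdr
  w_raw(35)                                 # data_type, db_name, extents, ...
  writeBin(as.raw(0L), con)                 # dim_info
  w_i16(c(ndim, shape, rep(1L, 7 - ndim)))  # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)              # intent
  w_i16(dt$code); w_i16(dt$bitpix); w_i16(0L)
  w_f32(c(1, voxel_size, rep(1, 4)))        # pixdim (qfac = 1)
  w_f32(352); w_f32(1); w_f32(0)            # vox_offset, scl_slope, scl_inter
  w_i16(0L); w_raw(2)                       # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))                      # cal_max/min, slice_duration, toffset
  w_i32(c(0L, 0L))                          # glmax, glmin
  w_raw(104)                                # descrip, aux_file
  w_i16(0L); w_i16(2L)                      # qform_code = 0, sform_code = 2
  w_f32(rep(0, 6))                          # quaternion + qoffset
  w_f32(affine[1, ]); w_f32(affine[2, ]); w_f32(affine[3, ])
  w_raw(16)                                 # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)
  w_raw(4)                                  # extender
  if (dt$what == "integer") {
    writeBin(as.integer(round(data)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(data), con, size = dt$size, endian = "little")
  }
  invisible(path)
}
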