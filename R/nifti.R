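#' Minimal NIfTI-1 input/output
#'
#' The package reads and writes uncompressed single-file NIfTI-1 (`.nii`)
#' volumes: a 348-byte header, a 4-byte extension flag, then the voxel data.
#' Only the fields this pipeline needs are interpreted -- grid dimensions,
#' datatype, scaling slope/intercept, and the sform affine.  Supported
#' datatypes are uint8 (2), int16 (4), int32 (8), float32 (16) and
#' float64 (64).  Files written by this package always carry an sform
#' (code 1) and no qform.
#'
#' @param path file path of an uncompressed `.nii` volume.
#' @return `read_nifti()` returns a list with elements `data` (numeric
#'   array), `affine` (4x4 voxel-to-world matrix) and `datatype`.
#' @name nifti_io
NULL

.nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8, signed = TRUE,  bitpix = 64L)
)

#' @rdname nifti_io
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    seek(con, 0L)
    sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
  }
  seek(con, 40L)
  dim <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  seek(con, 70L)
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  seek(con, 108L)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "double", 1L, size = 4L, endian = endian)
  seek(con, 344L)
  magic <- readBin(con, "raw", 4L)
  if (!identical(rawToChar(magic[1:3]), "n+1"))
    stop("unsupported NIfTI magic (expected single-file 'n+1'): ", path)
  seek(con, 280L)
  srow <- matrix(readBin(con, "double", 12L, size = 4L, endian = endian),
                 nrow = 3, byrow = TRUE)
  dt <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  ndim <- dim[1L]
  shape <- dim[seq(2L, 1L + max(ndim, 1L))]
  shape[shape == 0L] <- 1L
  n <- prod(shape)
  seek(con, vox_offset)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  affine <- rbind(srow, c(0, 0, 0, 1))
  list(data = array(vals, dim = shape), affine = affine, datatype = datatype)
}

#' @rdname nifti_io
#' @param data numeric or integer array (up to 3 dimensions used here).
#' @param affine 4x4 voxel-to-world matrix; stored as the sform.
#' @param datatype NIfTI datatype code: 16 (float32, default), 64 (float64)
#'   or 8 (int32, used for label volumes).
#' @export
write_nifti <- function(data, path, affine = diag(4), datatype = 16L) {
  stopifnot(is.array(data) || is.numeric(data))
  if (is.null(dim(data))) dim(data) <- length(data)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  dt <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt) || datatype == 2L)
    stop("write supports datatype codes 4, 8, 16, 64")
  shape <- dim(data)
  ndim <- length(shape)
  dimfield <- rep(1L, 8L)
  dimfield[1L] <- ndim
  dimfield[seq(2L, 1L + ndim)] <- shape
  # voxel sizes from the affine column norms
  pixdim <- rep(1, 8)
  pixdim[2:4] <- sqrt(colSums(affine[1:3, 1:3]^2))

  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wb(348L, 4L)                                    # sizeof_hdr
  writeBin(raw(36L), con)                         # data_type..dim_info
  wb(as.integer(dimfield), 2L)                    # dim[8]
  wb(c(0, 0, 0), 4L)                              # intent_p1..p3 (float)
  wb(0L, 2L)                                      # intent_code
  wb(as.integer(datatype), 2L)                    # datatype
  wb(dt$bitpix, 2L)                               # bitpix
  wb(0L, 2L)                                      # slice_start
  wb(pixdim, 4L)                                  # pixdim[8] (float)
  wb(352, 4L)                                     # vox_offset (float)
  wb(c(1, 0), 4L)                                 # scl_slope, scl_inter
  wb(0L, 2L); writeBin(raw(2L), con)              # slice_end, slice_code+xyzt
  wb(c(0, 0, 0, 0), 4L)                           # cal_max..toffset
  wb(c(0L, 0L), 4L)                               # glmax, glmin
  writeBin(raw(104L), con)                        # descrip + aux_file
  wb(0L, 2L)                                      # qform_code
  wb(1L, 2L)                                      # sform_code
  wb(rep(0, 6), 4L)                               # quatern + qoffset
  wb(as.numeric(t(affine[1:3, ])), 4L)            # srow_x/y/z
  writeBin(raw(16L), con)                         # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  writeBin(raw(4L), con)                          # extension flag
  vals <- as.vector(data)
  if (dt$what == "integer") {
    writeBin(as.integer(vals), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}
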