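# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# No NIfTI package is available in the target environment, so the subset of
# the format this pipeline needs is implemented here: 3D/4D volumes, data
# types uint8 / int16 / int32 / float32 / float64, scl_slope/scl_inter
# scaling on read, sform affine carried through, both byte orders on read.
# Written files are little-endian with a diagonal sform unless an affine is
# supplied.

NIFTI_TYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE))

nifti_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return A list of class `nifti_image`: `data` (numeric array), `voxel_size`
#'   (first three pixdim entries, mm), `affine` (4x4 voxel-to-world matrix).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header in ", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (magic != "n+1") stop("unsupported NIfTI magic '", magic, "' in ", path)
  rd <- function(off, what, n, size)
    readBin(hdr_raw[(off + 1):(off + n * size)], what, n, size, endian = endian)
  dim0 <- rd(40, "integer", 8L, 2L)
  ndim <- dim0[1]
  if (ndim < 1 || ndim > 7) stop("invalid NIfTI dim[0] = ", ndim)
  dims <- dim0[2:(1 + ndim)]
  datatype <- rd(70, "integer", 1L, 2L)
  typ <- NIFTI_TYPES[[as.character(datatype)]]
  if (is.null(typ)) stop("unsupported NIfTI datatype code ", datatype)
  pixdim <- rd(76, "double", 8L, 4L)
  vox_offset <- rd(108, "double", 1L, 4L)
  scl_slope <- rd(112, "double", 1L, 4L)
  scl_inter <- rd(116, "double", 1L, 4L)
  srow <- matrix(rd(280, "double", 12L, 4L), 3, 4, byrow = TRUE)
  sform_code <- rd(254, "integer", 1L, 2L)
  affine <- rbind(srow, c(0, 0, 0, 1))
  if (sform_code <= 0)
    affine <- diag(c(pixdim[2:4], 1))
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", as.integer(skip))
  n_vox <- prod(dims)
  data <- readBin(con, typ$what, n_vox, typ$size, signed = typ$signed,
                  endian = endian)
  if (length(data) != n_vox) stop("truncated NIfTI data in ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  structure(list(data = array(as.numeric(data), dim = dims),
                 voxel_size = pixdim[2:4],
                 affine = affine),
            class = "nifti_image")
}

#' Write a NIfTI-1 volume
#'
#' @param data numeric 3D or 4D array.
#' @param path output `.nii` or `.nii.gz` path (directories created).
#' @param voxel_size voxel dimensions in mm (length 3).
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `voxel_size`.
#' @param datatype `"float32"`, `"float64"` or `"int32"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, voxel_size = c(1, 1, 1), affine = NULL,
                        datatype = c("float32", "float64", "int32")) {
  datatype <- match.arg(datatype)
  dims <- dim(data)
  if (is.null(dims) || length(dims) < 3 || length(dims) > 7)
    stop("data must be a 3D-7D array")
  if (!dir.exists(dirname(path)))
    dir.create(dirname(path), recursive = TRUE)
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  stopifnot(identical(dim(affine), c(4L, 4L)))
  code <- switch(datatype, float32 = 16L, float64 = 64L, int32 = 8L)
  bitpix <- switch(datatype, float32 = 32L, float64 = 64L, int32 = 32L)
  size <- bitpix / 8L

  hcon <- rawConnection(raw(0), "wb")
  w <- function(x, size) writeBin(x, hcon, size = size, endian = "little")
  w(348L, 4L)                                       # sizeof_hdr
  writeBin(raw(36), hcon)                           # unused through dim_info
  dim8 <- integer(8); dim8[1] <- length(dims); dim8[2:(1 + length(dims))] <- dims
  dim8[dim8 == 0] <- 1L
  w(as.integer(dim8), 2L)                           # dim
  w(c(0, 0, 0), 4L)                                 # intent_p1..p3
  w(c(0L, code, bitpix, 0L), 2L)                    # intent_code, datatype, bitpix, slice_start
  pixdim <- c(1, voxel_size, rep(1, 4))
  w(pixdim, 4L)                                     # pixdim (qfac = 1)
  w(c(352, 1, 0), 4L)                               # vox_offset, scl_slope, scl_inter
  w(0L, 2L); writeBin(raw(2), hcon)                 # slice_end, slice_code, xyzt_units
  w(c(0, 0, 0, 0), 4L)                              # cal_max/min, slice_duration, toffset
  w(c(0L, 0L), 4L)                                  # glmax, glmin
  writeBin(raw(104), hcon)                          # descrip + aux_file
  w(c(0L, 1L), 2L)                                  # qform_code = 0, sform_code = 1
  w(c(0, 0, 0, 0, 0, 0), 4L)                        # quaternions + qoffsets
  w(as.numeric(t(affine[1:3, ])), 4L)               # srow_x/y/z
  writeBin(raw(20), hcon)                           # intent_name + magic, filled below
  hdr <- rawConnectionValue(hcon)
  close(hcon)
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0))
  # hdr is 348 bytes; pad 4 bytes of zero extension to vox_offset = 352
  stopifnot(length(hdr) == 348L)

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4), con)
  vals <- as.numeric(data)
  if (datatype == "int32") {
    writeBin(as.integer(round(vals)), con, size = 4L, endian = "little")
  } else {
    writeBin(vals, con, size = size, endian = "little")
  }
  invisible(path)
}
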