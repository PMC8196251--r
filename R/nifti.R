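# Minimal NIfTI-1 single-file (.nii, uncompressed) I/O.
#
# Only what the pipeline needs: 3D scalar maps, binary masks and integer
# label atlases on a shared grid.  Little-endian files, no extensions,
# datatypes uint8(2) / int16(4) / int32(8) / float32(16) / float64(64).

NIFTI_DATATYPES <- c(uint8 = 2L, int16 = 4L, int32 = 8L,
                     float32 = 16L, float64 = 64L)
NIFTI_BITPIX <- c(uint8 = 8L, int16 = 16L, int32 = 32L,
                  float32 = 32L, float64 = 64L)

#' Write a 3D array as a NIfTI-1 image
#'
#' @param img 3D numeric, integer or logical array.
#' @param path Output path; conventionally ending in `.nii` (uncompressed).
#' @param pixdim Voxel dimensions in mm, length 3.
#' @param datatype One of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`; by default integer/logical arrays are stored as `int32`
#'   (or `uint8` for logicals) and doubles as `float32`.
#' @return `path`, invisibly.
#' @seealso [read_nifti()]
#' @export
write_nifti <- function(img, path, pixdim = c(1, 1, 1), datatype = NULL) {
  if (length(dim(img)) != 3L)
    stop("write_nifti() expects a 3D array, got ", length(dim(img)), " dims")
  if (is.null(datatype)) {
    datatype <- if (is.logical(img)) "uint8"
                else if (is.integer(img)) "int32"
                else "float32"
  }
  datatype <- match.arg(datatype, names(NIFTI_DATATYPES))
  dims <- dim(img)

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wc <- function(n) writeBin(raw(n), con)

  wi(348L, 4)                      # sizeof_hdr
  wc(35)                           # data_type, db_name, extents, session_error, regular
  wc(1)                            # dim_info
  wi(c(3L, dims, 1L, 1L, 1L, 1L), 2)  # dim[8]
  wf(c(0, 0, 0))                   # intent_p1..3
  wi(0L, 2)                        # intent_code
  wi(NIFTI_DATATYPES[[datatype]], 2)
  wi(NIFTI_BITPIX[[datatype]], 2)
  wi(0L, 2)                        # slice_start
  wf(c(1, pixdim, 1, 1, 1, 1))     # pixdim[8] (qfac = 1)
  wf(352)                          # vox_offset
  wf(1); wf(0)                     # scl_slope, scl_inter
  wi(0L, 2); wc(1); wc(1)          # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                 # glmax, glmin
  desc <- charToRaw("svdstrat")
  writeBin(c(desc, raw(80 - length(desc))), con)
  wc(24)                           # aux_file
  wi(c(0L, 1L), 2)                 # qform_code, sform_code
  wf(c(0, 0, 0)); wf(c(0, 0, 0))   # quatern, qoffset
  wf(c(pixdim[1], 0, 0, 0))        # srow_x
  wf(c(0, pixdim[2], 0, 0))        # srow_y
  wf(c(0, 0, pixdim[3], 0))        # srow_z
  wc(16)                           # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  wc(4)                            # extension flag

  vals <- as.vector(img)
  if (datatype %in% c("float32", "float64")) {
    writeBin(as.double(vals), con, size = NIFTI_BITPIX[[datatype]] / 8L,
             endian = "little")
  } else {
    writeBin(as.integer(vals), con, size = NIFTI_BITPIX[[datatype]] / 8L,
             endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 image
#'
#' @param path Path to an uncompressed single-file `.nii` image.
#' @return A 3D array with attributes `pixdim` (mm) and `datatype`.
#'   Integer datatypes come back as integer arrays.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352L)
  if (length(hdr) < 352L) stop("truncated NIfTI header in ", path)
  ri <- function(off, size, n = 1L)
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 4L * n)], "double", n = n, size = 4L,
            endian = "little")
  if (ri(0, 4) != 348L)
    stop(path, " is not a little-endian NIfTI-1 file (bad sizeof_hdr)")
  magic <- rawToChar(hdr[345:347])
  if (magic != "n+1")
    stop(path, ": unsupported magic '", magic, "' (need single-file 'n+1')")
  dim8 <- ri(40, 2, 8)
  ndim <- dim8[1]
  if (ndim < 3L || any(dim8[5:8] > 1L))
    stop(path, ": only 3D images are supported")
  dims <- dim8[2:4]
  datatype_code <- ri(70, 2)
  dt <- names(NIFTI_DATATYPES)[match(datatype_code, NIFTI_DATATYPES)]
  if (is.na(dt)) stop(path, ": unsupported datatype code ", datatype_code)
  pixdim <- rf(76, 8)[2:4]
  vox_offset <- rf(108)
  scl_slope <- rf(112); scl_inter <- rf(116)

  seek(con, where = vox_offset, origin = "start")
  nvox <- prod(dims)
  size <- NIFTI_BITPIX[[dt]] / 8L
  vals <- if (dt %in% c("float32", "float64")) {
    readBin(con, "double", n = nvox, size = size, endian = "little")
  } else {
    readBin(con, "integer", n = nvox, size = size, endian = "little",
            signed = dt != "uint8")
  }
  if (length(vals) != nvox) stop("truncated voxel data in ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  out <- array(vals, dim = dims)
  attr(out, "pixdim") <- pixdim
  attr(out, "datatype") <- dt
  out
}
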