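# Minimal NIfTI-1 single-file (.nii) codec.
#
# No NIfTI package is assumed available, so the package carries its own
# reader/writer for the subset it needs: uncompressed .nii, 3D or 4D,
# little-endian, datatypes uint8/int16/int32/float32/float64, pixdim
# spacing, scl_slope/scl_inter, and a diagonal sform built from spacing.
# This is deliberately not a general NIfTI implementation.

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE)    # float64
)

#' Write a 3D or 4D array as an uncompressed NIfTI-1 file
#'
#' @param data Numeric array, 3 or 4 dimensions (x = sagittal, y, z, echo).
#' @param path Output path; conventionally ending in `.nii`.
#' @param spacing_mm Voxel spacing in mm per spatial axis (length 3).
#' @param datatype NIfTI datatype code: 16 (float32, default), 64 (float64),
#'   8 (int32), 4 (int16), 2 (uint8).
#' @param t_units_ms Optional vector of per-volume times (ms) for 4D data,
#'   stored in pixdim[5] as the first spacing only; full echo metadata
#'   belongs in a sidecar (see [write_echo_series()]).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing_mm = c(1, 1, 1), datatype = 16L,
                        t_units_ms = NULL) {
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stopf("write_nifti: data must be 3D or 4D, got %dD", nd)
  if (length(spacing_mm) != 3L) stopf("write_nifti: spacing_mm must have length 3")
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stopf("write_nifti: unsupported datatype code %s", datatype)

  dims <- rep(1L, 8L); dims[1L] <- nd; dims[2L:(1L + nd)] <- dim(data)
  pixdim <- rep(0, 8); pixdim[1] <- 1
  pixdim[2:4] <- spacing_mm
  if (nd == 4L) pixdim[5] <- if (!is.null(t_units_ms) && length(t_units_ms) > 1L) {
    diff(t_units_ms)[1]
  } else 1

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")

  wi(348L, 4)                               # sizeof_hdr
  writeBin(raw(36L), con)                   # data_type[10], db_name[18], extents, session_error, regular, dim_info
  wi(dims, 2)                               # dim[8]
  wf(rep(0, 3))                             # intent_p1..p3
  wi(0L, 2)                                 # intent_code
  wi(as.integer(datatype), 2)               # datatype
  wi(8L * dt$size, 2)                       # bitpix
  wi(0L, 2)                                 # slice_start
  wf(pixdim)                                # pixdim[8]
  wf(352)                                   # vox_offset
  wf(1); wf(0)                              # scl_slope, scl_inter
  wi(0L, 2)                                 # slice_end
  wi(0L, 1)                                 # slice_code
  wi(18L, 1)                                # xyzt_units = mm | msec (2 | 16)
  wf(0); wf(0)                              # cal_max, cal_min
  wf(0); wf(0)                              # slice_duration, toffset
  wi(c(0L, 0L), 4)                          # glmax, glmin
  writeBin(raw(104L), con)                  # descrip[80] + aux_file[24]
  wi(0L, 2); wi(1L, 2)                      # qform_code = 0, sform_code = 1
  wf(rep(0, 6))                             # quatern b,c,d + qoffset x,y,z
  wf(c(spacing_mm[1], 0, 0, 0))             # srow_x
  wf(c(0, spacing_mm[2], 0, 0))             # srow_y
  wf(c(0, 0, spacing_mm[3], 0))             # srow_z
  writeBin(raw(16L), con)                   # intent_name[16]
  writeBin(charToRaw("n+1"), con); writeBin(raw(1L), con)  # magic
  writeBin(raw(4L), con)                    # extension indicator

  vals <- as.vector(data)
  if (dt$what == "integer") {
    writeBin(as.integer(round(vals)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read an uncompressed NIfTI-1 file
#'
#' Supports the subset written by [write_nifti()] plus any single-file
#' little- or big-endian NIfTI-1 with datatype uint8/int16/int32/
#' float32/float64. Applies `scl_slope`/`scl_inter` when set.
#'
#' @param path Path to a `.nii` file.
#' @return List with `data` (array), `spacing_mm` (length 3) and `dim`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  endian <- "little"
  sz <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    seek(con, 0L)
    sz <- readBin(con, "integer", 1L, size = 4L, endian = endian)
    if (sz != 348L) stopf("read_nifti: %s is not a NIfTI-1 file", path)
  }
  seek(con, 40L)
  dims <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  nd <- dims[1L]
  if (!nd %in% c(2L, 3L, 4L)) stopf("read_nifti: unsupported ndim %d", nd)
  seek(con, 70L)
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stopf("read_nifti: unsupported datatype code %d", datatype)
  seek(con, 76L)
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "double", 1L, size = 4L, endian = endian)
  seek(con, 344L)
  magic <- rawToChar(readBin(con, "raw", 3L))
  if (!magic %in% c("n+1", "ni1")) stopf("read_nifti: bad magic in %s", path)

  shape <- dims[2L:(1L + nd)]
  n <- prod(shape)
  seek(con, as.integer(vox_offset))
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  list(data = array(vals, dim = shape),
       spacing_mm = pixdim[2:4],
       dim = shape)
}
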