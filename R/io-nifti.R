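# Minimal NIfTI-1 single-file (.nii / .nii.gz) support.
#
# No NIfTI package is available in the target environment, so the format is
# handled directly: a 348-byte header, 4 bytes of extension flags, then the
# voxel payload.  Only the fields this package needs are honoured: dim,
# datatype, pixdim, vox_offset, scl_slope/scl_inter, magic.  Volumes and
# fields are written as float64 (lossless round trip), labels as int32.
#
# On disk NIfTI stores x fastest (dim[1] = nx); in memory this package
# indexes [z, y, x].  Readers/writers permute accordingly.  Spacing is
# stored in pixdim (xyzt_units = 3, micrometres).

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

nii_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

read_nifti_raw <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- nii_connection(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1, 4, endian = endian)
  if (!identical(sizeof_hdr, 348L)) {
    endian <- "big"
    if (!identical(rev_int32(sizeof_hdr), 348L))
      stopf("not a NIfTI-1 file: %s", path)
  }
  readBin(con, "raw", 36)                                   # unused fields
  dims <- readBin(con, "integer", 8, 2, endian = endian)    # dim[0..7]
  readBin(con, "raw", 14)                                   # intent_p*, intent_code
  datatype <- readBin(con, "integer", 1, 2, endian = endian)
  readBin(con, "integer", 1, 2, endian = endian)            # bitpix
  readBin(con, "integer", 1, 2, endian = endian)            # slice_start
  pixdim <- readBin(con, "numeric", 8, 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, 4, endian = endian)
  scl_slope <- readBin(con, "numeric", 1, 4, endian = endian)
  scl_inter <- readBin(con, "numeric", 1, 4, endian = endian)
  readBin(con, "raw", 3)                                    # slice_end, slice_code
  xyzt_units <- as.integer(readBin(con, "raw", 1))
  # skip to the payload
  readBin(con, "raw", max(0, round(vox_offset) - 124))
  nd <- dims[1]
  if (nd < 1 || nd > 7) stopf("corrupt NIfTI dim[0] = %d", nd)
  shape <- dims[2:(1 + nd)]
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stopf("unsupported NIfTI datatype code %d", datatype)
  n <- prod(shape)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed, endian = endian)
  if (length(vals) < n) stopf("truncated NIfTI payload in %s", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  spatial_unit <- bitwAnd(xyzt_units, 7L)
  # pixdim in mm (code 2) is converted to um; code 3 already um; else as-is
  sp <- pixdim[2:4]
  if (spatial_unit == 2L) sp <- sp * 1000
  if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(25, 25, 25)
  list(data = array(vals, dim = shape), spacing_xyz = sp)
}

rev_int32 <- function(x) {
  r <- writeBin(as.integer(x), raw(), 4, endian = "little")
  readBin(rev(r), "integer", 1, 4, endian = "little")
}

write_nifti_raw <- function(arr, path, spacing_xyz, datatype = 64L) {
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  con <- nii_connection(path, "wb")
  on.exit(close(con))
  nd <- length(dim(arr))
  dims <- integer(8)
  dims[1] <- nd
  dims[2:(1 + nd)] <- dim(arr)
  if (nd < 7) dims[(2 + nd):8] <- 1L
  pixdim <- numeric(8)
  pixdim[1] <- 1
  pixdim[2:4] <- spacing_xyz
  pixdim[5:8] <- 1
  wb <- function(x, size) writeBin(x, con, size, endian = "little")
  wb(348L, 4L)                                   # sizeof_hdr
  wb(raw(36), 1L)
  wb(as.integer(dims), 2L)                       # dim
  wb(raw(14), 1L)                                # intent
  wb(as.integer(datatype), 2L)                   # datatype
  wb(as.integer(dt$size * 8L), 2L)               # bitpix
  wb(0L, 2L)                                     # slice_start
  wb(pixdim, 4L)                                 # pixdim
  wb(352, 4L)                                    # vox_offset
  wb(1, 4L)                                      # scl_slope
  wb(0, 4L)                                      # scl_inter
  wb(raw(3), 1L)                                 # slice_end, slice_code
  wb(as.raw(3L), 1L)                             # xyzt_units: micrometres
  wb(numeric(2), 4L)                             # cal_max, cal_min
  wb(numeric(2), 4L)                             # slice_duration, toffset
  wb(integer(2), 4L)                             # glmax, glmin
  wb(raw(80 + 24), 1L)                           # descrip, aux_file
  wb(c(0L, 0L), 2L)                              # qform_code, sform_code
  wb(numeric(6), 4L)                             # quatern b/c/d, qoffset x/y/z
  wb(numeric(12), 4L)                            # srow_x/y/z
  wb(raw(16), 1L)                                # intent_name
  wb(c(charToRaw("n+1"), as.raw(0L)), 1L)        # magic
  wb(raw(4), 1L)                                 # extension flags
  if (dt$what == "integer") wb(as.integer(arr), dt$size)
  else wb(as.numeric(arr), dt$size)
  invisible(path)
}
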