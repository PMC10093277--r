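# Minimal single-file NIfTI-1 I/O. The pre-installed R stack has no NIfTI
# package, so the package carries its own reader/writer for the subset it
# needs: 3D volumes, float32/float64/int16/int32/uint8, little-endian,
# spacing in pixdim, plain .nii or gzipped .nii.gz.

nifti_datatypes <- list(
  `2` = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4` = list(what = "integer", size = 2L, signed = TRUE, bitpix = 16L),
  `8` = list(what = "integer", size = 4L, signed = TRUE, bitpix = 32L),
  `16` = list(what = "double", size = 4L, signed = TRUE, bitpix = 32L),
  `64` = list(what = "double", size = 8L, signed = TRUE, bitpix = 64L)
)

#' Write a 3D volume as NIfTI-1
#'
#' @param vol 3D numeric or integer array; spacing is taken from
#'   [voxel_spacing()] and stored in pixdim.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param datatype one of "float32", "float64", "int16", "int32", "uint8".
#' @return the path, invisibly.
#' @export
write_nifti <- function(vol, path, datatype = "float32") {
  stopifnot(is.array(vol), length(dim(vol)) == 3L)
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 stopf("unsupported datatype '%s'", datatype))
  dt <- nifti_datatypes[[as.character(code)]]
  sp <- voxel_spacing(vol)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x, size = 4L) writeBin(as.double(x), con, size = size,
                                        endian = "little")
  wi(348L, 4L)                       # sizeof_hdr
  writeBin(raw(36L), con)            # data_type, db_name, extents, ...
  wi(c(3L, dim(vol), 1L, 1L, 1L, 1L), 2L)  # dim[8]
  wf(rep(0, 3), 4L)                  # intent_p1..p3
  wi(0L, 2L)                         # intent_code
  wi(code, 2L)                       # datatype
  wi(dt$bitpix, 2L)                  # bitpix
  wi(0L, 2L)                         # slice_start
  wf(c(1, sp, 1, 1, 1, 1), 4L)       # pixdim[8] (qfac 1)
  wf(352, 4L)                        # vox_offset
  wf(c(1, 0), 4L)                    # scl_slope, scl_inter
  wi(0L, 2L); wi(0L, 1L); wi(0L, 1L) # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0), 4L)                 # cal_max, cal_min, slice_duration
  wf(0, 4L)                          # toffset
  wi(c(0L, 0L), 4L)                  # glmax, glmin
  writeBin(raw(104L), con)           # descrip(80) + aux_file(24)
  wi(c(0L, 1L), 2L)                  # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0), 4L)        # quaternion b,c,d + offsets
  wf(c(sp[1], 0, 0, 0), 4L)          # srow_x
  wf(c(0, sp[2], 0, 0), 4L)          # srow_y
  wf(c(0, 0, sp[3], 0), 4L)          # srow_z
  writeBin(raw(16L), con)            # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  writeBin(raw(4L), con)             # extension flag
  if (dt$what == "integer") {
    wi(as.vector(vol), dt$size)
  } else {
    wf(as.vector(vol), dt$size)
  }
  invisible(path)
}

#' Read a 3D NIfTI-1 volume written by [write_nifti()] (or compatible)
#'
#' @param path `.nii` or `.nii.gz` file, little-endian, single-file NIfTI-1.
#' @return 3D array with the spacing attribute set from pixdim.
#' @export
read_nifti <- function(path) {
  con <- gzfile(path, "rb")  # gzfile reads plain files transparently
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stopf("truncated NIfTI header in %s", path)
  ri <- function(off, size, n = 1L) {
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  }
  rf <- function(off, n = 1L) {
    readBin(hdr[(off + 1L):(off + 4L * n)], "double", n = n, size = 4L,
            endian = "little")
  }
  if (ri(0L, 4L) != 348L) stopf("not a little-endian NIfTI-1 file: %s", path)
  dims <- ri(40L, 2L, 8L)
  if (dims[1] < 3L) stopf("expected a 3D volume in %s", path)
  d <- dims[2:4]
  code <- ri(70L, 2L)
  dt <- nifti_datatypes[[as.character(code)]]
  if (is.null(dt)) stopf("unsupported NIfTI datatype code %d", code)
  pixdim <- rf(76L, 8L)
  vox_offset <- rf(108L)
  skip <- as.integer(vox_offset) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(d)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = "little")
  if (length(vals) < n) stopf("truncated NIfTI data in %s", path)
  slope <- rf(112L); inter <- rf(116L)
  if (slope != 0 && !(slope == 1 && inter == 0)) vals <- vals * slope + inter
  out <- array(vals, dim = d)
  voxel_spacing(out) <- pixdim[2:4]
  out
}
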