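#' Minimal NIfTI-1 volume I/O
#'
#' Reads and writes uncompressed single-file NIfTI-1 (`.nii`) volumes with
#' an identity direction matrix, which is all the synthetic pipeline needs
#' as an interchange format.  The world mapping is stored in the sform
#' (`sform_code = 1`, srow = diag(spacing) with the origin in the fourth
#' column), matching this package's voxel-centre convention.  Only scalar
#' 3-D volumes of datatype float32, int16 or int32 are supported; no R
#' NIfTI package is assumed to be installed.
#'
#' @param volume a [voxel_volume()] (or `label_map`, whose integer grid is
#'   written as int32).
#' @param path output `.nii` path.
#' @param datatype `"float32"` or `"int32"`.
#' @return `write_nifti()` returns `path` invisibly; `read_nifti()` returns
#'   a [voxel_volume()].
#' @export
write_nifti <- function(volume, path, datatype = c("float32", "int32")) {
  datatype <- match.arg(datatype)
  if (inherits(volume, "label_map"))
    volume <- voxel_volume(volume$labels + 0, volume$spacing, volume$origin)
  stopifnot(inherits(volume, "voxel_volume"))
  dims <- dim(volume$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size = 4L) writeBin(as.integer(x), con, size = size,
                                        endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(348L)                                   # sizeof_hdr
  writeBin(raw(35), con)                     # data_type[10], db_name[18], extents, session_error, regular
  writeBin(as.raw(0L), con)                  # dim_info
  wi(c(3L, dims, 1L, 1L, 1L, 1L), size = 2L) # dim[8]
  wf(c(0, 0, 0))                             # intent_p1..p3
  wi(0L, size = 2L)                          # intent_code
  dt_code <- switch(datatype, float32 = 16L, int32 = 8L)
  bitpix <- 32L
  wi(dt_code, size = 2L)                     # datatype
  wi(bitpix, size = 2L)                      # bitpix
  wi(0L, size = 2L)                          # slice_start
  wf(c(1, volume$spacing, 0, 0, 0, 0))       # pixdim[8] (qfac = 1)
  wf(352)                                    # vox_offset
  wf(c(1, 0))                                # scl_slope, scl_inter
  wi(0L, size = 2L)                          # slice_end
  writeBin(raw(2), con)                      # slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                          # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L))                              # glmax, glmin
  writeBin(raw(104), con)                    # descrip[80] + aux_file[24]
  wi(c(0L, 1L), size = 2L)                   # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))                    # quatern b,c,d + qoffset x,y,z
  wf(c(volume$spacing[1], 0, 0, volume$origin[1]))  # srow_x
  wf(c(0, volume$spacing[2], 0, volume$origin[2]))  # srow_y
  wf(c(0, 0, volume$spacing[3], volume$origin[3]))  # srow_z
  writeBin(raw(16), con)                     # intent_name[16]
  writeBin(c(charToRaw("n+1"), raw(1)), con) # magic
  writeBin(raw(4), con)                      # extender
  if (datatype == "float32") {
    writeBin(as.numeric(volume$data), con, size = 4L, endian = "little")
  } else {
    writeBin(as.integer(round(volume$data)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  ri <- function(off, n, size) readBin(hdr[(off + 1):(off + n * size)],
                                       "integer", n, size = size,
                                       endian = "little")
  rf <- function(off, n) readBin(hdr[(off + 1):(off + n * 4)], "numeric", n,
                                 size = 4L, endian = "little")
  if (ri(0, 1, 4) != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr)")
  magic <- rawToChar(hdr[345:347])
  if (magic != "n+1") stop("only single-file NIfTI-1 ('n+1') is supported")
  d <- ri(40, 8, 2)
  if (d[1] != 3L) stop("only 3-D volumes are supported")
  dims <- d[2:4]
  dt <- ri(70, 1, 2)
  spacing <- rf(76, 8)[2:4]
  vox_offset <- rf(108, 1)
  sform_code <- ri(254, 1, 2)
  if (sform_code > 0) {
    sx <- rf(280, 4); sy <- rf(296, 4); sz <- rf(312, 4)
    origin <- c(sx[4], sy[4], sz[4])
    if (any(abs(c(sx[2:3], sy[c(1, 3)], sz[1:2])) > 1e-6))
      stop("only identity direction matrices are supported")
    spacing <- c(sx[1], sy[2], sz[3])
  } else {
    origin <- c(0, 0, 0)
  }
  n <- prod(dims)
  seek(con, vox_offset)
  data <- switch(as.character(dt),
                 "16" = readBin(con, "numeric", n, size = 4L, endian = "little"),
                 "8"  = readBin(con, "integer", n, size = 4L, endian = "little"),
                 "4"  = readBin(con, "integer", n, size = 2L, endian = "little"),
                 stop("unsupported NIfTI datatype code: ", dt))
  dim(data) <- dims
  voxel_volume(data + 0, spacing, origin)
}
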