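# Minimal single-file NIfTI-1 (.nii) writer/reader, little-endian,
# uncompressed, covering the three datatypes this package emits: signed
# 16-bit HU volumes, unsigned 8-bit masks, and 32-bit float. Scale slope is
# fixed at 1 (HU are stored as-is). Array layout matches the package
# convention [row, column, slice] mapped to NIfTI (i, j, k).

NIFTI_DTYPES <- list(uint8 = list(code = 2L, bitpix = 8L, size = 1L),
                     int16 = list(code = 4L, bitpix = 16L, size = 2L),
                     float32 = list(code = 16L, bitpix = 32L, size = 4L))

#' Write a 3D array or voxel volume as NIfTI-1
#'
#' @param x a [voxel_volume()], or a 3D array (numeric or logical).
#' @param path output file path ending in `.nii`.
#' @param spacing mm triple; taken from `x` when it is a `voxel_volume`.
#' @param datatype one of `"int16"` (default for HU), `"uint8"` (masks),
#'   `"float32"`. Logical input defaults to `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, spacing = NULL, datatype = NULL) {
  if (inherits(x, "voxel_volume")) {
    spacing <- x$spacing
    x <- x$hu
  }
  stopifnot(is.array(x), length(dim(x)) == 3L, length(spacing) == 3L,
            all(spacing > 0))
  if (is.null(datatype)) datatype <- if (is.logical(x)) "uint8" else "int16"
  dt <- NIFTI_DTYPES[[match.arg(datatype, names(NIFTI_DTYPES))]]
  d <- dim(x)

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size = 4L) writeBin(as.integer(v), con, size = size, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)

  wi(348L)                                   # sizeof_hdr
  wraw(36L)                                  # data_type, db_name, extents, session_error, regular, dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), size = 2L)    # dim[8]
  wf(c(0, 0, 0))                             # intent_p1..p3
  wi(0L, size = 2L)                          # intent_code
  wi(dt$code, size = 2L)                     # datatype
  wi(dt$bitpix, size = 2L)                   # bitpix
  wi(0L, size = 2L)                          # slice_start
  wf(c(1, spacing, 0, 0, 0, 0))              # pixdim[8] (qfac = 1)
  wf(352)                                    # vox_offset
  wf(1); wf(0)                               # scl_slope, scl_inter
  wi(0L, size = 2L); wraw(1L); wraw(1L)      # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                          # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L))                              # glmax, glmin
  desc <- charToRaw(sprintf("cortqct %s", datatype))
  wraw0 <- function(r, n) { writeBin(c(r, raw(n - length(r))), con) }
  wraw0(desc, 80L)                           # descrip
  wraw(24L)                                  # aux_file
  wi(c(0L, 1L), size = 2L)                   # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))                    # quatern b,c,d + qoffset x,y,z
  wf(c(spacing[1], 0, 0, 0))                 # srow_x
  wf(c(0, spacing[2], 0, 0))                 # srow_y
  wf(c(0, 0, spacing[3], 0))                 # srow_z
  wraw(16L)                                  # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con) # magic
  wraw(4L)                                   # extension flag

  vals <- as.vector(x)
  if (dt$code %in% c(2L, 4L)) {
    writeBin(as.integer(round(vals)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file written by [write_nifti()]
#'
#' Supports uncompressed little-endian single-file NIfTI-1 with datatypes
#' uint8, int16 and float32 and applies `scl_slope`/`scl_inter`.
#'
#' @param path file path.
#' @return list with `data` (3D array) and `spacing` (mm triple).
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(hdr_size, 348L)) stop("not a little-endian NIfTI-1 file")
  invisible(readBin(con, "raw", 36))
  dims <- readBin(con, "integer", 8, size = 2, endian = "little")
  invisible(readBin(con, "numeric", 3, size = 4, endian = "little"))
  invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
  dtype <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "integer", 2, size = 2, endian = "little"))
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = "little")
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = "little")
  scl_slope <- readBin(con, "numeric", 1, size = 4, endian = "little")
  scl_inter <- readBin(con, "numeric", 1, size = 4, endian = "little")
  d <- dims[2:(1 + dims[1])]
  n <- prod(d)
  seek(con, vox_offset)
  data <- switch(as.character(dtype),
    "2" = readBin(con, "integer", n, size = 1, signed = FALSE, endian = "little"),
    "4" = readBin(con, "integer", n, size = 2, signed = TRUE, endian = "little"),
    "16" = readBin(con, "numeric", n, size = 4, endian = "little"),
    stop("unsupported NIfTI datatype: ", dtype))
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  list(data = array(data, d), spacing = pixdim[2:4])
}
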