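# Minimal NIfTI-1 I/O.
#
# No NIfTI package is assumed; this covers exactly the subset the pipeline
# writes: single-file uncompressed .nii, 2-D to 4-D, little-endian, no
# extensions. scl_slope/scl_inter are applied on read if present.

NIFTI_TYPES <- data.frame(
  code = c(2L, 4L, 8L, 16L, 64L),
  bits = c(8L, 16L, 32L, 32L, 64L),
  what = c("integer", "integer", "integer", "double", "double"),
  stringsAsFactors = FALSE)

#' Write an array as a NIfTI-1 volume
#'
#' @param x Numeric/integer array, 2 to 7 dimensions.
#' @param path Output path; should end in `.nii`.
#' @param pixdim Voxel sizes per dimension, recycled to the array rank.
#' @param datatype One of `"float32"` (default), `"float64"`, `"uint8"`,
#'   `"int16"`, `"int32"`.
#' @return `path`, invisibly.
#' @export
nifti_write <- function(x, path, pixdim = 1,
                        datatype = c("float32", "float64", "uint8", "int16",
                                     "int32")) {
  datatype <- match.arg(datatype)
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L)
  tp <- NIFTI_TYPES[NIFTI_TYPES$code == code, ]
  stopifnot(is.array(x) || is.matrix(x))
  dm <- dim(x)
  if (length(dm) < 2 || length(dm) > 7) stop("need 2 to 7 dimensions")
  pixdim <- rep_len(pixdim, length(dm))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(352), con)  # zeroed header + 4-byte extension flag
  at <- function(off) seek(con, off, rw = "write")
  wi <- function(off, v, size) { at(off)
    writeBin(as.integer(v), con, size = size, endian = "little") }
  wf <- function(off, v) { at(off)
    writeBin(as.numeric(v), con, size = 4, endian = "little") }
  wi(0, 348L, 4)                                       # sizeof_hdr
  at(38); writeBin(charToRaw("r"), con)                # regular
  wi(40, c(length(dm), dm, rep(1L, 7 - length(dm))), 2)  # dim[8]
  wi(70, code, 2)                                      # datatype
  wi(72, tp$bits, 2)                                   # bitpix
  wf(76, c(1, pixdim, rep(1, 7 - length(dm))))         # pixdim[8]
  wf(108, 352)                                         # vox_offset
  wf(112, c(1, 0))                                     # scl_slope, scl_inter
  at(344); writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic

  at(352)
  if (tp$what == "integer")
    writeBin(as.integer(round(as.vector(x))), con, size = tp$bits / 8,
             endian = "little")
  else
    writeBin(as.numeric(as.vector(x)), con, size = tp$bits / 8,
             endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume written by [nifti_write()]
#'
#' @param path Path to an uncompressed single-file `.nii`.
#' @return Numeric array with a `pixdim` attribute.
#' @export
nifti_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(off, n, size) { seek(con, off)
    readBin(con, "integer", n = n, size = size, endian = "little") }
  rf <- function(off, n) { seek(con, off)
    readBin(con, "double", n = n, size = 4, endian = "little") }
  if (ri(0, 1, 4) != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr)")
  dimv <- ri(40, 8, 2)
  nd <- dimv[1]
  if (nd < 1 || nd > 7) stop("bad dimension count")
  dm <- dimv[2:(1 + nd)]
  code <- ri(70, 1, 2)
  tp <- NIFTI_TYPES[NIFTI_TYPES$code == code, ]
  if (nrow(tp) != 1) stop("unsupported NIfTI datatype code ", code)
  pd <- rf(76, 8)
  vox_offset <- rf(108, 1)
  scl <- rf(112, 2)
  seek(con, 344)
  magic <- rawToChar(readBin(con, "raw", 3))
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic")
  seek(con, vox_offset)
  x <- readBin(con, tp$what, n = prod(dm), size = tp$bits / 8,
               endian = "little", signed = tp$bits > 8)
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0))
    x <- x * scl[1] + scl[2]
  out <- array(x, dim = dm)
  attr(out, "pixdim") <- pd[2:(1 + nd)]
  out
}
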