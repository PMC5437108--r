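# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
#
# No neuroimaging I/O package is available in the target library, so the
# subset of NIfTI-1 the pipeline needs is implemented here directly:
# 3D/4D float32/float64/int16/int32/uint8 data, little- or big-endian,
# sform affine. Written files carry float64 data, sform_code = 2 and
# magic "n+1".

nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "numeric", size = 4L, signed = TRUE),
  `64` = list(what = "numeric", size = 8L, signed = TRUE)
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a volume or 4D series as NIfTI-1
#'
#' @param x an `nb_volume`, `nb_bold`, or a 3D/4D array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param affine affine override when `x` is a bare array.
#' @param tr_s frame duration stored in `pixdim[4]` for 4D data.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, affine = NULL, tr_s = 0) {
  if (inherits(x, "nb_volume")) { arr <- x$data; affine <- x$affine }
  else if (inherits(x, "nb_bold")) { arr <- x$data; affine <- x$affine; tr_s <- x$tr_s }
  else arr <- x
  nd <- length(dim(arr))
  if (!nd %in% c(3L, 4L)) stop("write_nifti supports 3D or 4D arrays")
  if (is.null(affine)) affine <- grid_affine(dim(arr)[1:3], 1)
  d <- dim(arr)
  dim_field <- rep(1L, 8); dim_field[1] <- nd; dim_field[1 + seq_len(nd)] <- d
  pixdim <- rep(0, 8); pixdim[1] <- 1
  pixdim[2:4] <- voxel_sizes(affine); pixdim[5] <- tr_s

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)                      # sizeof_hdr
  writeBin(raw(36), con)                             # unused fields
  writeBin(as.integer(dim_field), con, size = 2)     # dim
  writeBin(raw(14), con)                             # intent_p*, intent_code
  writeBin(64L, con, size = 2)                       # datatype float64
  writeBin(64L, con, size = 2)                       # bitpix
  writeBin(0L, con, size = 2)                        # slice_start
  writeBin(pixdim, con, size = 4)                    # pixdim
  writeBin(352, con, size = 4)                       # vox_offset
  writeBin(c(1, 0), con, size = 4)                   # scl_slope, scl_inter
  writeBin(raw(3), con)                              # slice_end, slice_code, xyzt_units
  writeBin(as.raw(0x0A), con)                        # xyzt_units: mm | sec
  writeBin(c(0, 0, 0), con, size = 4)                # cal_max/min, slice_duration
  writeBin(0, con, size = 4)                         # toffset
  writeBin(raw(8), con)                              # glmax/glmin
  writeBin(raw(104), con)                            # descrip + aux_file
  writeBin(c(0L, 2L), con, size = 2)                 # qform_code, sform_code
  writeBin(rep(0, 6), con, size = 4)                 # quaternion b,c,d + offsets
  writeBin(as.numeric(t(affine[1:3, ])), con, size = 4)  # srow_x/y/z
  writeBin(raw(16), con)                             # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)      # magic
  writeBin(raw(4), con)                              # extension flag
  writeBin(as.numeric(arr), con, size = 8)
  invisible(path)
}

#' Read a NIfTI-1 file
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return an `nb_volume` (3D) or `nb_bold` (4D).
#' @export
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("truncated NIfTI header in ", path)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", 1, 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", 1, 4, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic in ", path)
  dim_field <- readBin(hdr[41:56], "integer", 8, 2, endian = endian)
  nd <- dim_field[1]
  if (!nd %in% c(3L, 4L)) stop("unsupported NIfTI dimensionality: ", nd)
  d <- dim_field[1 + seq_len(nd)]
  datatype <- readBin(hdr[71:72], "integer", 1, 2, endian = endian)
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype, " in ", path)
  pixdim <- readBin(hdr[77:108], "numeric", 8, 4, endian = endian)
  vox_offset <- readBin(hdr[109:112], "numeric", 1, 4, endian = endian)
  scl <- readBin(hdr[113:120], "numeric", 2, 4, endian = endian)
  sform_code <- readBin(hdr[255:256], "integer", 1, 2, endian = endian)
  srow <- readBin(hdr[281:328], "numeric", 12, 4, endian = endian)
  if (sform_code > 0) {
    affine <- rbind(matrix(srow, 3, 4, byrow = TRUE), c(0, 0, 0, 1))
  } else {
    affine <- grid_affine(d[1:3], pixdim[2:4])
  }
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(d)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed, endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0)) vals <- vals * scl[1] + scl[2]
  arr <- array(as.numeric(vals), d)
  if (nd == 3L) volume(arr, affine)
  else bold_series(arr, tr_s = pixdim[5], affine = affine)
}
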