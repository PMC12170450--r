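# Minimal NIfTI-1 reader/writer.
#
# No NIfTI package ships with the target environment, and the format needs
# are narrow: single-file .nii / .nii.gz, 3D, scalar dtypes, sform affine.
# The 348-byte header is laid out by hand; datatype codes follow the NIfTI-1
# standard (2 = uint8, 4 = int16, 8 = int32, 16 = float32, 64 = float64).

NIFTI_DT <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3D volume as NIfTI-1
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-mm matrix, stored as the sform (sform_code 1).
#' @param path output file; `.nii` or `.nii.gz`.
#' @param datatype one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, affine, path, datatype = "float32") {
  dt <- NIFTI_DT[[datatype]]
  if (is.null(dt)) stop("unsupported datatype: ", datatype)
  d <- dim(data)
  if (length(d) != 3L) stop("only 3D volumes are written")
  pixdim <- sqrt(colSums(affine[1:3, 1:3]^2))
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wc <- function(n) writeBin(raw(n), con)
  wi(348L, 4L)                               # sizeof_hdr
  wc(35L)                                    # data_type, db_name, extents, ...
  writeBin(as.raw(0L), con)                  # dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2L)           # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2L)                 # intent_p1..3, intent_code
  wi(dt$code, 2L); wi(dt$bitpix, 2L); wi(0L, 2L)   # datatype, bitpix, slice_start
  wf(c(1, pixdim, 1, 1, 1, 1))               # pixdim[8] (qfac = 1)
  wf(352); wf(1); wf(0)                      # vox_offset, scl_slope, scl_inter
  wi(0L, 2L); writeBin(as.raw(c(0L, 2L)), con)     # slice_end, slice_code, xyzt_units (mm)
  wf(c(0, 0, 0, 0)); wi(c(0L, 0L), 4L)       # cal_max/min, slice_dur, toffset, glmax/glmin
  wc(104L)                                   # descrip + aux_file
  wi(0L, 2L); wi(1L, 2L)                     # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))                    # quatern b,c,d + qoffset x,y,z
  wf(affine[1, ]); wf(affine[2, ]); wf(affine[3, ])  # srow_x/y/z
  wc(16L)                                    # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL); writeBin(as.raw(0L), con)
  wc(4L)                                     # extension flag
  if (dt$what == "integer") {
    storage <- as.integer(round(data))
    writeBin(storage, con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(data), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports single-file 3D NIfTI-1 (optionally gzipped) with scalar dtypes.
#' The affine comes from the sform when set, else from the qform quaternion,
#' else from pixdim on the diagonal. Scl slope/intercept are applied.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (3D array) and `affine` (4x4).
#' @export
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop(path, ": not a NIfTI-1 file (short header)")
  rd <- function(off, what, n, size, signed = TRUE, endian = "little") {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            signed = signed, endian = endian)
  }
  endian <- "little"
  if (rd(0L, "integer", 1L, 4L) != 348L) {
    endian <- "big"
    if (rd(0L, "integer", 1L, 4L, endian = "big") != 348L)
      stop(path, ": not a NIfTI-1 file (sizeof_hdr != 348)")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop(path, ": missing NIfTI magic")
  dim8 <- rd(40L, "integer", 8L, 2L, endian = endian)
  ndim <- dim8[1]
  if (ndim > 3L && any(dim8[(4 + 1):(ndim + 1)] > 1L))
    stop(path, ": 4D+ images are not supported")
  d <- pmax(dim8[2:4], 1L)
  dtcode <- rd(70L, "integer", 1L, 2L, endian = endian)
  dt <- Filter(function(x) x$code == dtcode, NIFTI_DT)
  if (length(dt) == 0) stop(path, ": unsupported NIfTI datatype code ", dtcode)
  dt <- dt[[1]]
  pixdim <- rd(76L, "double", 8L, 4L, endian = endian)
  vox_offset <- rd(108L, "double", 1L, 4L, endian = endian)
  scl_slope <- rd(112L, "double", 1L, 4L, endian = endian)
  scl_inter <- rd(116L, "double", 1L, 4L, endian = endian)
  qform_code <- rd(252L, "integer", 1L, 2L, endian = endian)
  sform_code <- rd(254L, "integer", 1L, 2L, endian = endian)
  affine <- diag(4)
  if (sform_code > 0L) {
    affine[1, ] <- rd(280L, "double", 4L, 4L, endian = endian)
    affine[2, ] <- rd(296L, "double", 4L, 4L, endian = endian)
    affine[3, ] <- rd(312L, "double", 4L, 4L, endian = endian)
  } else if (qform_code > 0L) {
    q <- rd(256L, "double", 6L, 4L, endian = endian)  # b, c, d, offsets
    b <- q[1]; c <- q[2]; dd <- q[3]
    a <- sqrt(max(0, 1 - b^2 - c^2 - dd^2))
    R <- matrix(c(a*a+b*b-c*c-dd*dd, 2*(b*c+a*dd),     2*(b*dd-a*c),
                  2*(b*c-a*dd),      a*a+c*c-b*b-dd*dd, 2*(c*dd+a*b),
                  2*(b*dd+a*c),      2*(c*dd-a*b),      a*a+dd*dd-b*b-c*c),
                3, 3, byrow = FALSE)
    qfac <- if (pixdim[1] < 0) -1 else 1
    affine[1:3, 1:3] <- R %*% diag(c(pixdim[2:3], qfac * pixdim[4]))
    affine[1:3, 4] <- q[4:6]
  } else {
    affine[1:3, 1:3] <- diag(pixdim[2:4])
  }
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  nv <- prod(d)
  vals <- readBin(con, dt$what, n = nv, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < nv) stop(path, ": truncated data section")
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = d), affine = affine)
}

#' Read a binary lesion mask from NIfTI
#'
#' Values are binarized at 0.5 (`>= 0.5` is lesioned); the number of
#' non-0/1 voxels encountered is reported via `message()`.
#'
#' @param path NIfTI file.
#' @param reference_affine optional 4x4; a mismatch beyond `tol` errors, so a
#'   cohort cannot silently mix spaces.
#' @param tol affine comparison tolerance (mm).
#' @return [lesion_mask].
#' @export
read_mask <- function(path, reference_affine = NULL, tol = 1e-4) {
  nii <- read_nifti(path)
  if (!is.null(reference_affine) &&
      max(abs(nii$affine - reference_affine)) > tol)
    stop(path, ": affine does not match the cohort reference affine")
  nonbin <- sum(!(nii$data %in% c(0, 1)))
  if (nonbin > 0)
    message(sprintf("%s: binarized %d non-0/1 voxels at 0.5", basename(path), nonbin))
  lesion_mask(ifelse(nii$data >= 0.5, 1L, 0L) * 1L, nii$affine)
}

#' Write a binary lesion mask as NIfTI (uint8)
#'
#' @param mask [lesion_mask].
#' @param path output `.nii` / `.nii.gz`.
#' @export
write_mask <- function(mask, path) {
  write_nifti(mask$data, mask$affine, path, datatype = "uint8")
}
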