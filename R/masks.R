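#' Binary lesion mask in a common space
#'
#' The unit of imaging input throughout the package: a 3D binary volume
#' together with its voxel-to-mm affine. Voxel indices are 0-based when
#' multiplied through the affine (NIfTI convention, RAS mm); in R code the
#' array is indexed 1-based as usual.
#'
#' @param data 3D array of 0/1 (logical or numeric).
#' @param affine 4x4 voxel-to-mm matrix; last row must be (0, 0, 0, 1).
#' @return An object of class `lesion_mask`: a list with elements `data`
#'   (integer 3D array) and `affine`.
#' @export
lesion_mask <- function(data, affine) {
  if (length(dim(data)) != 3L) stop("lesion mask must be a 3D array")
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-8)
    stop("last affine row must be (0, 0, 0, 1)")
  vals <- as.numeric(data)
  if (any(!vals %in% c(0, 1)))
    stop("lesion mask values must be 0/1; binarize first (see read_mask)")
  arr <- array(as.integer(vals), dim = dim(data))
  structure(list(data = arr, affine = affine), class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<lesion_mask> %d x %d x %d, %d lesioned voxels (%.2f cm^3)\n",
              d[1], d[2], d[3], sum(x$data), mask_volume_cm3(x)))
  invisible(x)
}

#' Default centered affine for a simulation grid
#'
#' Isotropic voxels with the grid center at mm origin, axes aligned to RAS.
#'
#' @param grid_shape integer triple of voxel counts.
#' @param voxel_size_mm isotropic voxel edge in mm.
#' @return 4x4 affine matrix.
#' @export
centered_affine <- function(grid_shape, voxel_size_mm = 2) {
  A <- diag(c(rep(voxel_size_mm, 3), 1))
  A[1:3, 4] <- -(grid_shape - 1) / 2 * voxel_size_mm
  A
}

voxel_volume_cm3 <- function(affine) {
  abs(det(affine[1:3, 1:3])) / 1000
}

mask_volume_cm3 <- function(mask) {
  sum(mask$data) * voxel_volume_cm3(mask$affine)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$affine - b$affine)) <= tol
}

stop_if_grid_mismatch <- function(a, b, what = "masks") {
  if (!same_grid(a, b))
    stop(sprintf("%s are not on the same grid (dim or affine mismatch)", what))
  invisible(TRUE)
}

#' Stack lesion masks into a subjects-by-voxels matrix
#'
#' Flattens each subject's volume column-major (R's native order) into one
#' row. All masks must share grid and affine; these are kept as attributes.
#'
#' @param masks list of [lesion_mask] objects.
#' @return Integer matrix n x V with attributes `grid_dim` and `affine`.
#' @export
lesion_matrix <- function(masks) {
  stopifnot(length(masks) >= 1)
  ref <- masks[[1]]
  for (m in masks[-1]) stop_if_grid_mismatch(ref, m)
  L <- do.call(rbind, lapply(masks, function(m) as.integer(m$data)))
  attr(L, "grid_dim") <- dim(ref$data)
  attr(L, "affine") <- ref$affine
  L
}

# mm coordinates of voxel centers for 1-based array indices (n x 3 matrix)
voxel_to_mm <- function(idx1, affine) {
  idx0 <- cbind(idx1 - 1, 1)
  t(affine[1:3, , drop = FALSE] %*% t(idx0))
}
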