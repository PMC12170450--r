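# build cluster descriptors from a logical 3D mask: face-connected
# components, sorted by size descending; center of mass is the unweighted
# mean of voxel-center mm coordinates
clusters_from_mask <- function(mask3d, affine, stat3d = NULL) {
  gdim <- dim(mask3d)
  lab <- cc_label_cpp(as.logical(mask3d), as.integer(gdim))
  ncl <- max(lab)
  if (ncl == 0L) return(list())
  vvol <- voxel_volume_cm3(affine)
  out <- lapply(seq_len(ncl), function(k) {
    lin <- which(lab == k)
    idx <- arrayInd(lin, gdim)
    mm <- voxel_to_mm(idx, affine)
    peak <- if (is.null(stat3d)) NA_real_ else max(stat3d[lin], na.rm = TRUE)
    list(voxels = idx, n_voxels = length(lin),
         volume_cm3 = length(lin) * vvol,
         center_of_mass_mm = colMeans(mm), peak = peak)
  })
  out[order(vapply(out, `[[`, 1L, "n_voxels"), decreasing = TRUE)]
}

#' Extract suprathreshold clusters from a statistic map
#'
#' Face-connected (6-neighbour) components of voxels with statistic
#' `>= threshold` (voxels touching only at an edge or corner belong to
#' different clusters), sorted by volume descending. The center of mass is
#' the unweighted mean of voxel-center mm coordinates via the affine;
#' cluster volume is voxel count times voxel volume.
#'
#' @param statmap a `stat_map` (its t volume is used), or a 3D numeric
#'   array. NaN entries never enter a cluster.
#' @param threshold finite cluster-forming value on the statistic's scale.
#' @param affine required when `statmap` is a bare array.
#' @return list of clusters; each has `voxels` (1-based index matrix),
#'   `n_voxels`, `volume_cm3`, `center_of_mass_mm`, `peak`.
#' @export
extract_clusters <- function(statmap, threshold, affine = NULL) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  if (inherits(statmap, "stat_map")) {
    arr <- statmap$t
    affine <- statmap$affine
  } else {
    arr <- statmap
    if (is.null(affine)) stop("affine is required for a bare array")
  }
  supra <- !is.na(arr) & arr >= threshold
  clusters_from_mask(supra, affine, arr)
}

# convert a cluster (or any voxel index set) back to a binary mask
cluster_to_mask <- function(cluster, grid_dim, affine) {
  arr <- array(0L, grid_dim)
  arr[cluster$voxels] <- 1L
  lesion_mask(arr, affine)
}
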