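# shared fixtures and independent oracles (kept deliberately separate from
# the package's own code paths)

tiny_config <- function(...) {
  args <- list(grid_shape = c(16L, 16L, 16L), n_subjects = 12L,
               critical_region = ellipsoid_spec(c(0, 2, 2), c(7, 7, 7)),
               aos_region = ellipsoid_spec(c(-9, -9, -9), c(5, 5, 5)),
               lesion_radius_meanlog = log(8), center_margin = 0.6,
               seed = 7L)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# build a lesion_mask by lighting up a set of 1-based voxel indices
make_mask <- function(gdim, idx, voxel_size = 2) {
  arr <- array(0L, gdim)
  if (length(idx)) arr[idx] <- 1L
  lesion_mask(arr, centered_affine(gdim, voxel_size))
}

# independent flood-fill connected-components oracle (6-connectivity)
flood_fill_oracle <- function(mask3d) {
  d <- dim(mask3d)
  lab <- array(0L, d)
  nxt <- 0L
  for (v in which(mask3d)) {
    if (lab[v] != 0L) next
    nxt <- nxt + 1L
    queue <- v
    lab[v] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(cur, d)
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        nb <- ijk; nb[ax] <- nb[ax] + s
        if (nb[ax] < 1L || nb[ax] > d[ax]) next
        w <- nb[1] + d[1] * (nb[2] - 1L) + d[1] * d[2] * (nb[3] - 1L)
        if (mask3d[w] && lab[w] == 0L) { lab[w] <- nxt; queue <- c(queue, w) }
      }
    }
  }
  lab
}

# recursive permutation enumerator, independent of the package's
all_perms_oracle <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms_oracle(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

voxel_to_mm_oracle <- function(idx1, A) {
  as.numeric(A[1:3, 1:3] %*% (idx1 - 1) + A[1:3, 4])
}

pearson_longhand <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# paired WAB/QAB table built directly from shared-metric values
paired_from_metrics <- function(self_w, self_q, overall = NULL) {
  n <- length(self_w)
  if (is.null(overall)) overall <- seq(2, 9, length.out = n)
  rep_ <- rev(overall); nam <- overall
  rbind(
    data.frame(subject_id = sprintf("s%02d", 1:n), instrument = "WAB",
               aos = 0L, days_post_surgery = 3L,
               wab_fluency = self_w, wab_aq = overall * 10,
               wab_repetition = rep_, wab_naming = nam,
               qab_length_complexity = NA_real_, qab_speech_rate = NA_real_,
               qab_comm_impairment = NA_real_, qab_overall = NA_real_,
               qab_repetition = NA_real_, qab_naming = NA_real_),
    data.frame(subject_id = sprintf("s%02d", 1:n), instrument = "QAB",
               aos = 0L, days_post_surgery = 3L,
               wab_fluency = NA_real_, wab_aq = NA_real_,
               wab_repetition = NA_real_, wab_naming = NA_real_,
               qab_length_complexity = self_q / 2.5,
               qab_speech_rate = self_q / 2.5,
               qab_comm_impairment = self_q / 2.5,
               qab_overall = overall, qab_repetition = rep_,
               qab_naming = nam))
}

largest_cluster_mask <- function(res, gdim, affine) {
  if (length(res$clusters) == 0) return(make_mask(gdim, integer(0)))
  lesionmap:::cluster_to_mask(res$clusters[[1]], gdim, affine)
}
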