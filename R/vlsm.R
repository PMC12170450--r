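#' Design specification for voxel-based lesion-symptom mapping
#'
#' @param outcome name of the harmonized outcome column.
#' @param covariates nuisance columns entered alongside the lesion indicator
#'   at every voxel. Defaults: overall language ability, AOS flag,
#'   instrument used, days post-surgery, and lesion size.
#' @param min_lesioned minimum subjects lesioned at a voxel for inclusion.
#' @param min_intact minimum intact subjects at a voxel (variance guard; the
#'   lesioned minimum alone leaves the contrast inestimable near full
#'   overlap).
#' @param n_permutations permutation count for familywise correction.
#' @param alpha familywise significance level.
#' @param tail `"lower"` (damage lowers the score; default) or
#'   `"two-sided"`.
#' @param cluster_forming_alpha parametric one-tailed p defining the primary
#'   threshold for the cluster-extent null.
#' @param seed RNG seed for the permutation draw.
#' @return list of class `design_spec`.
#' @export
design_spec <- function(outcome = "self_generated",
                        covariates = c("overall", "aos", "instrument",
                                       "days_post_surgery", "lesion_cm3"),
                        min_lesioned = 5L, min_intact = 2L,
                        n_permutations = 1000L, alpha = 0.05,
                        tail = c("lower", "two-sided"),
                        cluster_forming_alpha = 0.01, seed = 1L) {
  tail <- match.arg(tail)
  if (min_lesioned < 2L) stop("min_lesioned must be >= 2")
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  structure(list(outcome = outcome, covariates = covariates,
                 min_lesioned = as.integer(min_lesioned),
                 min_intact = as.integer(min_intact),
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, tail = tail,
                 cluster_forming_alpha = cluster_forming_alpha,
                 seed = as.integer(seed)),
            class = "design_spec")
}

# nuisance design matrix with intercept; factors expanded, constant columns
# dropped (they are collinear with the intercept and would sink every voxel)
covariate_matrix <- function(behavior, covariates) {
  if (length(covariates) == 0)
    return(matrix(1, nrow(behavior), 1, dimnames = list(NULL, "(Intercept)")))
  missing <- setdiff(covariates, names(behavior))
  if (length(missing))
    stop("behavior table lacks covariate column(s): ",
         paste(missing, collapse = ", "))
  df <- behavior[covariates]
  for (nm in names(df)) {
    if (is.character(df[[nm]]) || is.logical(df[[nm]]))
      df[[nm]] <- factor(df[[nm]])
    if (is.factor(df[[nm]]) && nlevels(droplevels(df[[nm]])) < 2) {
      warning("dropping constant covariate: ", nm)
      df[[nm]] <- NULL
    }
  }
  Z <- stats::model.matrix(~ ., data = as.data.frame(df))
  const <- apply(Z[, -1, drop = FALSE], 2, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning("dropping constant covariate column(s): ",
            paste(colnames(Z[, -1, drop = FALSE])[const], collapse = ", "))
    Z <- Z[, c(TRUE, !const), drop = FALSE]
  }
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z))
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(colnames(Z)[qrz$pivot[(qrz$rank + 1):ncol(Z)]], collapse = ", "))
  Z
}

# t statistics of the lesion coefficient at each column of Lr given
# covariate-residualized lesions/outcome (Frisch-Waugh-Lovell): identical to
# fitting the full GLM [intercept, lesion, covariates] at every voxel.
fwl_t <- function(Lr, rll, Yr, df, y_scale = NULL) {
  ryy <- colSums(Yr^2)
  # a constant outcome leaves only projection round-off; force t = 0 there
  if (!is.null(y_scale)) ryy[ryy <= 1e-18 * (y_scale + 1)] <- 0
  Rly <- crossprod(Lr, Yr)                         # V x B
  Rly[, ryy == 0] <- 0
  denom <- outer(rll, ryy) - Rly^2
  denom[denom < 0] <- 0
  Tm <- Rly * sqrt(df) / sqrt(denom)
  Tm[is.nan(Tm)] <- 0   # 0/0: no association and no residual variance
  Tm
}

#' Mass-univariate voxelwise GLM
#'
#' At every included voxel, fits outcome ~ intercept + lesion status +
#' covariates by least squares and stores the t statistic of the lesion
#' coefficient. A voxel enters the analysis when lesioned in at least
#' `min_lesioned` subjects (and intact in at least `min_intact`); voxels
#' whose lesion indicator is collinear with the covariates are excluded and
#' counted. Excluded voxels carry NaN.
#'
#' @param masks list of [lesion_mask], or a matrix from [lesion_matrix()].
#' @param behavior harmonized behavior table (see [harmonize()]); rows must
#'   match masks 1:1.
#' @param spec [design_spec].
#' @return object of class `stat_map`: t volume, inclusion mask, per-voxel
#'   lesion counts, affine, residual df, plus the fitted ingredients reused
#'   by [permutation_correct()].
#' @export
voxelwise_glm <- function(masks, behavior, spec = design_spec()) {
  L <- if (is.matrix(masks)) masks else lesion_matrix(masks)
  gdim <- attr(L, "grid_dim"); affine <- attr(L, "affine")
  n <- nrow(L)
  if (nrow(behavior) != n)
    stop("behavior rows (", nrow(behavior), ") do not match masks (", n, ")")
  y <- behavior[[spec$outcome]]
  if (is.null(y)) stop("behavior table lacks outcome column: ", spec$outcome)
  counts <- colSums(L)
  include <- counts >= spec$min_lesioned & (n - counts) >= spec$min_intact
  Z <- covariate_matrix(behavior, spec$covariates)
  df <- n - ncol(Z) - 1L
  if (df < 1L) stop("not enough subjects for the requested design")
  Q <- qr.Q(qr(Z))
  Li <- L[, include, drop = FALSE]
  Lr <- Li - Q %*% crossprod(Q, Li)
  rll <- colSums(Lr^2)
  # rank guard: lesion indicator explained by covariates -> exclude
  degenerate <- rll <= 1e-10 * counts[include]
  n_rank_excluded <- sum(degenerate)
  if (n_rank_excluded > 0) {
    idx <- which(include)[degenerate]
    include[idx] <- FALSE
    Lr <- Lr[, !degenerate, drop = FALSE]
    rll <- rll[!degenerate]
    message(n_rank_excluded, " voxel(s) excluded: lesion status collinear with covariates")
  }
  yr <- y - Q %*% crossprod(Q, y)
  tvals <- fwl_t(Lr, rll, yr, df, y_scale = sum(y^2))[, 1]
  tvol <- array(NaN, dim = gdim)
  tvol[include] <- tvals
  structure(list(t = tvol, include = array(include, gdim),
                 n_lesioned = array(as.integer(counts), gdim),
                 affine = affine, df = df,
                 n_rank_excluded = n_rank_excluded,
                 .fit = list(Q = Q, Lr = Lr, rll = rll, y = y,
                             include_idx = which(include), grid_dim = gdim)),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s, %d included voxels, df = %d\n",
              paste(dim(x$t), collapse = " x "), sum(x$include), x$df))
  invisible(x)
}

# all permutations of 1..n (n <= 8), one per column
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  cols <- lapply(seq_len(n), function(pos) {
    top <- sub[seq_len(pos - 1L), , drop = FALSE]
    bot <- if (pos <= n - 1L) sub[pos:(n - 1L), , drop = FALSE]
           else sub[0L, , drop = FALSE]
    rbind(top, matrix(n, 1L, ncol(sub)), bot)
  })
  do.call(cbind, cols)
}

# permutation index matrix (n x B); exhaustive when feasible and requested
# count covers the whole group, else simple random draws
permutation_matrix <- function(n, n_permutations, seed) {
  n_distinct <- if (n <= 8L) factorial(n) else Inf
  if (n_permutations >= n_distinct) {
    message("exhaustive enumeration: all ", n_distinct, " permutations used")
    list(perms = all_permutations(n), exhaustive = TRUE)
  } else {
    set.seed(seed)
    list(perms = vapply(seq_len(n_permutations), function(b) sample.int(n),
                        integer(n)),
         exhaustive = FALSE)
  }
}

#' Permutation-based familywise correction
#'
#' Re-fits the voxelwise GLM with the outcome vector shuffled across
#' subjects (lesions and covariates fixed), recording per permutation the
#' extreme statistic over included voxels and the largest face-connected
#' suprathreshold extent at the primary threshold. Yields the empirical
#' critical value, per-voxel FWER-corrected p values under the
#' (B+1)-denominator convention, and the cluster-extent null. When the
#' requested permutation count covers all distinct orderings (n <= 8) the
#' enumeration is exhaustive and p values are exact proportions.
#'
#' @param statmap result of [voxelwise_glm()].
#' @param spec the same [design_spec].
#' @return list: `critical_value` (on the tail-adjusted scale: -t for the
#'   lower tail, |t| two-sided), `fwer_p` (3D array), `max_null`,
#'   `cluster_null` (max extents per permutation), `cluster_forming_t`,
#'   `exhaustive`, `n_permutations`.
#' @export
permutation_correct <- function(statmap, spec) {
  fit <- statmap$.fit
  if (length(fit$include_idx) == 0L)
    return(list(critical_value = Inf, fwer_p = array(NaN, fit$grid_dim),
                max_null = numeric(0), cluster_null = integer(0),
                cluster_forming_t = NA_real_, exhaustive = FALSE,
                n_permutations = 0L))
  n <- length(fit$y)
  pm <- permutation_matrix(n, spec$n_permutations, spec$seed)
  B <- ncol(pm$perms)
  Yp <- matrix(fit$y[pm$perms], n, B)
  Yr <- Yp - fit$Q %*% crossprod(fit$Q, Yp)
  Tm <- fwl_t(fit$Lr, fit$rll, Yr, statmap$df, y_scale = colSums(Yp^2))
  adj <- function(t) if (spec$tail == "lower") -t else abs(t)
  S <- adj(Tm)
  s_obs <- adj(statmap$t[fit$include_idx])
  max_null <- apply(S, 2, max)
  crit <- as.numeric(stats::quantile(max_null, 1 - spec$alpha, type = 1))
  if (pm$exhaustive) {
    p_incl <- vapply(s_obs, function(s) mean(max_null >= s - 1e-12), numeric(1))
  } else {
    p_incl <- vapply(s_obs, function(s) (1 + sum(max_null >= s - 1e-12)) / (B + 1),
                     numeric(1))
  }
  fwer_p <- array(NaN, dim = fit$grid_dim)
  fwer_p[fit$include_idx] <- p_incl
  t_primary <- stats::qt(1 - spec$cluster_forming_alpha, statmap$df)
  cluster_null <- max_extent_batch_cpp(S, fit$include_idx - 1L,
                                       as.integer(fit$grid_dim), t_primary)
  list(critical_value = crit, fwer_p = fwer_p, max_null = max_null,
       cluster_null = as.integer(cluster_null),
       cluster_forming_t = t_primary,
       exhaustive = pm$exhaustive, n_permutations = B)
}

#' Full univariate lesion-symptom mapping analysis
#'
#' [voxelwise_glm()] + [permutation_correct()] + cluster extraction of the
#' FWER-significant voxels (per-voxel corrected p <= alpha).
#'
#' @inheritParams voxelwise_glm
#' @return object of class `vlsm_result`: `statmap`, `perm`,
#'   `significant_mask` ([lesion_mask]), `clusters` (see
#'   [extract_clusters()]), and cluster-extent p values.
#' @export
vlsm <- function(masks, behavior, spec = design_spec()) {
  sm <- voxelwise_glm(masks, behavior, spec)
  pc <- permutation_correct(sm, spec)
  sig <- !is.nan(pc$fwer_p) & pc$fwer_p <= spec$alpha
  sig_mask <- lesion_mask(array(as.integer(sig), dim(sm$t)), sm$affine)
  stat_adj <- if (spec$tail == "lower") -sm$t else abs(sm$t)
  clusters <- clusters_from_mask(sig, sm$affine, stat_adj)
  B <- pc$n_permutations
  cluster_p <- vapply(clusters, function(cl)
    (1 + sum(pc$cluster_null >= cl$n_voxels)) / (B + 1), numeric(1))
  structure(list(statmap = sm, perm = pc, significant_mask = sig_mask,
                 clusters = clusters, cluster_extent_p = cluster_p,
                 spec = spec),
            class = "vlsm_result")
}

#' @export
print.vlsm_result <- function(x, ...) {
  cat(sprintf("<vlsm_result> %d significant voxel(s) in %d cluster(s) at FWER alpha = %g\n",
              sum(x$significant_mask$data), length(x$clusters), x$spec$alpha))
  for (cl in x$clusters)
    cat(sprintf("  cluster: %d voxels, %.2f cm^3, center of mass (%.1f, %.1f, %.1f) mm\n",
                cl$n_voxels, cl$volume_cm3, cl$center_of_mass_mm[1],
                cl$center_of_mass_mm[2], cl$center_of_mass_mm[3]))
  invisible(x)
}

#' Re-run the univariate pipeline on a subgroup and compare clusters
#'
#' Runs the full VLSM on the subset selected by `subset` and reports the
#' Dice similarity and the Euclidean center-of-mass distance between the
#' subgroup's largest significant cluster and a reference cluster mask
#' (typically the full-cohort result), mirroring an etiology-restricted
#' sensitivity analysis.
#'
#' @param masks list of [lesion_mask].
#' @param behavior harmonized behavior table.
#' @param subset logical vector over subjects, or a predicate function of
#'   the behavior data.frame returning one.
#' @param spec [design_spec].
#' @param reference [lesion_mask] to compare against (e.g. the full-cohort
#'   significant-cluster mask).
#' @return list: `result` (`vlsm_result` on the subset), `dice`,
#'   `com_distance_mm` (NA when either side has no significant cluster),
#'   `n_subset`.
#' @export
subgroup_rerun <- function(masks, behavior, subset, spec, reference) {
  keep <- if (is.function(subset)) subset(behavior) else subset
  keep <- as.logical(keep)
  if (!any(keep)) stop("subset selects no subjects")
  if (sum(keep) < spec$min_lesioned + 2L)
    stop("subset too small: need at least min_lesioned + 2 subjects")
  res <- vlsm(masks[keep], behavior[keep, , drop = FALSE], spec)
  d <- dice(res$significant_mask, reference)
  com_dist <- NA_real_
  if (length(res$clusters) > 0 && sum(reference$data) > 0) {
    ref_cl <- clusters_from_mask(reference$data == 1, reference$affine,
                                 reference$data)
    com_dist <- sqrt(sum((res$clusters[[1]]$center_of_mass_mm -
                            ref_cl[[1]]$center_of_mass_mm)^2))
  }
  list(result = res, dice = d, com_distance_mm = com_dist, n_subset = sum(keep))
}
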