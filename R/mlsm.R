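#' Specification for multivariate (SVR) lesion-symptom mapping
#'
#' Defaults: linear kernel with `C = 1`, `epsilon = 0.1`. The linear kernel
#' makes the back-projected weight map equal the exact primal weight vector;
#' the rbf mode is provided for fidelity to the SVR-LSM family of tools, in
#' which case the back-projection is a sensitivity map.
#'
#' @param kernel `"linear"` or `"rbf"`.
#' @param C box constraint of the epsilon-SVR.
#' @param epsilon insensitive-tube half-width (outcome units).
#' @param gamma rbf bandwidth; default `1 / n_voxels` at fit time.
#' @param n_permutations,min_lesioned,min_intact,alpha,seed as in
#'   [design_spec()].
#' @param covariates,outcome as in [design_spec()]; the covariates are
#'   regressed out of the outcome before the SVR (not entered as features).
#' @return list of class `mlsm_spec`.
#' @export
mlsm_spec <- function(kernel = c("linear", "rbf"), C = 1, epsilon = 0.1,
                      gamma = NULL, n_permutations = 1000L,
                      min_lesioned = 5L, min_intact = 2L, alpha = 0.05,
                      outcome = "self_generated",
                      covariates = c("overall", "aos", "instrument",
                                     "days_post_surgery", "lesion_cm3"),
                      seed = 1L) {
  kernel <- match.arg(kernel)
  if (C <= 0) stop("C must be positive")
  if (epsilon < 0) stop("epsilon must be nonnegative")
  if (!is.null(gamma) && gamma <= 0) stop("gamma must be positive")
  structure(list(kernel = kernel, C = C, epsilon = epsilon, gamma = gamma,
                 n_permutations = as.integer(n_permutations),
                 min_lesioned = as.integer(min_lesioned),
                 min_intact = as.integer(min_intact), alpha = alpha,
                 outcome = outcome, covariates = covariates,
                 seed = as.integer(seed)),
            class = "mlsm_spec")
}

#' Residualize an outcome on nuisance covariates
#'
#' Least-squares regression of the outcome on an intercept plus the
#' covariate columns; returns residuals, which are exactly orthogonal to
#' every covariate column and to the intercept (mean zero).
#'
#' @param outcome numeric vector.
#' @param covariates numeric matrix of nuisance columns, without intercept.
#' @return residual vector.
#' @export
residualize <- function(outcome, covariates) {
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  if (nrow(X) != length(outcome)) stop("outcome and covariate rows differ")
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]], collapse = ", "))
  as.numeric(qr.resid(qrx, outcome))
}

#' Direct total lesion volume control
#'
#' Scales each subject's binary lesion row by the inverse square root of
#' that subject's lesioned-voxel count within the supplied matrix, so every
#' binary row has unit Euclidean norm. This decouples the fitted weight map
#' from overall lesion volume.
#'
#' @param lesions subjects x voxels binary matrix.
#' @return the scaled matrix.
#' @export
dtlvc <- function(lesions) {
  cnt <- rowSums(lesions)
  if (any(cnt == 0)) {
    who <- which(cnt == 0)
    nm <- rownames(lesions)[who]
    if (is.null(nm)) nm <- as.character(who)
    stop("subject(s) with no lesioned voxel in the matrix: ",
         paste(nm, collapse = ", "))
  }
  lesions / sqrt(cnt)
}

svr_kernel <- function(X, spec) {
  if (spec$kernel == "linear") return(tcrossprod(X))
  gamma <- if (is.null(spec$gamma)) 1 / ncol(X) else spec$gamma
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  exp(-gamma * D2)
}

#' Fit an epsilon-SVR lesion-symptom map
#'
#' Fits epsilon-SVR on the (dTLVC-scaled) lesion features against the
#' residualized outcome and back-projects the dual coefficients onto the
#' voxels: `w_v = sum_i beta_i x_iv`. For the linear kernel this equals the
#' primal weight vector exactly.
#'
#' @param lesions_scaled subjects x voxels feature matrix (see [dtlvc()]).
#' @param outcome residualized outcome vector.
#' @param spec [mlsm_spec].
#' @param tol,max_iter SMO termination controls.
#' @return list of class `svr_map`: `w` (per-voxel weight), `beta` (dual
#'   coefficients), `intercept`, `iterations`.
#' @export
fit_svr_map <- function(lesions_scaled, outcome, spec = mlsm_spec(),
                        tol = 1e-4, max_iter = 200000L) {
  n <- nrow(lesions_scaled)
  if (n < 2L) stop("at least 2 subjects are required")
  if (stats::sd(outcome) == 0) {
    warning("outcome is constant; returning an all-zero weight map")
    return(structure(list(w = numeric(ncol(lesions_scaled)),
                          beta = numeric(n), intercept = mean(outcome),
                          iterations = 0L),
                     class = "svr_map"))
  }
  K <- svr_kernel(lesions_scaled, spec)
  fit <- svr_smo_cpp(K, matrix(outcome, ncol = 1), spec$C, spec$epsilon,
                     tol, as.integer(max_iter))
  structure(list(w = as.numeric(crossprod(lesions_scaled, fit$beta[, 1])),
                 beta = fit$beta[, 1], intercept = fit$b[1],
                 iterations = fit$iterations[1]),
            class = "svr_map")
}

#' Permutation thresholding of the SVR weight map
#'
#' The residualized outcome is permuted across subjects; the SVR is re-fit
#' per permutation with identical hyperparameters (the kernel matrix is
#' permutation-invariant and reused) and the weight map re-projected. The
#' per-voxel p value is `(1 + #{|w_perm| >= |w_obs|}) / (B + 1)`; on tiny
#' cohorts where the requested count covers all distinct orderings the
#' enumeration is exhaustive and p values are exact proportions.
#'
#' @inheritParams fit_svr_map
#' @param w_obs observed weight vector (from [fit_svr_map()]); refit when
#'   omitted.
#' @return list: `p` (per-voxel), `w_obs`, `exhaustive`, `n_permutations`.
#' @export
mlsm_permute <- function(lesions_scaled, outcome, spec = mlsm_spec(),
                         w_obs = NULL, tol = 1e-4, max_iter = 200000L) {
  n <- nrow(lesions_scaled)
  if (is.null(w_obs)) w_obs <- fit_svr_map(lesions_scaled, outcome, spec,
                                           tol, max_iter)$w
  K <- svr_kernel(lesions_scaled, spec)
  pm <- permutation_matrix(n, spec$n_permutations, spec$seed)
  B <- ncol(pm$perms)
  Yp <- matrix(outcome[pm$perms], n, B)
  fit <- svr_smo_cpp(K, Yp, spec$C, spec$epsilon, tol, as.integer(max_iter))
  Wp <- crossprod(lesions_scaled, fit$beta)          # V x B
  exceed <- rowSums(abs(Wp) >= abs(w_obs) - 1e-12)
  p <- if (pm$exhaustive) exceed / B else (1 + exceed) / (B + 1)
  list(p = p, w_obs = w_obs, exhaustive = pm$exhaustive, n_permutations = B)
}

#' Full multivariate lesion-symptom mapping analysis
#'
#' Applies the voxel-inclusion rule, regresses the nuisance covariates out
#' of the outcome, applies direct total lesion volume control to the
#' included lesion features, fits the SVR map, permutation-thresholds it,
#' and extracts the significant clusters (per-voxel p <= alpha).
#'
#' @param masks list of [lesion_mask] or a [lesion_matrix()] matrix.
#' @param behavior harmonized behavior table.
#' @param spec [mlsm_spec].
#' @return object of class `mlsm_result`: `weight_map` and `p_map` (3D,
#'   NaN off-inclusion), `significant_mask`, `clusters`, `include`,
#'   `spec`.
#' @export
mlsm <- function(masks, behavior, spec = mlsm_spec()) {
  L <- if (is.matrix(masks)) masks else lesion_matrix(masks)
  gdim <- attr(L, "grid_dim"); affine <- attr(L, "affine")
  n <- nrow(L)
  if (nrow(behavior) != n)
    stop("behavior rows (", nrow(behavior), ") do not match masks (", n, ")")
  counts <- colSums(L)
  include <- counts >= spec$min_lesioned & (n - counts) >= spec$min_intact
  if (!any(include)) stop("no voxel passes the inclusion threshold")
  y <- behavior[[spec$outcome]]
  if (is.null(y)) stop("behavior table lacks outcome column: ", spec$outcome)
  Z <- covariate_matrix(behavior, spec$covariates)
  yr <- residualize(y, Z[, -1, drop = FALSE])
  # scale by each subject's *total* lesioned-voxel count, then subset to the
  # included voxels: a subject whose whole lesion falls below the inclusion
  # threshold contributes an all-zero (not undefined) feature row
  rownames(L) <- behavior$subject_id
  Xs <- dtlvc(L)[, include, drop = FALSE]
  obs <- fit_svr_map(Xs, yr, spec)
  perm <- mlsm_permute(Xs, yr, spec, w_obs = obs$w)
  wvol <- array(NaN, gdim); wvol[include] <- obs$w
  pvol <- array(NaN, gdim); pvol[include] <- perm$p
  sig <- !is.nan(pvol) & pvol <= spec$alpha
  sig_mask <- lesion_mask(array(as.integer(sig), gdim), affine)
  clusters <- clusters_from_mask(sig, affine, abs(wvol))
  structure(list(weight_map = wvol, p_map = pvol,
                 significant_mask = sig_mask, clusters = clusters,
                 include = array(include, gdim), affine = affine,
                 fit = obs, exhaustive = perm$exhaustive,
                 n_permutations = perm$n_permutations, spec = spec),
            class = "mlsm_result")
}

#' @export
print.mlsm_result <- function(x, ...) {
  cat(sprintf("<mlsm_result> %s kernel, %d significant voxel(s) in %d cluster(s) at alpha = %g\n",
              x$spec$kernel, sum(x$significant_mask$data), length(x$clusters),
              x$spec$alpha))
  invisible(x)
}
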