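#' Dice similarity coefficient of two binary masks
#'
#' `2|A ∩ B| / (|A| + |B|)`; defined as 0 (with a warning) when both masks
#' are empty.
#'
#' @param a,b [lesion_mask] objects on the same grid.
#' @return real in \[0, 1\].
#' @export
dice <- function(a, b) {
  stop_if_grid_mismatch(a, b)
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0) {
    warning("both masks are empty; Dice defined as 0")
    return(0)
  }
  2 * sum(a$data * b$data) / (na + nb)
}

#' Intersect two cluster masks into an LSM-ROI
#'
#' Voxelwise AND of two binary masks — the region-of-interest construction
#' that combines the univariate and multivariate significant clusters.
#'
#' @param a,b [lesion_mask] objects on the same grid.
#' @return [lesion_mask]; empty with a warning when the masks are disjoint.
#' @export
intersect_rois <- function(a, b) {
  stop_if_grid_mismatch(a, b)
  out <- lesion_mask(a$data * b$data, a$affine)
  if (sum(out$data) == 0) warning("cluster intersection is empty")
  out
}

sd_rule_flags <- function(x, k = 1.5) {
  s <- stats::sd(x)   # sample SD, denominator n - 1
  if (s == 0) {
    warning("zero standard deviation; no subject flagged")
    return(list(flag = rep(FALSE, length(x)), threshold = Inf))
  }
  thr <- mean(x) + k * s
  list(flag = x >= thr, threshold = thr)
}

#' Classify subjects as having an ROI resection
#'
#' A subject counts as an ROI resection when the Dice similarity of their
#' lesion with the LSM-ROI is at least 1.5 sample standard deviations above
#' the cohort mean, the threshold being recomputed from the supplied cohort.
#'
#' @param masks list of [lesion_mask], one per subject.
#' @param lsm_roi [lesion_mask].
#' @return list: `flag` (logical per subject), `dsc` (Dice per subject),
#'   `threshold`.
#' @export
classify_roi_resection <- function(masks, lsm_roi) {
  if (length(masks) < 2L) stop("at least 2 subjects are required")
  dsc <- vapply(masks, dice, numeric(1), b = lsm_roi)
  r <- sd_rule_flags(dsc)
  list(flag = r$flag, dsc = dsc, threshold = r$threshold)
}

#' Classify subjects as having a disproportionate self-generated speech deficit
#'
#' The per-subject difference `d = overall - self_generated` is flagged when
#' at least 1.5 sample standard deviations above the cohort mean, with the
#' additional stipulation that no apraxia of speech be present. The
#' threshold is computed on all subjects; the AOS exclusion is applied
#' afterwards.
#'
#' @param harmonized data.frame with `overall`, `self_generated` and `aos`.
#' @return list: `flag`, `difference`, `threshold`.
#' @export
classify_deficit <- function(harmonized) {
  need <- c("overall", "self_generated", "aos")
  miss <- setdiff(need, names(harmonized))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(harmonized) < 2L) stop("at least 2 subjects are required")
  d <- harmonized$overall - harmonized$self_generated
  r <- sd_rule_flags(d)
  list(flag = r$flag & !(harmonized$aos > 0), difference = d,
       threshold = r$threshold)
}

#' Cross-tabulate ROI-resection and deficit flags
#'
#' @param roi_flags,deficit_flags logical vectors of equal length.
#' @return object of class `contingency_table` with counts `a` (ROI and
#'   deficit), `b` (ROI, no deficit), `c` (no ROI, deficit), `d` (neither).
#' @export
contingency <- function(roi_flags, deficit_flags) {
  if (length(roi_flags) != length(deficit_flags))
    stop("flag vectors differ in length")
  contingency_table(a = sum(roi_flags & deficit_flags),
                    b = sum(roi_flags & !deficit_flags),
                    c = sum(!roi_flags & deficit_flags),
                    d = sum(!roi_flags & !deficit_flags))
}

#' Construct a 2x2 contingency table from counts
#'
#' @param a,b,c,d nonnegative counts: rows are deficit / no deficit, columns
#'   ROI resection / no ROI resection (`a` = exposed with outcome).
#' @return object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop("counts must be nonnegative")
  structure(as.list(counts), n = sum(counts), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> a=%g b=%g c=%g d=%g (N=%g)\n",
              x$a, x$b, x$c, x$d, attr(x, "n")))
  invisible(x)
}

apply_correction <- function(t) contingency_table(t$a + 0.5, t$b + 0.5,
                                                  t$c + 0.5, t$d + 0.5)

#' Relative risk with Katz log confidence interval
#'
#' `RR = [a/(a+b)] / [c/(c+d)]`, CI
#' `exp(ln RR ± z * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`.
#'
#' @param t [contingency_table].
#' @param level confidence level (default 0.95).
#' @param correction add 0.5 to every cell (needed when `a` or `c` is 0).
#' @return list of class `effect_estimate`: `measure`, `point`, `ci_low`,
#'   `ci_high`, `level`.
#' @export
relative_risk <- function(t, level = 0.95, correction = FALSE) {
  if (correction) t <- apply_correction(t)
  if (t$a + t$b == 0 || t$c + t$d == 0)
    stop("both exposure groups must be nonempty")
  if (t$a == 0 || t$c == 0)
    stop("zero event count; rerun with correction = TRUE for a continuity-corrected estimate")
  rr <- (t$a / (t$a + t$b)) / (t$c / (t$c + t$d))
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / t$a - 1 / (t$a + t$b) + 1 / t$c - 1 / (t$c + t$d))
  effect_estimate("RR", rr, exp(log(rr) - z * se), exp(log(rr) + z * se), level)
}

#' Odds ratio with Woolf log confidence interval
#'
#' `OR = ad/(bc)`, CI `exp(ln OR ± z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @inheritParams relative_risk
#' @return list of class `effect_estimate`.
#' @export
odds_ratio <- function(t, level = 0.95, correction = FALSE) {
  if (correction) t <- apply_correction(t)
  if (any(unlist(t[c("a", "b", "c", "d")]) == 0))
    stop("all four cells must be positive; rerun with correction = TRUE")
  or <- (t$a * t$d) / (t$b * t$c)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  effect_estimate("OR", or, exp(log(or) - z * se), exp(log(or) + z * se), level)
}

effect_estimate <- function(measure, point, ci_low, ci_high, level) {
  structure(list(measure = measure, point = point, ci_low = ci_low,
                 ci_high = ci_high, level = level),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s = %.2f, %d%% CI [%.2f, %.2f]\n", x$measure, x$point,
              round(100 * x$level), x$ci_low, x$ci_high))
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson chi-square on the r x c cross-tabulation of two label
#' vectors; levels with zero marginal count are dropped with a warning.
#' Yates continuity correction is available for 2x2 tables via `correct`.
#'
#' @param labels_a,labels_b vectors of equal length (coerced to factor).
#' @param correct apply the Yates correction (2x2 only).
#' @return list: `statistic`, `df`, `p_value`, `observed`, `expected`.
#' @export
chi_square_independence <- function(labels_a, labels_b, correct = FALSE) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors differ in length")
  fa <- if (is.factor(labels_a)) labels_a else factor(labels_a)
  fb <- if (is.factor(labels_b)) labels_b else factor(labels_b)
  tab <- table(fa, fb)
  zero_r <- rowSums(tab) == 0; zero_c <- colSums(tab) == 0
  if (any(zero_r) || any(zero_c)) {
    warning("dropping level(s) with zero marginal count")
    tab <- tab[!zero_r, !zero_c, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("each label vector must retain at least 2 levels")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  dev <- abs(tab - E)
  if (correct) {
    if (!all(dim(tab) == 2L)) stop("Yates correction applies to 2x2 tables only")
    dev <- pmax(dev - 0.5, 0)
  }
  stat <- sum(dev^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       observed = tab, expected = E)
}

#' Mann-Whitney rank-sum test
#'
#' U statistic for the first sample using midranks for ties. The two-sided
#' p value is exact (Wilcoxon distribution) when there are no ties and
#' `n_a * n_b` is small, otherwise a normal approximation with tie
#' correction is used. The exact two-sided p is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param values_a,values_b numeric vectors, both nonempty.
#' @param exact_limit use the exact distribution when `n_a * n_b` is at most
#'   this (and no ties are present).
#' @return list: `U`, `p_value`, `exact`.
#' @export
rank_sum <- function(values_a, values_b, exact_limit = 400L) {
  na <- length(values_a); nb <- length(values_b)
  if (na == 0 || nb == 0) stop("both samples must be nonempty")
  pooled <- c(values_a, values_b)
  r <- rank(pooled)           # midranks
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(pooled))
  if (!ties && na * nb <= exact_limit) {
    p_le <- stats::pwilcox(u, na, nb)
    p_ge <- 1 - if (u >= 1) stats::pwilcox(u - 1, na, nb) else 0
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(U = u, p_value = p, exact = TRUE))
  }
  N <- na + nb
  mu <- na * nb / 2
  tie_counts <- table(pooled)
  tie_term <- sum(tie_counts^3 - tie_counts) / (N * (N - 1))
  sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
  z <- (u - mu) / sqrt(sigma2)
  list(U = u, p_value = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
}

#' Percent damage to an atlas region
#'
#' `100 * |mask ∩ region| / |region|` for the atlas voxels carrying `label`.
#'
#' @param mask [lesion_mask].
#' @param atlas integer-labelled 3D array or a [lesion_mask]-like list with
#'   `data`/`affine` on the same grid.
#' @param label integer region label, must be present in the atlas.
#' @return percent in \[0, 100\].
#' @export
region_damage_percent <- function(mask, atlas, label) {
  adata <- if (is.list(atlas)) {
    stop_if_grid_mismatch(mask, atlas, "mask and atlas")
    atlas$data
  } else {
    if (!identical(dim(atlas), dim(mask$data)))
      stop("mask and atlas are not on the same grid (dim or affine mismatch)")
    atlas
  }
  region <- adata == label
  if (!any(region)) stop("label ", label, " is absent from the atlas")
  100 * sum(mask$data[region]) / sum(region)
}
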