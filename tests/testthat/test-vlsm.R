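# small handcrafted cohort: 10 subjects, 4x4x4 grid
handmade_cohort <- function(n = 10, gdim = c(4L, 4L, 4L), seed = 9) {
  set.seed(seed)
  masks <- lapply(seq_len(n), function(i)
    make_mask(gdim, which(array(runif(prod(gdim)) < 0.4, gdim))))
  y <- rnorm(n, 6, 2)
  behavior <- data.frame(subject_id = sprintf("s%02d", seq_len(n)),
                         self_generated = y,
                         overall = rnorm(n, 7, 1),
                         aos = rbinom(n, 1, 0.2),
                         days_post_surgery = sample(1:5, n, TRUE),
                         lesion_cm3 = vapply(masks, function(m) sum(m$data) * 0.008, 1))
  list(masks = masks, behavior = behavior)
}

test_that("voxel t with no covariates equals the pooled two-sample t", {
  co <- handmade_cohort()
  spec <- design_spec(covariates = character(0), min_lesioned = 3,
                      min_intact = 3, n_permutations = 10)
  sm <- voxelwise_glm(co$masks, co$behavior, spec)
  y <- co$behavior$self_generated
  L <- lesion_matrix(co$masks)
  idx <- which(sm$include)
  for (v in idx[c(1, 5, 10, length(idx))]) {
    les <- L[, v] == 1
    tt <- t.test(y[les], y[!les], var.equal = TRUE)
    # lesion-coefficient t = (mean lesioned - mean intact) / se
    expect_equal(sm$t[v], unname(tt$statistic), tolerance = 1e-10)
  }
})

test_that("constant outcomes give t = 0 and sparse voxels are excluded", {
  co <- handmade_cohort()
  co$behavior$self_generated <- rep(4, nrow(co$behavior))
  spec <- design_spec(covariates = character(0), min_lesioned = 3, min_intact = 3)
  sm <- voxelwise_glm(co$masks, co$behavior, spec)
  expect_true(all(sm$t[sm$include] == 0))

  # a voxel lesioned in 4 subjects is excluded when min_lesioned = 5
  co2 <- handmade_cohort(n = 12)
  L <- lesion_matrix(co2$masks)
  v4 <- which(colSums(L) == 4)[1]
  expect_false(is.na(v4))
  sm2 <- voxelwise_glm(co2$masks, co2$behavior,
                       design_spec(covariates = character(0), min_lesioned = 5,
                                   min_intact = 1))
  expect_false(sm2$include[v4])
  expect_true(is.nan(sm2$t[v4]))
})

test_that("lesion indicators collinear with a covariate trigger the rank guard", {
  co <- handmade_cohort()
  L <- lesion_matrix(co$masks)
  v <- which(colSums(L) >= 3 & colSums(L) <= 7)[1]
  co$behavior$copyvox <- L[, v]
  spec <- design_spec(covariates = "copyvox", min_lesioned = 3, min_intact = 3)
  expect_message(sm <- voxelwise_glm(co$masks, co$behavior, spec),
                 "collinear with covariates")
  expect_false(sm$include[v])
  expect_gte(sm$n_rank_excluded, 1L)
})

test_that("exhaustive permutation p-values match full enumeration via lm refits", {
  co <- handmade_cohort(n = 5, gdim = c(3L, 3L, 3L), seed = 21)
  spec <- design_spec(covariates = character(0), min_lesioned = 2,
                      min_intact = 2, n_permutations = 120, tail = "lower",
                      seed = 4)
  sm <- voxelwise_glm(co$masks, co$behavior, spec)
  expect_message(pc <- permutation_correct(sm, spec), "exhaustive")
  expect_true(pc$exhaustive)
  expect_equal(pc$n_permutations, 120L)

  # oracle: refit every permutation at every included voxel with lm()
  y <- co$behavior$self_generated
  L <- lesion_matrix(co$masks)
  idx <- which(sm$include)
  perms <- all_perms_oracle(5L)
  max_null <- vapply(perms, function(p) {
    ts <- vapply(idx, function(v) {
      fit <- summary(lm(y[p] ~ L[, v]))
      unname(coef(fit)[2, "t value"])
    }, numeric(1))
    max(-ts)  # lower tail
  }, numeric(1))
  for (v in idx) {
    p_oracle <- mean(max_null >= -sm$t[v] - 1e-9)
    expect_equal(pc$fwer_p[v], p_oracle, tolerance = 1e-9)
  }
})

test_that("alpha = 1 declares every included voxel significant", {
  co <- handmade_cohort()
  spec <- design_spec(covariates = character(0), min_lesioned = 3,
                      min_intact = 3, n_permutations = 50, alpha = 1)
  res <- vlsm(co$masks, co$behavior, spec)
  expect_identical(res$significant_mask$data == 1L, res$statmap$include)
})

test_that("permutation outputs are bit-identical for a fixed seed", {
  co <- handmade_cohort(n = 14)
  spec <- design_spec(covariates = c("overall", "lesion_cm3"), min_lesioned = 4,
                      min_intact = 3, n_permutations = 60, seed = 99)
  sm <- voxelwise_glm(co$masks, co$behavior, spec)
  p1 <- permutation_correct(sm, spec)
  p2 <- permutation_correct(sm, spec)
  expect_identical(p1$fwer_p, p2$fwer_p)
  expect_identical(p1$cluster_null, p2$cluster_null)
})

test_that("subgroup_rerun reports self-similarity and disjoint references", {
  co <- generate_cohort(tiny_config(n_subjects = 20, noise_sd = 0.5))
  b <- harmonize(co$behavior)
  spec <- design_spec(min_lesioned = 4, n_permutations = 50, seed = 3)
  full <- suppressMessages(suppressWarnings(vlsm(co$masks, b, spec)))
  all_in <- suppressMessages(suppressWarnings(
    subgroup_rerun(co$masks, b, rep(TRUE, 20), spec, full$significant_mask)))
  expect_equal(all_in$dice, 1.0)
  if (!is.na(all_in$com_distance_mm)) expect_equal(all_in$com_distance_mm, 0)

  far <- make_mask(dim(full$significant_mask$data), integer(0))
  far$data[1, 1, 1] <- 1L
  d <- suppressMessages(suppressWarnings(
    subgroup_rerun(co$masks, b, rep(TRUE, 20), spec, far)))
  expect_equal(d$dice, 0)
  expect_error(subgroup_rerun(co$masks, b, rep(FALSE, 20), spec, far),
               "no subjects")
})
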