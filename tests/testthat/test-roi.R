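test_that("dice handles identity, disjoint, partial overlap and empty input", {
  gdim <- c(6L, 6L, 6L)
  a <- make_mask(gdim, 1:4)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, make_mask(gdim, 10:12)), 0)
  expect_equal(dice(a, make_mask(gdim, 3:4)), 2 * 2 / 6)
  expect_warning(z <- dice(make_mask(gdim, integer(0)), make_mask(gdim, integer(0))),
                 "empty")
  expect_equal(z, 0)
  expect_error(dice(a, make_mask(c(5L, 6L, 6L), 1)), "grid")
})

test_that("intersect_rois equals a brute-force voxel loop", {
  set.seed(3)
  gdim <- c(7L, 6L, 5L)
  a <- make_mask(gdim, which(runif(prod(gdim)) < 0.3))
  b <- make_mask(gdim, which(runif(prod(gdim)) < 0.3))
  r <- intersect_rois(a, b)
  manual <- array(0L, gdim)
  for (v in seq_len(prod(gdim)))
    manual[v] <- as.integer(a$data[v] == 1L && b$data[v] == 1L)
  expect_identical(r$data, manual)
  inner <- make_mask(gdim, which(a$data == 1L)[1:2])
  expect_identical(intersect_rois(inner, a)$data, inner$data)
  expect_warning(intersect_rois(make_mask(gdim, 1), make_mask(gdim, 2)), "empty")
})

test_that("1.5-SD classification rules match longhand computation", {
  gdim <- c(6L, 6L, 6L)
  roi <- make_mask(gdim, 1:10)
  masks <- c(list(make_mask(gdim, 1:9)),                    # near-perfect overlap
             lapply(1:9, function(i) make_mask(gdim, 100 + i)))  # no overlap
  r <- classify_roi_resection(masks, roi)
  dsc <- vapply(masks, function(m) {
    inter <- sum(m$data * roi$data)
    2 * inter / (sum(m$data) + sum(roi$data))
  }, numeric(1))
  thr <- mean(dsc) + 1.5 * sd(dsc)
  expect_equal(r$dsc, dsc)
  expect_identical(r$flag, dsc >= thr)
  expect_identical(which(r$flag), 1L)

  # identical DSC everywhere -> zero SD -> no flags, warning
  same <- lapply(1:5, function(i) make_mask(gdim, 1:5))
  expect_warning(r0 <- classify_roi_resection(same, roi), "zero standard deviation")
  expect_false(any(r0$flag))
})

test_that("deficit classification applies the AOS stipulation after thresholding", {
  h <- data.frame(overall = c(8, 8, 8, 8, 8, 8, 8, 8),
                  self_generated = c(1, 1.5, 8, 8, 8, 8, 8, 8),
                  aos = c(0, 1, 0, 0, 0, 0, 0, 0))
  d <- h$overall - h$self_generated
  thr <- mean(d) + 1.5 * sd(d)
  r <- classify_deficit(h)
  expect_equal(r$difference, d)
  expect_identical(r$flag, d >= thr & h$aos == 0)
  # subject 2 exceeds the threshold but has AOS -> not flagged
  expect_true(d[2] >= thr)
  expect_false(r$flag[2])
  expect_true(r$flag[1])

  expect_warning(r0 <- classify_deficit(data.frame(overall = rep(5, 4),
                                                   self_generated = rep(2, 4),
                                                   aos = 0)),
                 "zero standard deviation")
  expect_false(any(r0$flag))
})

test_that("contingency cross-tabulates flags and flag order is immaterial", {
  tab <- contingency(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(contingency(rep(FALSE, 7), rep(FALSE, 7))$d, 7)

  set.seed(2)
  rf <- runif(30) < 0.3; df_ <- runif(30) < 0.4
  o <- sample(30)
  t1 <- contingency(rf, df_); t2 <- contingency(rf[o], df_[o])
  expect_identical(unclass(t1), unclass(t2))
})

test_that("relative risk and odds ratio have the standard closed forms", {
  t0 <- contingency_table(5, 5, 5, 5)
  expect_equal(relative_risk(t0)$point, 1)
  rr0 <- relative_risk(t0)
  expect_true(rr0$ci_low < 1 && rr0$ci_high > 1)
  expect_equal(odds_ratio(contingency_table(2, 4, 3, 6))$point, 1)

  # row-swap inversion invariance
  tt <- contingency_table(7, 3, 4, 11)
  expect_equal(relative_risk(tt)$point,
               1 / relative_risk(contingency_table(4, 11, 7, 3))$point,
               tolerance = 1e-12)
  expect_equal(odds_ratio(tt)$point,
               1 / odds_ratio(contingency_table(4, 11, 7, 3))$point,
               tolerance = 1e-12)

  expect_error(relative_risk(contingency_table(0, 5, 3, 7)), "correction")
  rc <- relative_risk(contingency_table(0, 5, 3, 7), correction = TRUE)
  expect_true(rc$point > 0 && rc$ci_low <= rc$point && rc$point <= rc$ci_high)
  expect_error(odds_ratio(contingency_table(1, 0, 3, 7)), "correction")
})

test_that("chi-square matches the longhand sum over (O-E)^2/E", {
  # identical proportions -> 0
  even <- chi_square_independence(rep(c("x", "y"), each = 20),
                                  rep(c("p", "q"), times = 20))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)

  # 4x2 hand table
  a <- rep(c("A", "B", "C", "D"), times = c(6, 4, 5, 3))
  b <- c(rep(c("yes", "no"), c(4, 2)), rep(c("yes", "no"), c(1, 3)),
         rep(c("yes", "no"), c(3, 2)), rep(c("yes", "no"), c(2, 1)))
  res <- chi_square_independence(a, b)
  O <- table(factor(a), factor(b))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  stat_longhand <- sum((O - E)^2 / E)
  expect_equal(res$statistic, stat_longhand, tolerance = 1e-12)
  expect_equal(res$df, 3L)
  expect_equal(res$p_value, pchisq(stat_longhand, 3, lower.tail = FALSE))
  # agreement with the standard implementation, uncorrected
  expect_equal(res$statistic,
               unname(suppressWarnings(chisq.test(O, correct = FALSE))$statistic))

  expect_warning(chi_square_independence(factor(a, levels = c("A", "B", "C", "D", "E")),
                                         b), "zero marginal")
})

test_that("rank-sum U and exact p match brute-force enumeration", {
  expect_equal(rank_sum(c(7, 8, 9), c(1, 2, 3))$U, 9)
  expect_equal(rank_sum(c(1, 2, 3), c(1, 2, 3))$U, 3 * 3 / 2)

  set.seed(14)
  x <- round(rnorm(4), 3); y <- round(rnorm(5) + 0.5, 3)
  res <- rank_sum(x, y)
  expect_true(res$exact)
  # enumerate all assignments of ranks to group A
  pooled <- c(x, y); r <- rank(pooled)
  combos <- combn(9, 4)
  Us <- apply(combos, 2, function(ix) sum(r[ix]) - 4 * 5 / 2)
  u_obs <- sum(r[1:4]) - 4 * 5 / 2
  expect_equal(res$U, u_obs)
  p_enum <- min(1, 2 * min(mean(Us <= u_obs), mean(Us >= u_obs)))
  expect_equal(res$p_value, p_enum, tolerance = 1e-12)

  # ties fall back to the corrected normal approximation
  tied <- rank_sum(c(1, 2, 2, 3), c(2, 3, 3, 4))
  expect_false(tied$exact)
  expect_true(tied$p_value > 0 && tied$p_value <= 1)
})

test_that("region damage percent is the lesioned fraction of the region", {
  gdim <- c(6L, 6L, 6L)
  atlas <- array(0L, gdim); atlas[1:8] <- 7L; atlas[9:16] <- 3L
  expect_equal(region_damage_percent(make_mask(gdim, 1:20), atlas, 7), 100)
  expect_equal(region_damage_percent(make_mask(gdim, 30:40), atlas, 7), 0)
  expect_equal(region_damage_percent(make_mask(gdim, 1:4), atlas, 7), 50)
  expect_error(region_damage_percent(make_mask(gdim, 1:4), atlas, 99), "absent")
})
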