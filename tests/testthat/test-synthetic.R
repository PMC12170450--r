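test_that("generate_lesion rasterizes strictly-interior voxel centers", {
  cfg <- tiny_config()
  A <- centered_affine(cfg$grid_shape, cfg$voxel_size_mm)
  center <- as.numeric(A %*% c(7, 7, 7, 1))[1:3]  # a voxel center (0-based idx 7)
  m <- generate_lesion(center, c(2, 2, 2), cfg)
  expect_equal(sum(m$data), 1L)
  expect_equal(m$data[8, 8, 8], 1L)

  all_in <- generate_lesion(c(0, 0, 0), c(1e3, 1e3, 1e3), cfg)
  expect_true(all(all_in$data == 1L))
})

test_that("generate_lesion matches an exhaustive point-in-ellipsoid scan", {
  cfg <- tiny_config()
  center <- c(0, 0, 0); radii <- c(6, 4, 4)
  m <- generate_lesion(center, radii, cfg)
  A <- centered_affine(cfg$grid_shape, cfg$voxel_size_mm)
  expected <- array(0L, cfg$grid_shape)
  for (i in seq_len(cfg$grid_shape[1]))
    for (j in seq_len(cfg$grid_shape[2]))
      for (k in seq_len(cfg$grid_shape[3])) {
        mm <- as.numeric(A %*% c(i - 1, j - 1, k - 1, 1))[1:3]
        expected[i, j, k] <- as.integer(sum(((mm - center) / radii)^2) < 1)
      }
  expect_identical(m$data, expected)
})

test_that("off-grid ellipsoids error naming the center", {
  expect_error(generate_lesion(c(1000, 0, 0), c(2, 2, 2), tiny_config()),
               "1000")
})

test_that("cohort scores follow the stated generative model", {
  # no planted effect, no noise: self-generated equals 10 - volume term
  cfg <- tiny_config(effect_beta = 0, noise_sd = 0)
  co <- generate_cohort(cfg)
  h <- harmonize(co$behavior)
  vols <- vapply(co$masks, function(m) sum(m$data), numeric(1)) *
    cfg$voxel_size_mm^3 / 1000
  expect_equal(h$self_generated,
               pmin(10, pmax(0, 10 - cfg$overall_beta * vols / cfg$reference_volume_cm3)),
               tolerance = 1e-12)
  expect_equal(h$self_generated, h$overall, tolerance = 1e-12)

  # planted effect only: score = 10 - beta * coverage, exactly
  cfg2 <- tiny_config(effect_beta = 4, overall_beta = 0, noise_sd = 0)
  co2 <- generate_cohort(cfg2)
  h2 <- harmonize(co2$behavior)
  expect_equal(h2$self_generated, 10 - 4 * co2$truth$coverage, tolerance = 1e-12)
  # full coverage drops the score to 6
  if (any(co2$truth$coverage == 1))
    expect_equal(unique(h2$self_generated[co2$truth$coverage == 1]), 6)
  # strictly decreasing in coverage
  ord <- order(co2$truth$coverage)
  dcov <- diff(co2$truth$coverage[ord])
  dscore <- diff(h2$self_generated[ord])
  expect_true(all(dscore[dcov > 0] < 0))
})

test_that("coverage fractions equal independent mask-intersection arithmetic", {
  co <- generate_cohort(tiny_config())
  crit <- co$truth$critical_mask$data
  manual <- vapply(co$masks, function(m) sum(m$data & crit) / sum(crit), numeric(1))
  expect_equal(co$truth$coverage, manual, tolerance = 0)
})

test_that("AOS flag is tied to the AOS region and instruments are mixed", {
  co <- generate_cohort(tiny_config(n_subjects = 30))
  aosv <- co$truth$aos_mask$data
  manual <- vapply(co$masks, function(m) as.integer(sum(m$data & aosv) > 0), integer(1))
  expect_identical(co$behavior$aos, manual)
  expect_setequal(unique(co$behavior$instrument), c("WAB", "QAB"))
})

test_that("same seed gives bit-identical cohorts; tiny cohorts are rejected", {
  a <- generate_cohort(tiny_config())
  b <- generate_cohort(tiny_config())
  expect_identical(a$behavior, b$behavior)
  expect_identical(lapply(a$masks, `[[`, "data"), lapply(b$masks, `[[`, "data"))
  expect_error(sim_config(n_subjects = 1), "at least 2")
})

test_that("paired assessments share one latent profile", {
  p0 <- generate_paired_assessments(14, latent_sd = 1.5, seed = 5,
                                    instrument_noise_sd = 0)
  r0 <- validate_harmonization(p0)
  expect_equal(unname(r0), rep(1, 4), tolerance = 1e-12)

  p1 <- generate_paired_assessments(14, latent_sd = 1.5, seed = 5,
                                    instrument_noise_sd = 0.8)
  r1 <- validate_harmonization(p1)
  expect_true(all(r1 > 0 & r1 < 1))

  p2 <- generate_paired_assessments(14, latent_sd = 1.5, seed = 5,
                                    instrument_noise_sd = 0.8)
  expect_identical(p1, p2)
  expect_error(generate_paired_assessments(2), "at least 3")
})
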