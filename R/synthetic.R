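#' Ellipsoid specification in mm coordinates
#'
#' Axis-aligned ellipsoid used for synthetic lesions and planted regions.
#'
#' @param center_mm real triple, center in mm (world) coordinates.
#' @param radii_mm positive real triple, semi-axes in mm.
#' @return list of class `ellipsoid_spec`.
#' @export
ellipsoid_spec <- function(center_mm, radii_mm) {
  stopifnot(length(center_mm) == 3L, length(radii_mm) == 3L)
  if (any(radii_mm <= 0)) stop("ellipsoid radii must be positive")
  structure(list(center_mm = as.numeric(center_mm),
                 radii_mm = as.numeric(radii_mm)),
            class = "ellipsoid_spec")
}

#' Synthetic-cohort configuration
#'
#' Defaults emulate the cohort the pipeline is designed for: a 2 mm
#' isotropic grid, resections averaging ~21 cm^3 (sampled as lognormal
#' ellipsoid radii), a planted critical region whose coverage depresses the
#' self-generated speech score by `effect_beta` points at full coverage,
#' a global severity effect of lesion volume, an apraxia-of-speech region
#' disjoint from the critical region, evaluations 1-5 days post-surgery,
#' ages ~46 +/- 16 years, and etiologies in roughly the clinical mix of a
#' left-hemisphere resective neurosurgery service (gliomas ~80%).
#'
#' @param grid_shape integer triple of voxel counts (all >= 8).
#' @param voxel_size_mm isotropic voxel size, mm.
#' @param n_subjects cohort size (>= 2).
#' @param critical_region [ellipsoid_spec]: coverage of this region drives
#'   the self-generated speech deficit.
#' @param effect_beta score-point drop per unit coverage fraction.
#' @param overall_beta score-point drop per reference lesion volume.
#' @param aos_region [ellipsoid_spec] or NULL; any lesion overlap sets the
#'   AOS flag.
#' @param noise_sd Gaussian score noise SD (score points).
#' @param qab_fraction probability a subject is evaluated with the QAB.
#' @param reference_volume_cm3 lesion volume yielding an `overall_beta`-point
#'   severity drop; default the cohort-typical resection size.
#' @param lesion_radius_meanlog,lesion_radius_sdlog lognormal parameters for
#'   per-axis lesion semi-axes (mm).
#' @param center_margin fraction of each grid half-extent within which lesion
#'   centers are sampled (keeps lesions mostly on-grid).
#' @param seed integer RNG seed; identical seeds give bit-identical cohorts.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(grid_shape = c(32L, 36L, 32L),
                       voxel_size_mm = 2,
                       n_subjects = 60L,
                       critical_region = ellipsoid_spec(c(-6, 10, 10), c(10, 12, 10)),
                       effect_beta = 4,
                       overall_beta = 2,
                       aos_region = ellipsoid_spec(c(18, -14, -8), c(8, 8, 8)),
                       noise_sd = 1,
                       qab_fraction = 0.5,
                       reference_volume_cm3 = 21.43,
                       lesion_radius_meanlog = log(17),
                       lesion_radius_sdlog = 0.3,
                       center_margin = 0.7,
                       seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("grid_shape must be a triple of integers, all >= 8")
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be positive")
  if (n_subjects < 2L) stop("n_subjects must be at least 2")
  if (effect_beta < 0 || overall_beta < 0)
    stop("effect_beta and overall_beta must be nonnegative")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (qab_fraction < 0 || qab_fraction > 1)
    stop("qab_fraction must be in [0, 1]")
  stopifnot(inherits(critical_region, "ellipsoid_spec"))
  if (!is.null(aos_region)) stopifnot(inherits(aos_region, "ellipsoid_spec"))
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 n_subjects = as.integer(n_subjects),
                 critical_region = critical_region,
                 effect_beta = effect_beta, overall_beta = overall_beta,
                 aos_region = aos_region, noise_sd = noise_sd,
                 qab_fraction = qab_fraction,
                 reference_volume_cm3 = reference_volume_cm3,
                 lesion_radius_meanlog = lesion_radius_meanlog,
                 lesion_radius_sdlog = lesion_radius_sdlog,
                 center_margin = center_margin,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Rasterize an ellipsoid lesion onto the simulation grid
#'
#' A voxel is lesioned iff its center lies strictly inside the ellipsoid
#' (sum of squared normalized offsets < 1); centers exactly on the surface
#' are outside, so 2 mm radii at 2 mm spacing hit exactly one voxel.
#'
#' @param center_mm,radii_mm ellipsoid in mm.
#' @param config [sim_config] supplying grid shape and voxel size.
#' @return [lesion_mask].
#' @export
generate_lesion <- function(center_mm, radii_mm, config) {
  d <- config$grid_shape
  A <- centered_affine(d, config$voxel_size_mm)
  arr <- array(0L, dim = d)
  # axis coordinates of voxel centers (diagonal affine)
  ax <- lapply(1:3, function(k) A[k, k] * (seq_len(d[k]) - 1) + A[k, 4])
  # bounding box of the ellipsoid on each axis
  rng <- lapply(1:3, function(k)
    which(ax[[k]] > center_mm[k] - radii_mm[k] &
          ax[[k]] < center_mm[k] + radii_mm[k]))
  if (any(vapply(rng, length, 1L) == 0L))
    stop(sprintf("ellipsoid centered at (%g, %g, %g) mm covers no voxel center",
                 center_mm[1], center_mm[2], center_mm[3]))
  u <- lapply(1:3, function(k) ((ax[[k]][rng[[k]]] - center_mm[k]) / radii_mm[k])^2)
  q <- outer(outer(u[[1]], u[[2]], `+`), u[[3]], `+`)
  inside <- q < 1
  if (!any(inside))
    stop(sprintf("ellipsoid centered at (%g, %g, %g) mm covers no voxel center",
                 center_mm[1], center_mm[2], center_mm[3]))
  arr[rng[[1]], rng[[2]], rng[[3]]] <- as.integer(inside)
  lesion_mask(arr, A)
}

rasterize_region <- function(region, config) {
  generate_lesion(region$center_mm, region$radii_mm, config)
}

clamp01_10 <- function(x) {
  y <- pmin(10, pmax(0, x))
  if (!is.null(dim(x))) dim(y) <- dim(x)   # pmax drops dim for scalar args
  y
}

# back-generate instrument subscores so that harmonize() reproduces the
# latent shared-space metrics exactly
backfill_subscores <- function(df) {
  wab <- df$instrument == "WAB"
  df$wab_fluency <- ifelse(wab, df$.self, NA_real_)
  df$wab_aq <- ifelse(wab, df$.overall * 10, NA_real_)
  df$wab_repetition <- ifelse(wab, df$.repetition, NA_real_)
  df$wab_naming <- ifelse(wab, df$.naming, NA_real_)
  df$qab_length_complexity <- ifelse(!wab, df$.self / 2.5, NA_real_)
  df$qab_speech_rate <- ifelse(!wab, df$.self / 2.5, NA_real_)
  df$qab_comm_impairment <- ifelse(!wab, df$.self / 2.5, NA_real_)
  df$qab_overall <- ifelse(!wab, df$.overall, NA_real_)
  df$qab_repetition <- ifelse(!wab, df$.repetition, NA_real_)
  df$qab_naming <- ifelse(!wab, df$.naming, NA_real_)
  df
}

ETIOLOGY_LEVELS <- c("low_grade_glioma", "high_grade_glioma", "epilepsy",
                     "vascular_malformation", "metastasis", "necrosis")
ETIOLOGY_PROBS <- c(103, 145, 34, 14, 9, 2) / 307

#' Generate a synthetic lesion-behavior cohort with planted ground truth
#'
#' Lesions are random axis-aligned ellipsoids; the latent self-generated
#' speech score is
#' `10 - effect_beta * coverage - overall_beta * volume / reference_volume`
#' plus Gaussian noise, clamped to 0-10, where coverage is the lesioned
#' fraction of the planted critical region. The overall severity score
#' carries only the volume term; repetition and naming track overall with
#' their own noise. The AOS flag is set iff the lesion touches `aos_region`.
#' Raw WAB/QAB subscores are back-generated so harmonization reproduces the
#' (noisy) latent metrics exactly.
#'
#' @param config [sim_config].
#' @return list with `masks` (list of [lesion_mask]), `behavior`
#'   (data.frame in the package's behavior schema), and `truth` (list:
#'   `critical_mask`, `aos_mask`, `coverage`, `latent` noiseless scores).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  set.seed(config$seed)
  critical <- rasterize_region(config$critical_region, config)
  n_crit <- sum(critical$data)
  aos_mask <- if (!is.null(config$aos_region))
    rasterize_region(config$aos_region, config) else NULL
  half <- (config$grid_shape - 1) / 2 * config$voxel_size_mm
  vvol <- config$voxel_size_mm^3 / 1000

  masks <- vector("list", n)
  coverage <- volume <- numeric(n)
  aos <- logical(n)
  for (i in seq_len(n)) {
    center <- runif(3, -half * config$center_margin, half * config$center_margin)
    radii <- rlnorm(3, config$lesion_radius_meanlog, config$lesion_radius_sdlog)
    m <- generate_lesion(center, radii, config)
    masks[[i]] <- m
    coverage[i] <- sum(m$data * critical$data) / n_crit
    volume[i] <- sum(m$data) * vvol
    aos[i] <- !is.null(aos_mask) && sum(m$data * aos_mask$data) > 0
  }

  overall_term <- config$overall_beta * volume / config$reference_volume_cm3
  latent_self <- clamp01_10(10 - config$effect_beta * coverage - overall_term)
  latent_overall <- clamp01_10(10 - overall_term)

  noise <- matrix(rnorm(4 * n, sd = config$noise_sd), n, 4)
  s_self <- clamp01_10(10 - config$effect_beta * coverage - overall_term + noise[, 1])
  s_overall <- clamp01_10(10 - overall_term + noise[, 2])
  s_rep <- clamp01_10(10 - overall_term + noise[, 3])
  s_nam <- clamp01_10(10 - overall_term + noise[, 4])

  instrument <- ifelse(runif(n) < config$qab_fraction, "QAB", "WAB")
  behavior <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    instrument = instrument,
    aos = as.integer(aos),
    days_post_surgery = sample(1:5, n, replace = TRUE),
    etiology = sample(ETIOLOGY_LEVELS, n, replace = TRUE, prob = ETIOLOGY_PROBS),
    age = round(pmin(87, pmax(18, rnorm(n, 46.21, 16.21)))),
    lesion_cm3 = volume,
    .self = s_self, .overall = s_overall,
    .repetition = s_rep, .naming = s_nam,
    stringsAsFactors = FALSE
  )
  behavior <- backfill_subscores(behavior)
  behavior <- behavior[, setdiff(names(behavior),
                                 c(".self", ".overall", ".repetition", ".naming"))]

  truth <- list(critical_mask = critical, aos_mask = aos_mask,
                coverage = coverage,
                latent = data.frame(self_generated = latent_self,
                                    overall = latent_overall))
  list(masks = masks, behavior = behavior, truth = truth, config = config)
}

#' Generate paired WAB+QAB assessments from one latent profile
#'
#' Emulates a validation sample in which both batteries are administered to
#' the same individuals: each subject has one latent 0-10 profile; each
#' instrument observes it with its own additive noise, and raw subscores are
#' back-generated. With `instrument_noise_sd = 0` the harmonized metrics of
#' the two instruments are identical (r = 1).
#'
#' @param n subjects (>= 3).
#' @param latent_sd SD of the latent profile around its center (score pts).
#' @param seed RNG seed.
#' @param instrument_noise_sd per-instrument observation noise SD.
#' @param latent_mean center of the latent profile (default 7, a mildly
#'   impaired post-stroke sample).
#' @return data.frame with one WAB row and one QAB row per subject
#'   (columns: subject_id, instrument, subscores, aos, days_post_surgery).
#' @export
generate_paired_assessments <- function(n, latent_sd = 1.5, seed = 1L,
                                        instrument_noise_sd = 0.5,
                                        latent_mean = 7) {
  if (n < 3L) stop("n must be at least 3")
  set.seed(seed)
  latent <- matrix(clamp01_10(rnorm(4 * n, latent_mean, latent_sd)), n, 4)
  colnames(latent) <- c("self", "overall", "repetition", "naming")
  one <- function(instr) {
    obs <- clamp01_10(latent + matrix(rnorm(4 * n, sd = instrument_noise_sd), n, 4))
    df <- data.frame(subject_id = sprintf("sub-%03d", seq_len(n)),
                     instrument = instr,
                     aos = 0L, days_post_surgery = 3L,
                     .self = obs[, 1], .overall = obs[, 2],
                     .repetition = obs[, 3], .naming = obs[, 4],
                     stringsAsFactors = FALSE)
    df <- backfill_subscores(df)
    df[, setdiff(names(df), c(".self", ".overall", ".repetition", ".naming"))]
  }
  rbind(one("WAB"), one("QAB"))
}

#' Write a synthetic cohort to disk
#'
#' One NIfTI mask per subject plus the ground-truth critical-region mask,
#' the behavior table as CSV, and a JSON sidecar echoing the configuration.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param gz write `.nii.gz` (default) or plain `.nii`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, gz = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gz) ".nii.gz" else ".nii"
  for (i in seq_along(cohort$masks))
    write_mask(cohort$masks[[i]],
               file.path(dir, paste0(cohort$behavior$subject_id[i], ext)))
  write_mask(cohort$truth$critical_mask, file.path(dir, paste0("truth_critical", ext)))
  utils::write.csv(cohort$behavior, file.path(dir, "behavior.csv"), row.names = FALSE)
  cfg <- cohort$config
  cfg$critical_region <- unclass(cfg$critical_region)
  if (!is.null(cfg$aos_region)) cfg$aos_region <- unclass(cfg$aos_region)
  jsonlite::write_json(unclass(cfg), file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
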