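#' Pipeline configuration
#'
#' A single declarative object driving [run_pipeline()]; serializes to and
#' from JSON losslessly via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param masks_dir directory of per-subject NIfTI masks (used when
#'   `sim` is NULL).
#' @param behavior_csv behavior table CSV (schema of [generate_cohort()]).
#' @param out_dir output directory.
#' @param design [design_spec()] for the univariate stage.
#' @param mlsm [mlsm_spec()] for the multivariate stage.
#' @param sim optional [sim_config()]; when present the cohort is simulated
#'   instead of read from disk.
#' @param seed master seed; stage seeds default to it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(masks_dir = NULL, behavior_csv = NULL,
                            out_dir = "lesionmap_out",
                            design = design_spec(), mlsm = mlsm_spec(),
                            sim = NULL, seed = 1L) {
  structure(list(masks_dir = masks_dir, behavior_csv = behavior_csv,
                 out_dir = out_dir, design = design, mlsm = mlsm,
                 sim = sim, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_to_list <- function(cfg) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  strip(cfg)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- NULL
  if (!is.null(raw$sim)) {
    s <- raw$sim
    sim <- sim_config(grid_shape = s$grid_shape, voxel_size_mm = s$voxel_size_mm,
                      n_subjects = s$n_subjects,
                      critical_region = ellipsoid_spec(s$critical_region$center_mm,
                                                       s$critical_region$radii_mm),
                      effect_beta = s$effect_beta, overall_beta = s$overall_beta,
                      aos_region = if (is.null(s$aos_region)) NULL else
                        ellipsoid_spec(s$aos_region$center_mm, s$aos_region$radii_mm),
                      noise_sd = s$noise_sd, qab_fraction = s$qab_fraction,
                      reference_volume_cm3 = s$reference_volume_cm3,
                      lesion_radius_meanlog = s$lesion_radius_meanlog,
                      lesion_radius_sdlog = s$lesion_radius_sdlog,
                      center_margin = s$center_margin, seed = s$seed)
  }
  d <- raw$design
  m <- raw$mlsm
  pipeline_config(
    masks_dir = raw$masks_dir, behavior_csv = raw$behavior_csv,
    out_dir = raw$out_dir,
    design = design_spec(outcome = d$outcome, covariates = d$covariates,
                         min_lesioned = d$min_lesioned, min_intact = d$min_intact,
                         n_permutations = d$n_permutations, alpha = d$alpha,
                         tail = d$tail,
                         cluster_forming_alpha = d$cluster_forming_alpha,
                         seed = d$seed),
    mlsm = mlsm_spec(kernel = m$kernel, C = m$C, epsilon = m$epsilon,
                     gamma = m$gamma, n_permutations = m$n_permutations,
                     min_lesioned = m$min_lesioned, min_intact = m$min_intact,
                     alpha = m$alpha, outcome = m$outcome,
                     covariates = m$covariates, seed = m$seed),
    sim = sim, seed = raw$seed)
}

read_cohort_dir <- function(masks_dir, behavior_csv) {
  behavior <- utils::read.csv(behavior_csv, stringsAsFactors = FALSE)
  need <- c("subject_id", "instrument", "aos", "days_post_surgery", "lesion_cm3")
  miss <- setdiff(need, names(behavior))
  if (length(miss))
    stop("behavior CSV lacks required column(s): ", paste(miss, collapse = ", "))
  paths <- file.path(masks_dir, paste0(behavior$subject_id, ".nii.gz"))
  alt <- file.path(masks_dir, paste0(behavior$subject_id, ".nii"))
  paths[!file.exists(paths)] <- alt[!file.exists(paths)]
  if (any(!file.exists(paths)))
    stop("missing mask file(s) for: ",
         paste(behavior$subject_id[!file.exists(paths)], collapse = ", "))
  masks <- vector("list", length(paths))
  ref <- NULL
  for (i in seq_along(paths)) {
    masks[[i]] <- read_mask(paths[i], reference_affine = ref)
    if (i == 1L) ref <- masks[[1]]$affine
  }
  list(masks = masks, behavior = behavior)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_pipeline_config(config, tmp)
  unname(tools::md5sum(tmp))
}

log_stage <- function(logcon, stage, t0) {
  msg <- sprintf("[%s] stage %-12s %.2fs", format(Sys.time(), "%H:%M:%S"),
                 stage, as.numeric(proc.time()[3] - t0))
  message(msg)
  if (!is.null(logcon)) writeLines(msg, logcon)
}

#' Run the end-to-end lesion-symptom mapping pipeline
#'
#' Sequences harmonization, univariate VLSM, multivariate SVR-LSM, cluster
#' intersection into the LSM-ROI, the 1.5-SD classifications, and the
#' contingency / relative-risk statistics. All imaging artifacts (t map,
#' FWER p map, weight map, cluster and ROI masks) are written as NIfTI, the
#' per-subject flags as CSV, and a deterministic JSON report (with seed,
#' package version and config hash as provenance) is returned and written.
#'
#' @param config [pipeline_config()].
#' @return the report, invisibly (a nested list mirroring `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(out, "pipeline.log"), "w")
  on.exit(close(logcon))
  t0 <- proc.time()[3]

  stage <- function(name, expr) {
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline aborted at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE))
    log_stage(logcon, name, t0)
    r
  }

  cohort <- stage("load", {
    if (!is.null(config$sim)) generate_cohort(config$sim)
    else read_cohort_dir(config$masks_dir, config$behavior_csv)
  })
  n <- nrow(cohort$behavior)
  if (n < config$design$min_lesioned + 2L)
    stop("pipeline aborted at stage 'load': cohort smaller than min_lesioned + 2")

  behavior <- stage("harmonize", harmonize(cohort$behavior))
  L <- lesion_matrix(cohort$masks)
  v <- stage("vlsm", vlsm(L, behavior, config$design))
  m <- stage("mlsm", mlsm(L, behavior, config$mlsm))
  roi <- stage("intersect", {
    suppressWarnings(intersect_rois(v$significant_mask, m$significant_mask))
  })
  cls <- stage("classify", {
    r <- classify_roi_resection(cohort$masks, roi)
    d <- classify_deficit(behavior)
    list(roi = r, deficit = d)
  })
  eff <- stage("effects", {
    tab <- contingency(cls$roi$flag, cls$deficit$flag)
    zero <- tab$a == 0 || tab$c == 0 || tab$b == 0 || tab$d == 0
    list(table = tab, corrected = zero,
         rr = relative_risk(tab, correction = zero),
         or = odds_ratio(tab, correction = zero))
  })

  gdim <- dim(v$statmap$t); aff <- v$statmap$affine
  write_nifti(v$statmap$t, aff, file.path(out, "vlsm_t.nii.gz"))
  write_nifti(v$perm$fwer_p, aff, file.path(out, "vlsm_fwer_p.nii.gz"))
  write_mask(v$significant_mask, file.path(out, "vlsm_cluster.nii.gz"))
  write_nifti(m$weight_map, aff, file.path(out, "mlsm_w.nii.gz"))
  write_nifti(m$p_map, aff, file.path(out, "mlsm_p.nii.gz"))
  write_mask(m$significant_mask, file.path(out, "mlsm_cluster.nii.gz"))
  write_mask(roi, file.path(out, "lsm_roi.nii.gz"))
  utils::write.csv(
    data.frame(subject_id = behavior$subject_id,
               roi_dsc = cls$roi$dsc, roi_flag = cls$roi$flag,
               deficit_difference = cls$deficit$difference,
               deficit_flag = cls$deficit$flag),
    file.path(out, "subject_flags.csv"), row.names = FALSE)

  cluster_summary <- function(cl_list, p = NULL) lapply(seq_along(cl_list), function(i)
    list(n_voxels = cl_list[[i]]$n_voxels,
         volume_cm3 = cl_list[[i]]$volume_cm3,
         center_of_mass_mm = as.numeric(cl_list[[i]]$center_of_mass_mm),
         peak = cl_list[[i]]$peak,
         extent_p = if (is.null(p)) NULL else p[i]))
  report <- list(
    provenance = list(package_version = as.character(utils::packageVersion("lesionmap")),
                      seed = config$seed, config_hash = config_hash(config),
                      n_subjects = n),
    vlsm = list(n_significant_voxels = sum(v$significant_mask$data),
                critical_value = v$perm$critical_value,
                n_permutations = v$perm$n_permutations,
                exhaustive = v$perm$exhaustive,
                clusters = cluster_summary(v$clusters, v$cluster_extent_p)),
    mlsm = list(n_significant_voxels = sum(m$significant_mask$data),
                n_permutations = m$n_permutations,
                clusters = cluster_summary(m$clusters)),
    lsm_roi = list(n_voxels = sum(roi$data),
                   volume_cm3 = mask_volume_cm3(roi),
                   dice_vlsm_mlsm = suppressWarnings(
                     dice(v$significant_mask, m$significant_mask))),
    classification = list(n_roi_resection = sum(cls$roi$flag),
                          n_deficit = sum(cls$deficit$flag),
                          roi_threshold = cls$roi$threshold,
                          deficit_threshold = cls$deficit$threshold),
    effects = list(table = list(a = eff$table$a, b = eff$table$b,
                                c = eff$table$c, d = eff$table$d),
                   continuity_corrected = eff$corrected,
                   relative_risk = unclass(eff$rr),
                   odds_ratio = unclass(eff$or))
  )
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(report)
}
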