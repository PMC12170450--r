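Package: lesionmap
Title: Lesion-Symptom Mapping of Self-Generated Speech Deficits
Version: 0.1.0
Authors@R: person("LSM", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for voxel-based and multivariate
    lesion-symptom mapping of post-neurosurgical language deficits.
    Harmonizes Western Aphasia Battery and Quick Aphasia Battery subscores
    into shared 0-10 metrics, fits mass-univariate general linear models at
    every voxel with permutation-based familywise-error correction, fits a
    support-vector-regression lesion-symptom map with nuisance
    residualization and direct total lesion volume control, intersects the
    resulting clusters into a region of interest, and runs the follow-up
    cohort statistics (1.5-SD classification rules, relative risk and odds
    ratio with confidence intervals, chi-square and rank-sum tests, percent
    regional damage). Includes a synthetic-cohort generator with planted
    ground truth for parameter-recovery benchmarking, and a minimal NIfTI-1
    reader/writer for binary lesion masks and statistic maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
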