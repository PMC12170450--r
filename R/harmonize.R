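#' Harmonize WAB/QAB subscores into shared 0-10 metrics
#'
#' Maps instrument-specific subscores onto four shared-space metrics, each
#' on 0-10 with 0 most impaired:
#' \describe{
#'   \item{self_generated}{WAB: spontaneous-speech Fluency rating (0-10,
#'     used as-is). QAB: mean of the Reduced Length and Complexity, Reduced
#'     Speech Rate, and Overall Communication Impairment connected-speech
#'     ratings (each 0-4), rescaled by 2.5 to 0-10.}
#'   \item{overall}{WAB: Aphasia Quotient / 10. QAB: Overall score as-is.}
#'   \item{repetition}{WAB Repetition / QAB Repetition summary, both 0-10.}
#'   \item{naming}{WAB Object Naming / QAB Picture Naming, both expected
#'     pre-scaled to 0-10 upstream (raw maxima differ across battery
#'     versions, so normalization happens before this table).}
#' }
#'
#' @param behavior data.frame with columns `instrument` ("WAB"/"QAB"), the
#'   instrument's subscore columns (`wab_fluency`, `wab_aq`,
#'   `wab_repetition`, `wab_naming`; `qab_length_complexity`,
#'   `qab_speech_rate`, `qab_comm_impairment`, `qab_overall`,
#'   `qab_repetition`, `qab_naming`) and `aos` (0/1).
#' @return the input data.frame with columns `self_generated`, `overall`,
#'   `repetition`, `naming` appended.
#' @export
harmonize <- function(behavior) {
  stopifnot(is.data.frame(behavior))
  if (!"instrument" %in% names(behavior)) stop("missing column: instrument")
  instr <- behavior$instrument
  if (!all(instr %in% c("WAB", "QAB")))
    stop("instrument must be 'WAB' or 'QAB'")
  check_range <- function(col, lo, hi, rows) {
    v <- behavior[[col]][rows]
    if (any(is.na(v)))
      stop(sprintf("missing %s for a %s row", col,
                   if (grepl("^wab", col)) "WAB" else "QAB"))
    bad <- which(v < lo | v > hi)
    if (length(bad))
      stop(sprintf("%s out of range: %g not in [%g, %g]", col, v[bad[1]], lo, hi))
    v
  }
  n <- nrow(behavior)
  self <- overall <- rep_ <- nam <- rep(NA_real_, n)
  wab <- which(instr == "WAB")
  if (length(wab)) {
    self[wab] <- check_range("wab_fluency", 0, 10, wab)
    overall[wab] <- check_range("wab_aq", 0, 100, wab) / 10
    rep_[wab] <- check_range("wab_repetition", 0, 10, wab)
    nam[wab] <- check_range("wab_naming", 0, 10, wab)
  }
  qab <- which(instr == "QAB")
  if (length(qab)) {
    a <- check_range("qab_length_complexity", 0, 4, qab)
    b <- check_range("qab_speech_rate", 0, 4, qab)
    c_ <- check_range("qab_comm_impairment", 0, 4, qab)
    self[qab] <- (a + b + c_) / 3 * 2.5
    overall[qab] <- check_range("qab_overall", 0, 10, qab)
    rep_[qab] <- check_range("qab_repetition", 0, 10, qab)
    nam[qab] <- check_range("qab_naming", 0, 10, qab)
  }
  behavior$self_generated <- self
  behavior$overall <- overall
  behavior$repetition <- rep_
  behavior$naming <- nam
  behavior
}

#' Cross-instrument validation of the harmonization
#'
#' Given a paired table (each subject assessed with both instruments, as
#' produced by [generate_paired_assessments()]), harmonizes each
#' instrument's rows and returns the Pearson correlation between the
#' WAB-derived and QAB-derived versions of each shared metric.
#'
#' @param paired data.frame with both a WAB row and a QAB row per
#'   `subject_id`.
#' @return named numeric vector of correlations for `self_generated`,
#'   `overall`, `repetition`, `naming`.
#' @export
validate_harmonization <- function(paired) {
  h <- harmonize(paired)
  wab <- h[h$instrument == "WAB", ]
  qab <- h[h$instrument == "QAB", ]
  wab <- wab[order(wab$subject_id), ]
  qab <- qab[order(qab$subject_id), ]
  if (!identical(wab$subject_id, qab$subject_id))
    stop("paired table must contain one WAB and one QAB row per subject")
  if (nrow(wab) < 3L) stop("at least 3 paired rows are required")
  metrics <- c("self_generated", "overall", "repetition", "naming")
  vapply(metrics, function(m) {
    x <- wab[[m]]; y <- qab[[m]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop(sprintf("correlation undefined for %s: zero variance", m))
    stats::cor(x, y)
  }, numeric(1))
}
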