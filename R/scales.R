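#' Default MBI-GS item-to-subscale map
#'
#' Items 1-5 form emotional exhaustion, 6-9 depersonalization and 10-15
#' reduced professional efficacy.
#'
#' @return named list of integer index vectors.
#' @export
mbi_item_map <- function() {
  list(emotional_exhaustion = 1:5,
       depersonalization = 6:9,
       reduced_professional_efficacy = 10:15)
}

#' Default SDS reverse-keyed items
#'
#' The ten positively worded items, recoded `5 - x` before summing.
#'
#' @return integer vector of item indices.
#' @export
sds_reverse_items <- function() c(2L, 5L, 6L, 11L, 12L, 14L, 16L, 17L, 18L, 20L)

mbi_severity <- function(score, mild_below, severe_above) {
  cut(score, breaks = c(-Inf, mild_below - 0.5, severe_above + 0.5, Inf),
      labels = c("mild", "moderate", "severe"))
}

#' Score the Maslach Burnout Inventory - General Survey
#'
#' Sums the three subscales and classifies each against the conventional
#' cutoffs: emotional exhaustion >15 severe, 11-15 moderate, <11 mild;
#' depersonalization >12 severe, 8-12 moderate, <8 mild; reduced
#' professional efficacy >22 severe, 18-22 moderate, <18 mild.
#'
#' @param responses numeric vector of 15 responses in 0-6, or a matrix with
#'   15 columns (one row per respondent).
#' @param item_map list mapping subscale names to item indices
#'   (default [mbi_item_map()]).
#' @return data.frame with one row per respondent: the three subscale scores
#'   and their severity levels.
#' @export
score_mbi <- function(responses, item_map = mbi_item_map()) {
  x <- if (is.matrix(responses)) responses else matrix(responses, nrow = 1)
  if (ncol(x) != 15) stop("expected 15 MBI-GS items, got ", ncol(x))
  bad <- which(x < 0 | x > 6, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("MBI response out of range 0-6 at item ", bad[1, 2],
         " (respondent ", bad[1, 1], ")")
  }
  ee <- rowSums(x[, item_map$emotional_exhaustion, drop = FALSE])
  dp <- rowSums(x[, item_map$depersonalization, drop = FALSE])
  rpe <- rowSums(x[, item_map$reduced_professional_efficacy, drop = FALSE])
  data.frame(
    emotional_exhaustion = ee,
    ee_severity = mbi_severity(ee, 11, 15),
    depersonalization = dp,
    dp_severity = mbi_severity(dp, 8, 12),
    reduced_professional_efficacy = rpe,
    rpe_severity = mbi_severity(rpe, 18, 22)
  )
}

#' Convert an SDS raw score to the standard score
#'
#' `standard = floor(raw * 1.25)`, the unique simple rule reproducing all the
#' published raw/standard anchor pairs (20/25, 40/50, 48/60, 56/70).
#'
#' @param raw integer raw score(s) in 20-80.
#' @return integer standard score(s).
#' @export
sds_standard_score <- function(raw) {
  if (any(raw < 20 | raw > 80)) stop("SDS raw score must lie in 20-80")
  as.integer(floor(raw * 1.25))
}

sds_severity <- function(standard) {
  cut(standard, breaks = c(-Inf, 49.5, 59.5, 69.5, Inf),
      labels = c("normal", "mild_to_moderate", "moderate_to_severe", "severe"))
}

#' Score the Zung Self-Rating Depression Scale
#'
#' Reverse-keyed items are recoded `5 - x`, all 20 items summed to the raw
#' score (20-80), converted to the standard score via
#' [sds_standard_score()], and banded: 25-49 normal, 50-59 mild to moderate,
#' 60-69 moderate to severe, 70+ severe.
#'
#' @param responses numeric vector of 20 responses in 1-4, or a matrix with
#'   20 columns.
#' @param reverse_keyed indices of the 10 reverse-keyed items
#'   (default [sds_reverse_items()]).
#' @return data.frame with columns `raw`, `standard`, `severity`.
#' @export
score_sds <- function(responses, reverse_keyed = sds_reverse_items()) {
  x <- if (is.matrix(responses)) responses else matrix(responses, nrow = 1)
  if (ncol(x) != 20) stop("expected 20 SDS items, got ", ncol(x))
  if (length(reverse_keyed) != 10) {
    stop("SDS requires exactly 10 reverse-keyed items, got ", length(reverse_keyed))
  }
  bad <- which(x < 1 | x > 4, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("SDS response out of range 1-4 at item ", bad[1, 2],
         " (respondent ", bad[1, 1], ")")
  }
  x[, reverse_keyed] <- 5 - x[, reverse_keyed]
  raw <- as.integer(rowSums(x))
  standard <- sds_standard_score(raw)
  data.frame(raw = raw, standard = standard, severity = sds_severity(standard))
}

#' Cohort summary of burnout and depression indicators
#'
#' Counts and percentages of respondents above the reporting thresholds used
#' in descriptive tables for this instrument pair: emotional exhaustion >10,
#' depersonalization >7, reduced professional efficacy >17, and SDS standard
#' score >62 (clinically relevant) and >52 (prevalence). Percentages are
#' rounded to two decimals.
#'
#' @param mbi data.frame from [score_mbi()].
#' @param sds data.frame from [score_sds()].
#' @return data.frame with columns `indicator`, `threshold`, `count`,
#'   `percent`.
#' @export
cohort_summary <- function(mbi, sds) {
  stopifnot(nrow(mbi) > 0, nrow(mbi) == nrow(sds))
  n <- nrow(mbi)
  counts <- c(
    emotional_exhaustion = sum(mbi$emotional_exhaustion > 10),
    depersonalization = sum(mbi$depersonalization > 7),
    reduced_professional_efficacy = sum(mbi$reduced_professional_efficacy > 17),
    depression_clinically_relevant = sum(sds$standard > 62),
    depression_prevalence = sum(sds$standard > 52)
  )
  data.frame(
    indicator = names(counts),
    threshold = c(10, 7, 17, 62, 52),
    count = as.integer(counts),
    percent = round(100 * counts / n, 2),
    row.names = NULL
  )
}

#' Cronbach's alpha
#'
#' Classical internal-consistency coefficient
#' `alpha = k/(k-1) * (1 - sum(var_items)/var_total)`; provided for checking
#' synthetic cohorts (raw study data are needed to reproduce published
#' reliabilities).
#'
#' @param x numeric matrix, respondents by items.
#' @return scalar alpha.
#' @export
cronbach_alpha <- function(x) {
  k <- ncol(x)
  if (k < 2) stop("alpha needs at least 2 items")
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / stats::var(rowSums(x)))
}
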