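# The stromal inflammation (SI) score and PD-L1 scoring rules.

#' Raw computational SI score of a segmented image
#'
#' The stromal inflammation score is the proportion of stromal (desmoplastic)
#' area occupied by chronic inflammatory cells: the summed area of
#' inflammatory-cell objects lying within the stromal compartment divided by
#' the stromal compartment area. Inflammatory-like objects inside epithelial
#' nests (intraepithelial lymphocytes) are excluded — only peri-tumoral
#' stromal inflammation counts.
#'
#' @param seg A `segmentation_result` from [segment_tma()].
#' @return Raw SI fraction in `[0, 1]`, or NA (with a warning) when the
#'   image has no stromal area.
#' @export
compute_si_raw <- function(seg) {
  stopifnot(inherits(seg, "segmentation_result"))
  stromal_px <- sum(seg$compartments == 2L)
  if (stromal_px == 0L) {
    warning("no stromal area in this image; SI is NA")
    return(NA_real_)
  }
  obj <- seg$cells$objects
  inf_ids <- obj$id[obj$class == "inflammatory_cell"]
  if (length(inf_ids) == 0L) return(0)
  inflam <- seg$cells$labels %in% inf_ids & seg$compartments == 2L
  sum(inflam) / stromal_px
}

#' Quantize a raw SI fraction to the recording grid
#'
#' Human SI scores run from 0.00 to 1.00 in increments of 0.10, with values
#' estimated to lie between two increments recorded as the middle value
#' (e.g. between 0.30 and 0.40 becomes 0.35). The machine analog maps a raw
#' fraction to the nearest point of the 0.05 grid; exact midpoints between
#' grid points round up.
#'
#' @param raw Numeric vector of raw fractions in `[0, 1]` (NA passes through).
#' @return Vector of recorded scores on the grid `{0.00, 0.05, ..., 1.00}`.
#' @examples
#' quantize_si(0.34)   # 0.35
#' quantize_si(0.30)   # 0.30
#' @export
quantize_si <- function(raw) {
  if (any(!is.na(raw) & (raw < 0 | raw > 1)))
    stop("raw SI values must lie in [0, 1]", call. = FALSE)
  out <- floor(raw * 20 + 0.5 + 1e-9) / 20
  out[is.na(raw)] <- NA_real_
  out
}

#' Case-level SI score from two recorded core scores
#'
#' The case score is the mean of the two core scores; if only one core was
#' scored the available one is used; if neither was scored the case is NA.
#'
#' @param core1,core2 Recorded core SI scores (numeric vectors, NA allowed).
#' @return Case-level SI vector.
#' @export
case_si <- function(core1, core2) pairwise_mean(core1, core2)

#' Delta-value: intratumoral SI heterogeneity between cores
#'
#' The absolute difference between the SI scores of the first and second
#' core of a case; NA when either core is missing.
#'
#' @param core1,core2 Recorded core SI scores.
#' @return Non-negative numeric vector.
#' @export
delta_value <- function(core1, core2) abs(core1 - core2)

#' Median split of delta-values into heterogeneity subgroups
#'
#' Cases with delta-value strictly greater than the cohort median form the
#' `"high"` (heterogeneous) subgroup, cases at or below it the `"low"`
#' subgroup — ties go to `"low"`.
#'
#' @param deltas Numeric delta-values (NA allowed).
#' @return Factor with levels `c("low", "high")`, NA where delta is NA.
#' @export
split_by_median <- function(deltas) {
  ok <- !is.na(deltas)
  if (sum(ok) < 2L) stop("need at least 2 non-NA delta-values", call. = FALSE)
  med <- stats::median(deltas[ok])
  if (all(deltas[ok] == deltas[ok][1L]))
    warning("all delta-values are identical; the median split is degenerate")
  factor(ifelse(deltas > med, "high", "low"), levels = c("low", "high"))
}

#' PD-L1 proportion score of one core
#'
#' The proportion of viable tumor cells with circumferential PD-L1 staining
#' of any intensity. A core needs at least `min_cells` viable tumor cells to
#' be scorable; otherwise its score is NA.
#'
#' @param viable Logical vector, one entry per tumor cell: is the cell viable?
#' @param stained Logical vector: does the cell show circumferential staining?
#' @param min_cells Minimum number of viable cells (default 100).
#' @return Proportion in `[0, 1]`, or NA.
#' @export
pdl1_core_score <- function(viable, stained, min_cells = 100L) {
  stopifnot(length(viable) == length(stained))
  n_viable <- sum(viable)
  if (n_viable < min_cells) return(NA_real_)
  sum(stained & viable) / n_viable
}

#' Case-level PD-L1 score from two core scores
#'
#' Mean of the scored cores; single-core fallback; NA when neither core was
#' scorable.
#'
#' @param core1,core2 Core PD-L1 proportions (NA allowed).
#' @return Case-level PD-L1 proportion vector.
#' @export
pdl1_case_score <- function(core1, core2) pairwise_mean(core1, core2)

#' PD-L1 expression stratum
#'
#' `"high"` when the proportion of PD-L1-positive tumor cells exceeds 0.00,
#' `"low"` when it equals 0.00.
#'
#' @param score PD-L1 proportion vector.
#' @return Factor with levels `c("low", "high")`.
#' @export
pdl1_stratum <- function(score) {
  factor(ifelse(score > 0, "high", "low"), levels = c("low", "high"))
}

#' Concordance between two score series
#'
#' Spearman rank correlation between two sets of scores of the same cases
#' (e.g. two observers, or the same observer on different days).
#'
#' @param scores_a,scores_b Numeric vectors (NA allowed).
#' @return Spearman rho, or NA (with a warning) if fewer than 3 complete
#'   pairs or a constant vector.
#' @export
concordance <- function(scores_a, scores_b) {
  spearman_or_na(scores_a, scores_b, min_pairs = 3L)
}

#' Score a cohort of segmented cores
#'
#' Computes per-core raw and recorded SI, the case SI, and the delta-value
#' for a set of cases given their two segmentations.
#'
#' @param seg1,seg2 Lists of `segmentation_result` objects (core 1 and 2 per
#'   case, same order).
#' @param case_ids Optional case identifiers.
#' @return data.frame: `case_id`, `si_core1_raw`, `si_core2_raw`,
#'   `si_core1`, `si_core2`, `si_case`, `delta`.
#' @export
score_cohort <- function(seg1, seg2, case_ids = NULL) {
  stopifnot(length(seg1) == length(seg2))
  n <- length(seg1)
  if (is.null(case_ids)) case_ids <- sprintf("case_%04d", seq_len(n))
  raw1 <- vapply(seg1, compute_si_raw, numeric(1))
  raw2 <- vapply(seg2, compute_si_raw, numeric(1))
  rec1 <- quantize_si(raw1)
  rec2 <- quantize_si(raw2)
  data.frame(case_id = case_ids,
             si_core1_raw = raw1, si_core2_raw = raw2,
             si_core1 = rec1, si_core2 = rec2,
             si_case = case_si(rec1, rec2),
             delta = delta_value(rec1, rec2),
             stringsAsFactors = FALSE)
}
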