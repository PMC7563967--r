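#' @include AllClasses.R
NULL

CT_MAX <- 40

checkCt <- function(ct, what = "Ct") {
  if (any(is.na(ct))) stop(what, " contains NA")
  if (any(ct < 0 | ct > CT_MAX))
    stop(what, " values must lie in [0, ", CT_MAX, "]")
  invisible(ct)
}

#' Relative expression by the delta-Ct method
#'
#' `2^-(Ct_target - Ct_reference)` against a housekeeping assay (RNU6A
#' for miRs; GAPDH/ACTB for mRNAs). Amplification efficiency is fixed at
#' 2, as the delta-Ct method assumes. A Ct of 40 marks a censored
#' (undetermined) reaction; when both target and reference are censored
#' the value is undefined and returned as `NA` with a warning.
#'
#' @param ctTarget,ctReference Ct values in cycles, each in \[0, 40\].
#'   Technical replicates should be averaged on the Ct scale first (see
#'   [averageTechReps()]).
#' @return numeric vector of relative expression values (> 0, or `NA`
#'   where undefined).
#' @examples
#' relativeExpression(24, 25)  # delta-Ct = -1 -> 2
#' @export
relativeExpression <- function(ctTarget, ctReference) {
  checkCt(ctTarget, "target Ct"); checkCt(ctReference, "reference Ct")
  out <- 2^(-(ctTarget - ctReference))
  both <- ctTarget == CT_MAX & ctReference == CT_MAX
  if (any(both)) {
    warning("target and reference both censored at Ct 40: value undefined")
    out[both] <- NA_real_
  }
  out
}

#' miTRAP ratio: fold enrichment of a miR in an eluate versus the input
#'
#' `2^-(Ct_eluate - Ct_input)`; the input is the baseline (set to 1).
#' Computed per bait, so the target-bait and MS2 control-bait folds can
#' be compared. A censored eluate (Ct 40) yields a below-detection fold,
#' flagged in the `"censored"` attribute.
#'
#' @param ctEluate,ctInput Ct values in cycles.
#' @return numeric fold vector with a logical `"censored"` attribute.
#' @examples
#' mitrapRatio(15.55, 25)  # ~ 2^9.45, a ~700-fold enrichment
#' @export
mitrapRatio <- function(ctEluate, ctInput) {
  checkCt(ctEluate, "eluate Ct"); checkCt(ctInput, "input Ct")
  out <- 2^(-(ctEluate - ctInput))
  attr(out, "censored") <- ctEluate == CT_MAX
  out
}

#' Average technical replicates on the Ct scale
#'
#' @param measurements `data.frame` with columns `assay_id`, `ct`, and a
#'   grouping column (`sample_id` or `condition`).
#' @param by name of the grouping column (default `"sample_id"`).
#' @return `data.frame` with one mean Ct per (group, assay).
#' @export
averageTechReps <- function(measurements, by = "sample_id") {
  if (!all(c(by, "assay_id", "ct") %in% colnames(measurements)))
    stop("measurements need columns ", by, ", assay_id, ct")
  out <- stats::aggregate(measurements$ct,
                          by = list(measurements[[by]],
                                    measurements$assay_id),
                          FUN = mean)
  colnames(out) <- c(by, "assay_id", "ct")
  out
}

#' Fold change between two conditions by the delta-delta-Ct method
#'
#' `2^-ddCt` with
#' `ddCt = (Ct_assay - Ct_ref)_condition - (Ct_assay - Ct_ref)_control`.
#' Technical replicates are averaged on the Ct scale first.
#'
#' @param measurements `data.frame` with columns `condition`, `assay_id`,
#'   `ct` (replicate rows allowed).
#' @param condition,controlCondition condition labels.
#' @param referenceAssay housekeeping assay id; must be measured in both
#'   conditions.
#' @return `data.frame` with `assay_id` and `fold` for every non-reference
#'   assay measured in both conditions.
#' @export
foldChangeDdct <- function(measurements, condition, controlCondition,
                           referenceAssay) {
  m <- averageTechReps(measurements, by = "condition")
  checkCt(m$ct)
  pick <- function(cond, assay) {
    v <- m$ct[m$condition == cond & m$assay_id == assay]
    if (length(v) != 1L) NA_real_ else v
  }
  refC <- pick(condition, referenceAssay)
  ref0 <- pick(controlCondition, referenceAssay)
  if (is.na(refC) || is.na(ref0))
    stop("reference assay '", referenceAssay,
         "' missing in one of the conditions")
  assays <- setdiff(unique(m$assay_id), referenceAssay)
  folds <- vapply(assays, function(a) {
    ctC <- pick(condition, a); ct0 <- pick(controlCondition, a)
    if (is.na(ctC) || is.na(ct0)) return(NA_real_)
    ddct <- (ctC - refC) - (ct0 - ref0)
    2^(-ddct)
  }, numeric(1))
  out <- data.frame(assay_id = assays, fold = unname(folds),
                    stringsAsFactors = FALSE)
  out[!is.na(out$fold), , drop = FALSE]
}
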