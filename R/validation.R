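#' @include AllClasses.R
NULL

#' Normalize dual-luciferase reporter readings
#'
#' Per-well relative light units are firefly/renilla (`rlu = FFL/RL`);
#' condition means are then scaled so the control condition maps to
#' exactly 1.
#'
#' @param records `data.frame` with columns `condition`, `ffl`, `rl`
#'   (one row per well).
#' @param controlLabel control condition (e.g. the mimic negative
#'   control).
#' @return `data.frame` with `condition`, `n_wells`, `mean_rlu`,
#'   `rlu_norm`.
#' @export
rluNormalize <- function(records, controlLabel) {
  need <- c("condition", "ffl", "rl")
  if (!all(need %in% colnames(records)))
    stop("records need columns ", paste(need, collapse = ", "))
  if (any(records$rl <= 0)) stop("renilla signal must be positive")
  if (!controlLabel %in% records$condition)
    stop("control condition '", controlLabel, "' not present")
  records$rlu <- records$ffl / records$rl
  agg <- stats::aggregate(rlu ~ condition, data = records, FUN = mean)
  nw <- stats::aggregate(rlu ~ condition, data = records, FUN = length)
  ctrl <- agg$rlu[agg$condition == controlLabel]
  data.frame(condition = agg$condition, n_wells = nw$rlu,
             mean_rlu = agg$rlu, rlu_norm = agg$rlu / ctrl,
             stringsAsFactors = FALSE)
}

#' Relative band density (arbitrary units)
#'
#' Western-blot densitometry: the band of interest is normalized to its
#' lane's loading control (e.g. GAPDH) and expressed relative to the
#' parental (untreated) cells.
#'
#' @param band,loading band and loading-control densities of the lane of
#'   interest (> 0).
#' @param parentalBand,parentalLoading the parental lane's densities
#'   (> 0).
#' @return relative density, A.U.
#' @export
relativeDensity <- function(band, loading, parentalBand, parentalLoading) {
  vals <- c(band, loading, parentalBand, parentalLoading)
  if (any(vals <= 0)) stop("densities must be positive")
  (band / loading) / (parentalBand / parentalLoading)
}

#' Specific CD107a degranulation and fold change versus control
#'
#' Spontaneous degranulation (effector cells alone) is subtracted from
#' the with-target percentage; a negative difference is floored at zero
#' (no meaningful negative degranulation). The x-fold change divides the
#' specific signal by the negative-control condition's specific signal.
#'
#' @param withTargetsPct percent CD107a-positive T cells co-incubated
#'   with targets.
#' @param spontaneousPct percent with effectors alone.
#' @param ncSpecificPct specific percentage of the negative-control
#'   condition; a zero value makes the fold undefined (`NA`, flagged with
#'   a warning).
#' @return list with `specific` and `x_fold`.
#' @examples
#' specificDegranulation(12, 2, 10)  # specific 10, x_fold 1
#' @export
specificDegranulation <- function(withTargetsPct, spontaneousPct,
                                  ncSpecificPct) {
  pcts <- c(withTargetsPct, spontaneousPct, ncSpecificPct)
  if (any(pcts < 0 | pcts > 100))
    stop("percentages must lie in [0, 100]")
  specific <- pmax(0, withTargetsPct - spontaneousPct)
  if (any(ncSpecificPct == 0)) {
    warning("negative-control specific degranulation is 0: fold undefined")
    xf <- ifelse(ncSpecificPct == 0, NA_real_, specific / ncSpecificPct)
  } else xf <- specific / ncSpecificPct
  list(specific = specific, x_fold = xf)
}

IHC_CATEGORIES <- c("0%", "1-10%", "11-30%", ">30%")

#' Grade tumor-cell TAP1 staining frequency
#'
#' Frequencies are graded into four categories (0%, 1-10%, 11-30%, >30%);
#' boundary values 10 and 30 belong to the lower bracket, per the printed
#' bracket notation. Groups: low (0-10%), intermediate (11-30%), high
#' (>30%).
#'
#' @param frequencyPct percent TAP1-positive tumor cells, in \[0, 100\].
#' @return `data.frame` with `frequency`, `category` (factor over the
#'   four categories), `group` (factor low/intermediate/high).
#' @examples
#' ihcCategory(c(0, 7, 35))$group  # low low high
#' @export
ihcCategory <- function(frequencyPct) {
  if (any(frequencyPct < 0 | frequencyPct > 100))
    stop("frequency must lie in [0, 100]")
  cat <- cut(frequencyPct, breaks = c(-Inf, 0, 10, 30, 100),
             labels = IHC_CATEGORIES)
  grp <- factor(c("low", "low", "intermediate",
                  "high")[as.integer(cat)],
                levels = c("low", "intermediate", "high"))
  data.frame(frequency = frequencyPct, category = cat, group = grp)
}

#' Two-group comparison by t-test
#'
#' Two-sided t-test; the unpaired default is Welch's unequal-variance
#' variant (pooled variance available via `varEqual`). A Wilcoxon test is
#' offered as a nonparametric alternative.
#'
#' @param valuesA,valuesB numeric vectors, at least 2 values each; equal
#'   lengths required when `paired`.
#' @param paired paired test (default unpaired).
#' @param varEqual pooled-variance t-test instead of Welch (unpaired
#'   only).
#' @param method `"t"` (default) or `"wilcoxon"`.
#' @return list with `statistic`, `p_value`, `df` (`NA` for Wilcoxon),
#'   `method`.
#' @export
groupCompare <- function(valuesA, valuesB, paired = FALSE,
                         varEqual = FALSE, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  if (length(valuesA) < 2L || length(valuesB) < 2L)
    stop("need at least 2 values per group")
  if (paired && length(valuesA) != length(valuesB))
    stop("paired comparison requires equal group sizes")
  if (method == "t") {
    tt <- stats::t.test(valuesA, valuesB, paired = paired,
                        var.equal = varEqual)
    list(statistic = unname(tt$statistic), p_value = tt$p.value,
         df = unname(tt$parameter), method = tt$method)
  } else {
    wt <- stats::wilcox.test(valuesA, valuesB, paired = paired,
                             exact = FALSE)
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         df = NA_real_, method = wt$method)
  }
}

#' Compare miR expression between TAP1-high and TAP1-low lesions
#'
#' Patients graded intermediate (11-30%) are excluded; miR relative
#' expression (2^-dCt versus RNU6A) is compared between the TAP1-high
#' (>30%) and TAP1-low (0-10%) groups with an unpaired test, and a
#' per-patient overview pairing TAP1 score, CD8+ infiltration and miR
#' expression is returned.
#'
#' @param patients `data.frame` with columns `patient_id`, `tap1_group`
#'   (or `tap1_frequency`, from which groups are derived via
#'   [ihcCategory()]), `cd8_per_hpf`, `mir_rel_expr`.
#' @param method passed to [groupCompare()].
#' @return list with `test` (the [groupCompare()] result, high vs low),
#'   `group_means`, and `overview` (one row per included patient).
#' @export
mirVsTap1Groups <- function(patients, method = "t") {
  if (!"tap1_group" %in% colnames(patients)) {
    if (!"tap1_frequency" %in% colnames(patients))
      stop("patients need tap1_group or tap1_frequency")
    patients$tap1_group <-
      as.character(ihcCategory(patients$tap1_frequency)$group)
  }
  keep <- patients$tap1_group %in% c("high", "low")
  p <- patients[keep, , drop = FALSE]
  hi <- p$mir_rel_expr[p$tap1_group == "high"]
  lo <- p$mir_rel_expr[p$tap1_group == "low"]
  if (length(hi) == 0L || length(lo) == 0L)
    stop("both TAP1-high and TAP1-low groups must be non-empty")
  test <- groupCompare(hi, lo, paired = FALSE, method = method)
  overview <- p[order(p$tap1_group, p$patient_id),
                intersect(c("patient_id", "tap1_group", "tap1_frequency",
                            "cd8_per_hpf", "mir_rel_expr"), colnames(p))]
  rownames(overview) <- NULL
  list(test = test,
       group_means = c(high = mean(hi), low = mean(lo)),
       overview = overview)
}
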