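#' @include AllClasses.R AllGenerics.R
NULL

#' Combine replicate tpm values
#'
#' Biological replicates of a bait are combined by the geometric mean of
#' (tpm + pseudocount). The geometric mean is the natural choice for
#' values that enter a downstream ratio; the pseudocount stabilizes miRs
#' absent from one replicate.
#'
#' @param tpm numeric vector of replicate tpm values, all >= 0.
#' @param pseudocount added to every value before averaging
#'   (default 0.01 tpm).
#' @return combined tpm (includes the pseudocount).
#' @examples
#' aggregateReplicates(c(100, 400), pseudocount = 0)  # 200
#' @export
aggregateReplicates <- function(tpm, pseudocount = 0.01) {
  if (length(tpm) == 0L) stop("no replicate values to combine")
  if (any(tpm < 0)) stop("tpm values must be non-negative")
  if (pseudocount == 0 && any(tpm == 0))
    stop("zero tpm with zero pseudocount: geometric mean undefined")
  exp(mean(log(tpm + pseudocount)))
}

#' Enrichment ratio of target-bait over control-bait tpm
#'
#' @param tpmTarget,tpmControl combined tpm in the target-bait and
#'   control-bait eluates.
#' @param pseudocount added to numerator and denominator; must be positive
#'   unless both tpm values are strictly positive.
#' @return `(tpmTarget + pseudocount) / (tpmControl + pseudocount)`.
#' @examples
#' enrichmentRatio(9210, 100, pseudocount = 0)  # 92.1
#' @export
enrichmentRatio <- function(tpmTarget, tpmControl, pseudocount = 0.01) {
  if (any(tpmTarget < 0) || any(tpmControl < 0))
    stop("tpm values must be non-negative")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && any(tpmTarget == 0 & tpmControl == 0))
    stop("both tpm values zero with zero pseudocount: ratio undefined")
  (tpmTarget + pseudocount) / (tpmControl + pseudocount)
}

#' @describeIn computeEnrichment Enrichment records from a
#'   `MitrapExperiment`. Replicates within each bait are combined with
#'   [aggregateReplicates()]; the ratio divides the combined target-bait
#'   tpm by the combined control-bait tpm (the pseudocount is already
#'   absorbed in the combination). A miR is `enriched` iff its ratio is
#'   strictly greater than 1; with `strict = TRUE` the ratio must
#'   additionally exceed 1 in every replicate pair.
#'
#' @param pseudocount tpm pseudocount, default 0.01.
#' @param strict logical; see below.
#' @return `data.frame` with per-replicate tpm columns, combined
#'   `tpm_target`/`tpm_control`, `tpm_input`, `ratio`, `enriched`, and
#'   `pseudo_flag` marking miRs whose control-bait tpm was zero in every
#'   replicate (ratio dominated by the pseudocount).
#' @export
setMethod("computeEnrichment", "MitrapExperiment",
          function(x, pseudocount = 0.01, strict = FALSE, ...) {
  if (!"tpm" %in% assayNames(x)) x <- countsToTpm(x)
  tpm <- assay(x, "tpm")
  cd <- colData(x)
  tcols <- which(cd$bait == "target")
  ccols <- which(cd$bait == "control")
  icols <- which(cd$bait == "input")
  if (!length(tcols) || !length(ccols))
    stop("need at least one target-bait and one control-bait library")
  tmat <- tpm[, tcols, drop = FALSE]
  cmat <- tpm[, ccols, drop = FALSE]
  comb <- function(m) apply(m, 1, aggregateReplicates,
                            pseudocount = pseudocount)
  tpmT <- comb(tmat)
  tpmC <- comb(cmat)
  ratio <- enrichmentRatio(tpmT, tpmC, pseudocount = 0)
  enriched <- ratio > 1
  if (strict) {
    nrep <- min(ncol(tmat), ncol(cmat))
    perRep <- vapply(seq_len(nrep), function(r)
      (tmat[, r] + pseudocount) / (cmat[, r] + pseudocount) > 1,
      logical(nrow(tmat)))
    enriched <- enriched & apply(matrix(perRep, nrow = nrow(tmat)), 1, all)
  }
  out <- data.frame(mir_id = rownames(tpm), stringsAsFactors = FALSE)
  for (r in seq_along(tcols))
    out[[sprintf("tpm_target_r%d", cd$replicate[tcols[r]])]] <- tmat[, r]
  for (r in seq_along(ccols))
    out[[sprintf("tpm_control_r%d", cd$replicate[ccols[r]])]] <- cmat[, r]
  out$tpm_target <- tpmT
  out$tpm_control <- tpmC
  out$tpm_input <- if (length(icols))
    rowMeans(tpm[, icols, drop = FALSE]) else NA_real_
  out$ratio <- ratio
  out$enriched <- enriched
  out$pseudo_flag <- rowSums(cmat) == 0
  rownames(out) <- NULL
  out
})

#' Enriched subset of an enrichment table
#'
#' A miR is enriched iff its target/control tpm ratio strictly exceeds 1
#' (a ratio of exactly 1 is not enrichment).
#'
#' @param records `data.frame` from [computeEnrichment()] (needs `ratio`).
#' @return the enriched rows.
#' @export
flagEnriched <- function(records) {
  if (!"ratio" %in% colnames(records)) stop("records must contain 'ratio'")
  records[records$ratio > 1, , drop = FALSE]
}

roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize the enriched miR set by prediction-vote count
#'
#' Reports how many miRs are enriched (ratio > 1), the percentage of the
#' universe they represent, and the breakdown of the enriched set by the
#' number of prediction tools voting for each miR. Percentages are rounded
#' half-up to two decimals, matching conventional reporting.
#'
#' @param records enrichment `data.frame` (needs `mir_id`, `ratio` or
#'   `enriched`).
#' @param votes named integer vector of per-miR vote counts, or a
#'   [VoteMatrix-class]; miRs absent from `votes` count as 0 votes.
#' @param nTools number of tools (breakdown rows 0..nTools; default 6).
#' @return list of class `enrichmentSummary`: `n_total`, `n_enriched`,
#'   `pct_enriched`, and `breakdown` (`data.frame` with `votes`, `n`,
#'   `pct` of the enriched set).
#' @export
summarizeEnrichment <- function(records, votes, nTools = 6L) {
  if (!"enriched" %in% colnames(records))
    records$enriched <- records$ratio > 1
  if (is(votes, "VoteMatrix")) votes <- countVotes(votes)
  nTotal <- nrow(records)
  enr <- records$mir_id[records$enriched]
  nEnr <- length(enr)
  v <- votes[enr]
  v[is.na(v)] <- 0L
  breakdown <- if (nEnr > 0) {
    counts <- vapply(0:nTools, function(k) sum(v == k), integer(1))
    data.frame(votes = 0:nTools, n = counts,
               pct = roundHalfUp(100 * counts / nEnr))
  } else data.frame(votes = integer(0), n = integer(0), pct = numeric(0))
  out <- list(
    n_total = nTotal, n_enriched = nEnr,
    pct_enriched = roundHalfUp(100 * nEnr / max(nTotal, 1L)),
    breakdown = breakdown)
  class(out) <- "enrichmentSummary"
  out
}

#' @export
print.enrichmentSummary <- function(x, ...) {
  cat(sprintf("%d of %d miRs enriched (%.2f%%)\n",
              x$n_enriched, x$n_total, x$pct_enriched))
  if (x$n_enriched > 0) {
    cat("breakdown of the enriched set by prediction votes:\n")
    print(x$breakdown, row.names = FALSE)
  }
  invisible(x)
}
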