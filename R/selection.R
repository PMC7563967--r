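#' @include AllClasses.R
NULL

CRITERIA <- c(votes = "i", tpm_target = "ii", tpm_control = "iii",
              ratio = "iv", energy = "v", mitrap = "vi")

#' Thresholds for the six-criterion candidate filter
#'
#' The six criteria, with published defaults where a number was printed
#' and package defaults where only "high" was stated:
#' (i) predicted by at least `minTools` of the prediction tools (>= 4 of
#' 6); (ii) target-bait eluate tpm strictly above `minTpmTarget` (1000);
#' (iii) control-bait eluate tpm strictly below `maxTpmControl` (100);
#' (iv) enrichment ratio strictly above `minRatio` (50); (v) binding free
#' energy strictly below `maxEnergy` (default -20.0 kcal/mol, chosen so a
#' candidate at -20.3 passes and one at -12.8 fails); (vi) target-bait
#' miTRAP fold strictly above `mitrapFactor` times the control-bait fold
#' (default factor 2).
#'
#' @param minTools,minTpmTarget,maxTpmControl,minRatio,maxEnergy,mitrapFactor
#'   see above.
#' @return list of class `selectionThresholds`.
#' @export
selectionThresholds <- function(minTools = 4L, minTpmTarget = 1000,
                                maxTpmControl = 100, minRatio = 50,
                                maxEnergy = -20.0, mitrapFactor = 2) {
  if (minRatio <= 1) stop("minRatio must be > 1")
  if (maxEnergy >= 0) stop("maxEnergy must be negative (kcal/mol)")
  if (minTools < 0) stop("minTools must be >= 0")
  if (mitrapFactor <= 0) stop("mitrapFactor must be positive")
  structure(list(minTools = as.integer(minTools),
                 minTpmTarget = minTpmTarget,
                 maxTpmControl = maxTpmControl, minRatio = minRatio,
                 maxEnergy = maxEnergy, mitrapFactor = mitrapFactor),
            class = "selectionThresholds")
}

#' Apply the candidate selection criteria
#'
#' Evaluates the six-criterion filter over every miR in the enrichment
#' records. Criteria whose inputs are missing for a miR (e.g. no energy
#' computed, no miTRAP qPCR) are marked not-applicable (`NA`) rather than
#' failed; the overall pass requires every *applicable* criterion to
#' hold. All inequalities are strict, matching the published wording
#' ("higher than", "less than"), except (i) which is "at least"
#' `minTools`. Failing miRs are retained with failure annotations; see
#' [selectionAudit()].
#'
#' @param records `data.frame` with `mir_id` and any of `tpm_target`,
#'   `tpm_control`, `ratio`.
#' @param votes named integer vote counts or a [VoteMatrix-class]
#'   (optional).
#' @param energies named numeric binding energies, kcal/mol (optional).
#' @param mitrap `data.frame` with `mir_id`, `fold_target`,
#'   `fold_control` (optional).
#' @param thresholds a [selectionThresholds()] list.
#' @param criteria subset of criteria to evaluate, by input name
#'   (`"votes"`, `"tpm_target"`, `"tpm_control"`, `"ratio"`, `"energy"`,
#'   `"mitrap"`); others are marked not-applicable.
#' @return `data.frame` of class `candidateReport`: one row per input miR
#'   with observed values, `pass_i`..`pass_vi`, `pass`, and `rank`
#'   (candidates ranked by [rankCandidates()]; `NA` for non-passers).
#' @export
applyCriteria <- function(records, votes = NULL, energies = NULL,
                          mitrap = NULL,
                          thresholds = selectionThresholds(),
                          criteria = names(CRITERIA)) {
  if (!inherits(thresholds, "selectionThresholds"))
    thresholds <- do.call(selectionThresholds, thresholds)
  criteria <- match.arg(criteria, names(CRITERIA), several.ok = TRUE)
  if (!"mir_id" %in% colnames(records))
    stop("records must contain mir_id")
  n <- nrow(records)
  mir <- records$mir_id
  if (is(votes, "VoteMatrix")) votes <- countVotes(votes)
  get <- function(col) if (col %in% colnames(records))
    records[[col]] else rep(NA_real_, n)
  v <- if (!is.null(votes)) unname(votes[mir]) else rep(NA_integer_, n)
  tT <- get("tpm_target"); tC <- get("tpm_control"); rat <- get("ratio")
  en <- if (!is.null(energies)) unname(energies[mir]) else rep(NA_real_, n)
  fT <- fC <- rep(NA_real_, n)
  if (!is.null(mitrap)) {
    idx <- match(mir, mitrap$mir_id)
    fT <- mitrap$fold_target[idx]; fC <- mitrap$fold_control[idx]
  }
  crit <- function(name, value) if (name %in% criteria) value else
    rep(NA, n)
  rep_ <- data.frame(
    mir_id = mir, votes = v, tpm_target = tT, tpm_control = tC,
    ratio = rat, energy = en, fold_target = fT, fold_control = fC,
    pass_i = crit("votes", v >= thresholds$minTools),
    pass_ii = crit("tpm_target", tT > thresholds$minTpmTarget),
    pass_iii = crit("tpm_control", tC < thresholds$maxTpmControl),
    pass_iv = crit("ratio", rat > thresholds$minRatio),
    pass_v = crit("energy", en < thresholds$maxEnergy),
    pass_vi = crit("mitrap", fT > thresholds$mitrapFactor * fC),
    stringsAsFactors = FALSE)
  passCols <- paste0("pass_", c("i", "ii", "iii", "iv", "v", "vi"))
  rep_$pass <- apply(rep_[, passCols], 1, function(x) all(x[!is.na(x)]))
  rep_$rank <- rep(NA_integer_, n)
  ranked <- rankCandidates(rep_)
  rep_$rank[match(ranked$mir_id, rep_$mir_id)] <- ranked$rank
  attr(rep_, "thresholds") <- thresholds
  attr(rep_, "criteria") <- criteria
  class(rep_) <- c("candidateReport", "data.frame")
  rep_
}

#' Rank passing candidates
#'
#' Passers are ordered by enrichment ratio (descending), ties broken by
#' more negative binding energy, then lexicographic miR id.
#'
#' @param report a `candidateReport` from [applyCriteria()].
#' @return the passing rows, ordered, with `rank` 1..k.
#' @export
rankCandidates <- function(report) {
  p <- report[which(report$pass), , drop = FALSE]
  if (nrow(p) == 0L) { p$rank <- integer(0); return(p) }
  en <- p$energy
  en[is.na(en)] <- Inf  # no energy ranks after any measured energy
  ord <- order(-p$ratio, en, p$mir_id)
  p <- p[ord, , drop = FALSE]
  p$rank <- seq_len(nrow(p))
  rownames(p) <- NULL
  p
}

fmtNum <- function(x) format(x, trim = TRUE, digits = 6)

#' Human-readable audit of the selection report
#'
#' One narrative per miR listing every failed criterion with the observed
#' value and the threshold it missed; passers list zero failures.
#'
#' @param report a `candidateReport` from [applyCriteria()].
#' @return `data.frame` with `mir_id`, `n_failed`, `audit`.
#' @export
selectionAudit <- function(report) {
  th <- attr(report, "thresholds")
  if (is.null(th)) th <- selectionThresholds()
  msgs <- vapply(seq_len(nrow(report)), function(i) {
    r <- report[i, ]
    fails <- character(0)
    if (isFALSE(r$pass_i))
      fails <- c(fails, sprintf("(i) votes %d < %d tools", r$votes,
                                th$minTools))
    if (isFALSE(r$pass_ii))
      fails <- c(fails, sprintf("(ii) target tpm %s <= %s",
                                fmtNum(r$tpm_target),
                                fmtNum(th$minTpmTarget)))
    if (isFALSE(r$pass_iii))
      fails <- c(fails, sprintf("(iii) control tpm %s >= %s",
                                fmtNum(r$tpm_control),
                                fmtNum(th$maxTpmControl)))
    if (isFALSE(r$pass_iv))
      fails <- c(fails, sprintf("(iv) ratio %s <= %s (required > %s)",
                                fmtNum(r$ratio), fmtNum(th$minRatio),
                                fmtNum(th$minRatio)))
    if (isFALSE(r$pass_v))
      fails <- c(fails, sprintf(
        "(v) binding energy %s kcal/mol above %s", fmtNum(r$energy),
        fmtNum(th$maxEnergy)))
    if (isFALSE(r$pass_vi))
      fails <- c(fails, sprintf(
        "(vi) miTRAP fold %s not > %s x control fold %s",
        fmtNum(r$fold_target), fmtNum(th$mitrapFactor),
        fmtNum(r$fold_control)))
    if (length(fails) == 0L) "pass: no failed criteria"
    else paste(fails, collapse = "; ")
  }, character(1))
  nf <- vapply(seq_len(nrow(report)), function(i) {
    x <- report[i, paste0("pass_", c("i", "ii", "iii", "iv", "v", "vi"))]
    sum(vapply(x, isFALSE, logical(1)))
  }, integer(1))
  data.frame(mir_id = report$mir_id, n_failed = nf, audit = msgs,
             stringsAsFactors = FALSE)
}
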