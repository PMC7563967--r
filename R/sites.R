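#' @include AllClasses.R AllGenerics.R duplex.R
#' @importFrom Biostrings RNAString RNAStringSet reverseComplement
#'   matchPattern start width
NULL

seedLength <- function(seedDef = c("6mer", "7mer")) {
  switch(match.arg(seedDef), "6mer" = 6L, "7mer" = 7L)
}

#' Seed sequence of a miR
#'
#' The seed is nucleotides 2-7 (`"6mer"`, default) or 2-8 (`"7mer"`) of
#' the mature miR.
#'
#' @param mirSeq miR sequence, 5'->3'.
#' @param seedDef `"6mer"` or `"7mer"`.
#' @return character seed sequence.
#' @export
mirSeed <- function(mirSeq, seedDef = "6mer") {
  s <- normalizeRna(mirSeq)
  k <- seedLength(seedDef)
  if (nchar(s) < k + 1L)
    stop("miR shorter than its seed definition")
  substr(s, 2L, 1L + k)
}

#' Seed-complementary positions in a UTR
#'
#' Scans the UTR for exact Watson-Crick reverse complements of the miR
#' seed (wobble pairing is not allowed in seed matching). Coordinates are
#' 0-based.
#'
#' @param mirSeq miR sequence, 5'->3' (T read as U).
#' @param utrSeq UTR sequence, 5'->3'.
#' @param seedDef `"6mer"` (miR nt 2-7, default) or `"7mer"` (nt 2-8).
#' @return integer vector of 0-based match start positions (possibly
#'   empty).
#' @export
seedMatches <- function(mirSeq, utrSeq, seedDef = "6mer") {
  utr <- normalizeRna(utrSeq)
  pat <- reverseComplement(RNAString(mirSeed(mirSeq, seedDef)))
  hits <- matchPattern(pat, RNAString(utr))
  as.integer(start(hits)) - 1L
}

#' Scan a UTR for miR binding sites
#'
#' For every seed match, the surrounding UTR window
#' `[match - flank5, match + seedLength + flank3)` (0-based, clipped to
#' the UTR) is folded against the full miR with [duplexMFE()]; the 30-nt
#' 5' context accommodates 3'-compensatory pairing of a ~22-nt miR.
#' Sites with free energy at or below `cutoff` are returned sorted by
#' ascending energy. The per-miR binding energy is the minimum over its
#' sites ([bindingEnergy()]).
#'
#' @param mirSeq,utrSeq sequences, 5'->3'.
#' @param params an [nnParams()] set.
#' @param seedDef `"6mer"` or `"7mer"`.
#' @param cutoff report sites with `delta_g <= cutoff` (kcal/mol,
#'   default -10).
#' @param flank5,flank3 UTR context upstream/downstream of the seed match
#'   included in the folding window (defaults 30 and 5 nt).
#' @return `data.frame` with columns `start`, `end` (0-based half-open
#'   duplex footprint on the UTR), `seed_start`, `seed_class`, `delta_g`,
#'   `structure`; the [DuplexStructure-class] objects are attached as the
#'   `"structures"` attribute.
#' @export
scanSites <- function(mirSeq, utrSeq, params = nnParams(),
                      seedDef = "6mer", cutoff = -10, flank5 = 30L,
                      flank3 = 5L) {
  utr <- normalizeRna(utrSeq)
  mir <- normalizeRna(mirSeq)
  k <- seedLength(seedDef)
  starts <- seedMatches(mir, utr, seedDef)
  rows <- list(); structs <- list()
  for (s in starts) {
    w0 <- max(0L, s - as.integer(flank5))
    w1 <- min(nchar(utr), s + k + as.integer(flank3))
    win <- substr(utr, w0 + 1L, w1)
    d <- duplexMFE(mir, win, params = params,
                   maxWindow = flank5 + k + flank3 + 1L)
    if (!isStable(d) || deltaG(d) > cutoff) next
    p <- pairedBases(d)
    fp0 <- w0 + min(p[, "target"])
    fp1 <- w0 + max(p[, "target"]) + 1L
    cls <- if (s + 7L <= nchar(utr) && nchar(mir) >= 8L &&
               length(seedMatches(mir, substr(utr, s + 1L, s + 7L),
                                  "7mer")) > 0L) "7mer" else "6mer"
    rows[[length(rows) + 1L]] <- data.frame(
      start = fp0, end = fp1, seed_start = s, seed_class = cls,
      delta_g = deltaG(d), structure = d@structure,
      stringsAsFactors = FALSE)
    structs[[length(structs) + 1L]] <- d
  }
  if (!length(rows)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      seed_start = integer(0), seed_class = character(0),
                      delta_g = numeric(0), structure = character(0))
    attr(out, "structures") <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  ord <- order(out$delta_g, out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "structures") <- structs[ord]
  out
}

#' Per-miR binding energy
#'
#' The reported binding energy of a miR against a UTR is the minimum free
#' energy over its scanned sites; `NA` when no site passes the cutoff.
#'
#' @param sites `data.frame` from [scanSites()].
#' @return numeric scalar (kcal/mol) or `NA`.
#' @export
bindingEnergy <- function(sites) {
  if (nrow(sites) == 0L) return(NA_real_)
  min(sites$delta_g)
}

#' Excise a binding site from a UTR
#'
#' Emulates reporter-construct deletion of a miR binding site: the
#' interval is removed and the flanks joined. Deleting an empty interval
#' returns the input unchanged.
#'
#' @param utrSeq UTR sequence.
#' @param start,end 0-based half-open interval to remove; also accepts a
#'   single-row `data.frame` with `start`/`end` columns (e.g. a
#'   [scanSites()] row) as `start`.
#' @return mutated UTR sequence (character).
#' @export
deleteSite <- function(utrSeq, start, end) {
  utr <- normalizeRna(utrSeq)
  if (is.data.frame(start)) {
    if (nrow(start) != 1L) stop("give exactly one site to delete")
    end <- start$end; start <- start$start
  }
  L <- nchar(utr)
  if (start < 0 || end > L || end < start)
    stop("deletion interval [", start, ", ", end, ") out of bounds for a ",
         L, " nt UTR")
  if (end == start) return(utr)
  paste0(substr(utr, 1L, start), substr(utr, end + 1L, L))
}
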