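#' @include AllClasses.R AllGenerics.R nn-params.R
NULL

pairCode <- function(a, b) match(paste0(a, b), rownames(STACK_DG))

#' Minimum free energy of an intermolecular miR:target duplex
#'
#' Dynamic program over all non-crossing intermolecular pairings of the
#' miR (5'->3') against a target window (antiparallel), in the style of
#' duplex-only hybridization tools: only canonical pairs (Watson-Crick
#' plus G:U wobble) may form; consecutive pairs with no unpaired
#' nucleotides between them score the nearest-neighbor stacking energy;
#' unpaired stretches are charged linear bulge/internal-loop penalties up
#' to `params$maxLoop` total unpaired nucleotides per loop; the duplex
#' initiation penalty is added once. Intramolecular structure is not
#' modeled. The program is deterministic; ties are resolved toward the
#' structure found first in a fixed scan order.
#'
#' If no structure with negative free energy exists, a sentinel
#' "no stable duplex" is returned (zero pairs, `deltaG` 0).
#'
#' @param mirSeq miR sequence, 5'->3'. T is silently read as U.
#' @param targetSeq target (UTR window) sequence, 5'->3'.
#' @param params an [nnParams()] parameter set.
#' @param maxWindow maximum target length accepted (default 40 nt).
#' @return a [DuplexStructure-class].
#' @examples
#' d <- duplexMFE("ACGCUUCG", "CGAAGCGU")
#' deltaG(d)  # sum of 7 perfect stacks + initiation
#' @export
duplexMFE <- function(mirSeq, targetSeq, params = nnParams(),
                      maxWindow = 40L) {
  m <- strsplit(normalizeRna(mirSeq), "")[[1]]
  tgt <- strsplit(normalizeRna(targetSeq), "")[[1]]
  n <- length(m); L <- length(tgt)
  if (L > maxWindow)
    stop("target window of ", L, " nt exceeds the ", maxWindow, " nt cap")
  if (n < 2L || L < 2L)
    stop("both sequences must be at least 2 nt")
  r <- rev(tgt)  # pair along the reversed target: monotone in both indices
  S <- params$stack
  maxLoop <- params$maxLoop
  # pair code of (m[i], r[j]) and of the flipped pair (r[j], m[i])
  pc <- outer(m, r, function(a, b) pairCode(a, b))
  pr <- outer(m, r, function(a, b) pairCode(b, a))
  E <- matrix(Inf, n, L)
  PK <- matrix(0L, n, L)  # traceback: previous i (0 = duplex start)
  PL <- matrix(0L, n, L)
  for (i in seq_len(n)) {
    for (j in seq_len(L)) {
      if (is.na(pc[i, j])) next
      best <- params$initiation
      bk <- 0L; bl <- 0L
      for (k in seq_len(i - 1L)) {
        g1 <- i - k - 1L
        if (g1 > maxLoop) next
        for (l in seq_len(j - 1L)) {
          if (is.infinite(E[k, l])) next
          g2 <- j - l - 1L
          if (g1 + g2 > maxLoop) next
          cost <- if (g1 == 0L && g2 == 0L)
            S[pc[k, l], pr[i, j]]
          else if (g1 == 0L || g2 == 0L)
            params$bulgePerNt * (g1 + g2)
          else
            params$internalPerNt * (g1 + g2)
          cand <- E[k, l] + cost
          if (cand < best) { best <- cand; bk <- k; bl <- l }
        }
      }
      E[i, j] <- best
      PK[i, j] <- bk
      PL[i, j] <- bl
    }
  }
  mfe <- suppressWarnings(min(E))
  if (!is.finite(mfe) || mfe >= 0)
    return(new("DuplexStructure", mirSeq = paste(m, collapse = ""),
               targetSeq = paste(tgt, collapse = ""),
               pairs = emptyPairs(), deltaG = 0,
               structure = "no stable duplex"))
  end <- which(E == mfe, arr.ind = TRUE)[1, ]
  path <- matrix(integer(0), ncol = 2)
  i <- end[1]; j <- end[2]
  while (i > 0L) {
    path <- rbind(c(i, j), path)
    k <- PK[i, j]; l <- PL[i, j]
    i <- k; j <- l
  }
  pairs <- cbind(mir = path[, 1] - 1L, target = L - path[, 2])
  new("DuplexStructure", mirSeq = paste(m, collapse = ""),
      targetSeq = paste(tgt, collapse = ""), pairs = pairs,
      deltaG = mfe,
      structure = renderDuplex(m, tgt, pairs))
}

emptyPairs <- function()
  matrix(integer(0), ncol = 2, dimnames = list(NULL, c("mir", "target")))

# Three-line rendering: target 5'->3' on top, miR 3'->5' underneath,
# '|' marking paired bases; loop nucleotides are shown padded with '-'.
renderDuplex <- function(m, tgt, pairs) {
  if (nrow(pairs) == 0L) return("no stable duplex")
  ord <- order(pairs[, "target"])
  tp <- pairs[ord, "target"] + 1L  # 1-based, ascending
  mp <- pairs[ord, "mir"] + 1L     # descending
  top <- tgt[tp[1]]; bot <- m[mp[1]]; bar <- "|"
  if (nrow(pairs) > 1L) for (s in 2:length(tp)) {
    gt <- tp[s] - tp[s - 1L] - 1L
    gm <- mp[s - 1L] - mp[s] - 1L
    g <- max(gt, gm)
    if (g > 0L) {
      tIns <- if (gt > 0L) tgt[(tp[s - 1L] + 1L):(tp[s] - 1L)] else character(0)
      mIns <- if (gm > 0L) m[(mp[s - 1L] - 1L):(mp[s] + 1L)] else character(0)
      top <- paste0(top, paste(c(tolower(tIns), rep("-", g - gt)),
                               collapse = ""))
      bot <- paste0(bot, paste(c(tolower(mIns), rep("-", g - gm)),
                               collapse = ""))
      bar <- paste0(bar, strrep(" ", g))
    }
    top <- paste0(top, tgt[tp[s]])
    bot <- paste0(bot, m[mp[s]])
    bar <- paste0(bar, "|")
  }
  paste0("target 5' ", top, " 3'\n",
         "          ", bar, "\n",
         "miR    3' ", bot, " 5'")
}

#' @rdname deltaG
#' @export
setMethod("deltaG", "DuplexStructure", function(object) object@deltaG)

#' @rdname deltaG
#' @export
setMethod("pairedBases", "DuplexStructure", function(object) object@pairs)

#' @rdname deltaG
#' @export
setMethod("isStable", "DuplexStructure",
          function(object) nrow(object@pairs) > 0L && object@deltaG < 0)

setMethod("show", "DuplexStructure", function(object) {
  if (!isStable(object)) {
    cat("DuplexStructure: no stable duplex\n")
  } else {
    cat(sprintf("DuplexStructure: %d pairs, dG = %.2f kcal/mol\n",
                nrow(object@pairs), object@deltaG))
    cat(object@structure, "\n")
  }
})
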