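# Independent oracles used to cross-check the package's algorithms.
# These re-derive results by enumeration / direct string manipulation and
# deliberately share no code with the implementations they check (the
# nearest-neighbor parameter *table* is shared data; the algorithms are
# not).

# base-by-base reverse complement without Biostrings
rcOracle <- function(s) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
}

# sliding-window 6-mer/7-mer seed scan
seedScanOracle <- function(mirSeq, utrSeq, seedLen = 6L) {
  seed <- substr(mirSeq, 2L, 1L + seedLen)
  pat <- rcOracle(seed)
  L <- nchar(utrSeq)
  hits <- integer(0)
  if (L >= seedLen)
    for (i in 0:(L - seedLen))
      if (substr(utrSeq, i + 1L, i + seedLen) == pat)
        hits <- c(hits, i)
  hits
}

CANONICAL_BF <- c("AU", "UA", "CG", "GC", "GU", "UG")

# Exhaustive enumeration of every legal intermolecular pairing: depth-first
# extension of monotone canonical pair sets, scoring each structure as it
# is built (initiation + stacks for adjacent pairs, linear loop penalties
# otherwise, loops capped at maxLoop). Returns the minimum energy over all
# structures, mapped to the same 0-sentinel convention as duplexMFE.
bfDuplexEnergy <- function(mirSeq, targetSeq, params = nnParams()) {
  m <- strsplit(mirSeq, "")[[1]]
  r <- rev(strsplit(targetSeq, "")[[1]])
  n <- length(m); L <- length(r)
  best <- Inf
  rec <- function(li, lj, e) {
    for (p in seq_len(n)) {
      if (p <= li) next
      for (q in seq_len(L)) {
        if (q <= lj) next
        if (!(paste0(m[p], r[q]) %in% CANONICAL_BF)) next
        if (li == 0L) {
          e2 <- params$initiation
        } else {
          g1 <- p - li - 1L
          g2 <- q - lj - 1L
          if (g1 + g2 > params$maxLoop) next
          cost <- if (g1 == 0L && g2 == 0L)
            params$stack[paste0(m[li], r[lj]), paste0(r[q], m[p])]
          else if (g1 == 0L || g2 == 0L)
            params$bulgePerNt * (g1 + g2)
          else
            params$internalPerNt * (g1 + g2)
          e2 <- e + cost
        }
        if (e2 < best) best <<- e2
        rec(p, q, e2)
      }
    }
  }
  rec(0L, 0L, NA_real_)
  if (is.finite(best) && best < 0) best else 0
}

# all sequences of given lengths over an alphabet
allSeqs <- function(lengths, alphabet) {
  unlist(lapply(lengths, function(k) {
    do.call(paste0, expand.grid(rep(list(alphabet), k),
                                stringsAsFactors = FALSE))
  }))
}

randomSeq <- function(len, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
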