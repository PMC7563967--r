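#' @include AllClasses.R
NULL

# Canonical RNA pairs (including G:U wobble), keyed "XY" = strand1 base X
# paired with strand2 base Y.
CANONICAL_PAIRS <- c("AU", "UA", "CG", "GC", "GU", "UG")

# Turner 2004 / Xia 1998 RNA/RNA nearest-neighbor stacking free energies
# at 37 C, kcal/mol. Entry [p1, p2] is the stack
#   5'-a1 a2-3'
#   3'-b1 b2-5'
# looked up as STACK_DG[pair(a1,b1), pair(b2,a2)] (second pair read from
# the opposite strand, the standard tabulation). The matrix is symmetric,
# which makes the duplex energy invariant under exchanging the two
# strands. Watson-Crick/Watson-Crick stacks are all negative; tandem
# G:U stacks can be destabilizing (positive).
STACK_DG <- matrix(c(
  #  CG     GC     GU     UG     AU     UA
  -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,  # CG
  -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,  # GC
  -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,  # GU
  -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,  # UG
  -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,  # AU
  -2.10, -2.40, -1.30, -1.00, -0.90, -1.30), # UA
  nrow = 6, byrow = TRUE,
  dimnames = list(c("CG", "GC", "GU", "UG", "AU", "UA"),
                  c("CG", "GC", "GU", "UG", "AU", "UA")))

#' Nearest-neighbor energy parameters for RNA:RNA duplexes
#'
#' Bundles the stacking free-energy table (Turner 2004 / Xia 1998 values
#' at 37 C, G:U wobble included), the duplex initiation penalty, and the
#' simplified loop model: unpaired nucleotides inside a duplex are charged
#' a linear per-nucleotide penalty (bulges when one strand is unpaired,
#' internal loops when both are), with a cap on total loop size. This is
#' deliberately a reduced model -- full Turner loop tables, terminal
#' mismatches and dangling ends are not applied -- so energies are an
#' independent interaction score, not a reproduction of any specific
#' folding server.
#'
#' @param initiation duplex initiation penalty, kcal/mol (> 0,
#'   default 4.10).
#' @param bulgePerNt penalty per unpaired nt in a bulge (default 3.0).
#' @param internalPerNt penalty per unpaired nt in an internal loop
#'   (default 1.0).
#' @param maxLoop maximum total unpaired nucleotides between two
#'   consecutive pairs (default 15).
#' @return list of class `nnParams` with elements `stack`, `initiation`,
#'   `bulgePerNt`, `internalPerNt`, `maxLoop`.
#' @export
nnParams <- function(initiation = 4.10, bulgePerNt = 3.0,
                     internalPerNt = 1.0, maxLoop = 15L) {
  if (initiation <= 0) stop("initiation penalty must be positive")
  if (bulgePerNt < 0 || internalPerNt < 0)
    stop("loop penalties must be non-negative")
  if (maxLoop < 1) stop("maxLoop must be >= 1")
  structure(list(stack = STACK_DG, initiation = initiation,
                 bulgePerNt = bulgePerNt, internalPerNt = internalPerNt,
                 maxLoop = as.integer(maxLoop)),
            class = "nnParams")
}

#' Read nearest-neighbor parameters from a tabular file
#'
#' Expects a TSV with columns `pair1`, `pair2`, `dg` for the stack table
#' (pairs as two-letter strings, e.g. `AU`), plus rows with `pair1` set to
#' `initiation`, `bulge_per_nt`, `internal_per_nt` or `max_loop` and the
#' value in `dg`.
#'
#' @param path file path.
#' @return an `nnParams` list.
#' @export
readNNParams <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pair1", "pair2", "dg") %in% colnames(d)))
    stop("parameter file needs columns pair1, pair2, dg")
  scalars <- d$pair1 %in% c("initiation", "bulge_per_nt", "internal_per_nt",
                            "max_loop")
  getScalar <- function(key, default) {
    i <- which(d$pair1 == key)
    if (length(i)) d$dg[i[1]] else default
  }
  p <- nnParams(initiation = getScalar("initiation", 4.10),
                bulgePerNt = getScalar("bulge_per_nt", 3.0),
                internalPerNt = getScalar("internal_per_nt", 1.0),
                maxLoop = getScalar("max_loop", 15L))
  st <- d[!scalars, , drop = FALSE]
  if (nrow(st)) {
    ok <- st$pair1 %in% rownames(STACK_DG) & st$pair2 %in% colnames(STACK_DG)
    if (!all(ok)) stop("unknown stack pair in parameter file")
    p$stack[cbind(st$pair1, st$pair2)] <- st$dg
  }
  p
}

# Stack energy for consecutive pairs (a1:b1) then (a2:b2) along strand 1,
# strand 2 read antiparallel.
stackEnergy <- function(params, a1, b1, a2, b2) {
  params$stack[paste0(a1, b1), paste0(b2, a2)]
}

isCanonical <- function(a, b) paste0(a, b) %in% CANONICAL_PAIRS

#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Uppercases and converts T to U; any symbol outside A/C/G/U is an error.
#'
#' @param seq character scalar (or `Biostrings` XString).
#' @return character scalar over A/C/G/U.
#' @export
normalizeRna <- function(seq) {
  s <- toupper(as.character(seq))
  s <- chartr("T", "U", s)
  if (grepl("[^ACGU]", s))
    stop("sequence contains symbols outside A/C/G/U(/T): ",
         gsub("[ACGU]", "", s))
  s
}
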