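#' @include AllClasses.R AllGenerics.R
NULL

COUNT_COLS <- c("mir_id", "locus_id", "sample_id", "bait", "replicate",
                "count")

checkCountTable <- function(counts, locusLevel = TRUE) {
  need <- if (locusLevel) COUNT_COLS else setdiff(COUNT_COLS, "locus_id")
  miss <- setdiff(need, colnames(counts))
  if (length(miss))
    stop("count table is missing columns: ", paste(miss, collapse = ", "))
  if (any(counts$count < 0)) stop("counts must be non-negative")
  if (any(counts$count != floor(counts$count)))
    stop("counts must be integers")
  bad <- setdiff(unique(counts$bait), BAITS)
  if (length(bad))
    stop("unknown bait label(s): ", paste(bad, collapse = ", "))
  if (locusLevel) {
    key <- paste(counts$mir_id, counts$locus_id, counts$sample_id)
    if (anyDuplicated(key))
      stop("duplicate (mir_id, locus_id, sample_id) rows in count table")
  }
  invisible(counts)
}

#' Read a long-format miR count table
#'
#' Expects a TSV with columns `mir_id`, `locus_id`, `sample_id`, `bait`
#' (one of `target`, `control`, `input`), `replicate`, `count`.
#'
#' @param path file path.
#' @return validated `data.frame`.
#' @export
readCountTable <- function(path) {
  counts <- utils::read.delim(path, stringsAsFactors = FALSE)
  checkCountTable(counts)
}

#' Aggregate locus-level counts per miR
#'
#' A mature miR can be encoded by multiple genomic loci; sequencing counts
#' are reported per locus. This sums locus counts within each
#' (miR, sample), leaving per-sample totals unchanged.
#'
#' @param counts locus-level count `data.frame` (see [readCountTable()]);
#'   duplicate (mir_id, locus_id, sample_id) rows are an input error.
#' @return count `data.frame` with one row per (mir_id, sample_id) and no
#'   `locus_id` column.
#' @examples
#' counts <- data.frame(
#'   mir_id = "miR-a", locus_id = c("L1", "L2"), sample_id = "s1",
#'   bait = "target", replicate = 1L, count = c(10L, 5L))
#' aggregateLoci(counts)$count  # 15
#' @export
aggregateLoci <- function(counts) {
  checkCountTable(counts)
  agg <- stats::aggregate(count ~ mir_id + sample_id, data = counts,
                          FUN = sum)
  meta <- unique(counts[, c("sample_id", "bait", "replicate")])
  if (anyDuplicated(meta$sample_id))
    stop("inconsistent bait/replicate annotation within a sample")
  out <- merge(agg, meta, by = "sample_id", sort = FALSE)
  out <- out[order(out$sample_id, out$mir_id),
             c("mir_id", "sample_id", "bait", "replicate", "count")]
  rownames(out) <- NULL
  out
}

#' Construct a MitrapExperiment from a long count table
#'
#' Locus-level rows are aggregated per miR ([aggregateLoci()]) and pivoted
#' into a miR-by-library count matrix; bait and replicate metadata go into
#' `colData`.
#'
#' @param counts long count `data.frame`, locus-level (with `locus_id`) or
#'   already miR-level.
#' @return a [MitrapExperiment-class].
#' @export
MitrapExperiment <- function(counts) {
  if ("locus_id" %in% colnames(counts)) counts <- aggregateLoci(counts)
  else checkCountTable(counts, locusLevel = FALSE)
  mirs <- sort(unique(counts$mir_id))
  samples <- unique(counts$sample_id)
  mat <- matrix(0, nrow = length(mirs), ncol = length(samples),
                dimnames = list(mirs, samples))
  mat[cbind(match(counts$mir_id, mirs), match(counts$sample_id, samples))] <-
    counts$count
  meta <- unique(counts[, c("sample_id", "bait", "replicate")])
  meta <- meta[match(samples, meta$sample_id), ]
  se <- SummarizedExperiment(
    assays = list(counts = mat),
    colData = DataFrame(sample_id = meta$sample_id, bait = meta$bait,
                        replicate = meta$replicate, row.names = samples))
  new("MitrapExperiment", se)
}

tpmFromVector <- function(v, sample) {
  total <- sum(v)
  if (total <= 0)
    stop("sample '", sample, "' has zero total count; cannot compute tpm")
  v / total * 1e6
}

#' @rdname countsToTpm
#' @export
setMethod("countsToTpm", "data.frame", function(x, ...) {
  if ("locus_id" %in% colnames(x)) x <- aggregateLoci(x)
  else checkCountTable(x, locusLevel = FALSE)
  parts <- split(x, x$sample_id)
  out <- do.call(rbind, lapply(parts, function(d) {
    d$tpm <- tpmFromVector(d$count, d$sample_id[1])
    d
  }))
  rownames(out) <- NULL
  out[, c("mir_id", "sample_id", "bait", "replicate", "tpm")]
})

#' @rdname countsToTpm
#' @export
setMethod("countsToTpm", "MitrapExperiment", function(x, ...) {
  cnt <- assay(x, "counts")
  tpm <- matrix(vapply(seq_len(ncol(cnt)),
                       function(j) tpmFromVector(cnt[, j], colnames(cnt)[j]),
                       numeric(nrow(cnt))),
                nrow = nrow(cnt), dimnames = dimnames(cnt))
  assay(x, "tpm") <- tpm
  x
})

#' Read-length quality control for a small RNA library
#'
#' Mature miRs are ~22 nt; a library dominated by the miR fraction shows a
#' modal read length of 21-23 nt. The check is advisory: a failing mode
#' raises a warning, never an error. Ties between modal lengths are broken
#' toward the smaller length.
#'
#' @param hist read-length histogram: a named numeric vector
#'   (names = length in nt) or a `data.frame` with columns `length`,
#'   `count`.
#' @param range acceptable modal-length window (default `c(21, 23)`).
#' @return list with `pass`, `modal_length` and the histogram.
#' @examples
#' lengthQC(c(`21` = 50, `22` = 120, `23` = 60, `30` = 10))$pass  # TRUE
#' @export
lengthQC <- function(hist, range = c(21, 23)) {
  if (is.data.frame(hist)) {
    h <- hist$count
    names(h) <- hist$length
    hist <- h
  }
  if (length(hist) == 0L) stop("empty histogram")
  if (any(hist < 0)) stop("histogram counts must be non-negative")
  if (sum(hist) == 0) stop("all-zero histogram")
  len <- as.numeric(names(hist))
  if (anyNA(len)) stop("histogram names must be read lengths in nt")
  ord <- order(len)
  len <- len[ord]; hist <- hist[ord]
  modal <- len[which.max(hist)]  # first max = smallest length on ties
  pass <- modal >= range[1] && modal <= range[2]
  if (!pass)
    warning(sprintf(
      "modal read length %g nt outside %g-%g nt: library may not be miR-dominated",
      modal, range[1], range[2]))
  list(pass = pass, modal_length = modal, histogram = hist)
}

setMethod("show", "MitrapExperiment", function(object) {
  cd <- colData(object)
  cat("MitrapExperiment:", nrow(object), "miRs x", ncol(object),
      "libraries\n")
  cat("  baits:",
      paste(sprintf("%s (n=%d)", names(table(cd$bait)), table(cd$bait)),
            collapse = ", "), "\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
})
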