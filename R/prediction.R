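#' @include AllClasses.R AllGenerics.R
NULL

#' The six default target-prediction tools
#'
#' Column order follows the published consensus table.
#' @export
PREDICTION_TOOLS <- c("miRWalk", "microrna.org", "miRDB", "TargetScan",
                      "RNA22", "RNAhybrid")

parsePredicted <- function(tok, where = "prediction table") {
  t <- tolower(trimws(as.character(tok)))
  out <- rep(NA, length(t))
  out[t %in% c("yes", "true", "1")] <- TRUE
  out[t %in% c("no", "false", "0")] <- FALSE
  bad <- which(is.na(out))
  if (length(bad))
    stop(sprintf("%s: unrecognized prediction token '%s' at row %d",
                 where, tok[bad[1]], bad[1]))
  as.logical(out)
}

#' Merge per-tool prediction tables into a VoteMatrix
#'
#' Each tool contributes a table of (mir_id, predicted) rows; yes/no
#' tokens are parsed case-insensitively (`yes`/`Yes`/`TRUE`/`1` are all
#' true). (miR, tool) pairs absent from a tool's table default to "not
#' predicted" rather than NA, matching the dense yes/no layout of
#' published consensus tables.
#'
#' @param tables named list of `data.frame`s (one per tool, names are the
#'   tool names) with columns `mir_id` and `predicted`.
#' @param mirs optional character vector fixing the miR universe (row
#'   order); defaults to the union of miRs seen in any table.
#' @param tools tool set (column order); defaults to `names(tables)`.
#' @return a [VoteMatrix-class].
#' @export
loadToolPredictions <- function(tables, mirs = NULL, tools = names(tables)) {
  if (is.null(tools) || anyDuplicated(tools))
    stop("tables must be a named list with unique tool names")
  if (is.null(mirs))
    mirs <- unique(unlist(lapply(tables, function(d) d$mir_id)))
  mat <- matrix(FALSE, nrow = length(mirs), ncol = length(tools),
                dimnames = list(mirs, tools))
  for (tool in tools) {
    d <- tables[[tool]]
    if (is.null(d) || nrow(d) == 0L) next
    if (!all(c("mir_id", "predicted") %in% colnames(d)))
      stop("tool '", tool, "': table needs columns mir_id, predicted")
    pred <- parsePredicted(d$predicted, where = tool)
    known <- d$mir_id %in% mirs
    if (!all(known))
      stop("tool '", tool, "': miR(s) outside the given universe: ",
           paste(unique(d$mir_id[!known]), collapse = ", "))
    mat[cbind(match(d$mir_id, mirs), match(tool, tools))] <- pred
  }
  new("VoteMatrix", predictions = mat)
}

#' VoteMatrix from a logical matrix
#'
#' @param predictions logical matrix with miR rownames and tool colnames.
#' @return a [VoteMatrix-class].
#' @export
VoteMatrix <- function(predictions) {
  mode(predictions) <- "logical"
  new("VoteMatrix", predictions = predictions)
}

#' @rdname countVotes
#' @export
setMethod("countVotes", "VoteMatrix", function(object, mir) {
  votes <- rowSums(object@predictions)
  storage.mode(votes) <- "integer"
  if (missing(mir)) return(votes)
  unknown <- setdiff(mir, names(votes))
  if (length(unknown))
    stop("unknown miR(s): ", paste(unknown, collapse = ", "))
  votes[mir]
})

#' @rdname filterByVotes
#' @export
setMethod("filterByVotes", "VoteMatrix", function(object, minTools) {
  nt <- ncol(object@predictions)
  if (minTools < 0 || minTools > nt)
    stop("minTools must be between 0 and ", nt)
  votes <- countVotes(object)
  names(votes)[votes >= minTools]
})

setMethod("show", "VoteMatrix", function(object) {
  p <- object@predictions
  cat("VoteMatrix:", nrow(p), "miRs x", ncol(p), "tools\n")
  cat("  tools:", paste(colnames(p), collapse = ", "), "\n")
  v <- rowSums(p)
  cat("  votes:", paste(sprintf("%d miRs with %s", table(v),
                                names(table(v))), collapse = ", "), "\n")
})

#' Write / read a VoteMatrix as TSV
#'
#' Serialization round-trips the logical matrix as `yes`/`no` tokens.
#'
#' @param object a [VoteMatrix-class].
#' @param path file path.
#' @return `readVoteMatrix` returns a [VoteMatrix-class].
#' @export
writeVoteMatrix <- function(object, path) {
  p <- object@predictions
  d <- data.frame(mir_id = rownames(p),
                  ifelse(p, "yes", "no"), check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVoteMatrix
#' @export
readVoteMatrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  mat <- as.matrix(d[, -1, drop = FALSE])
  rownames(mat) <- d$mir_id
  out <- matrix(parsePredicted(mat, where = path), nrow = nrow(mat),
                dimnames = dimnames(mat))
  VoteMatrix(out)
}

#' Load the published 21-miR consensus prediction table
#'
#' Parses the transcribed consensus table shipped with the package: for
#' each of 21 enriched candidate miRs, the RNA-seq enrichment ratio,
#' yes/no predictions of six tools, the printed vote count and the
#' reported binding energy (kcal/mol). On load, the printed vote count of
#' every row is checked against the count recomputed from the yes/no
#' columns; a mismatch is an error naming the accession.
#'
#' @param path fixture path; defaults to the copy under `extdata`.
#' @return `data.frame` with columns `accession`, `mir_id`, `ratio`, one
#'   logical column per tool (see [PREDICTION_TOOLS]), `votes_printed`,
#'   `energy`.
#' @export
readTable2 <- function(path = system.file("extdata", "table2.tsv",
                                          package = "miTRAPseq")) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- c("accession", "mir_id", "ratio", PREDICTION_TOOLS,
            "votes_printed", "energy")
  miss <- setdiff(need, colnames(d))
  if (length(miss))
    stop("consensus table missing columns: ", paste(miss, collapse = ", "))
  for (tool in PREDICTION_TOOLS)
    d[[tool]] <- parsePredicted(d[[tool]], where = tool)
  d$ratio <- as.numeric(d$ratio)
  # tolerate a typeset Unicode minus on the energies
  d$energy <- as.numeric(gsub("−", "-", d$energy))
  recomputed <- rowSums(as.matrix(d[, PREDICTION_TOOLS]))
  bad <- which(recomputed != d$votes_printed)
  if (length(bad))
    stop("vote-count mismatch for ",
         paste(d$accession[bad], collapse = ", "),
         ": printed != recomputed")
  d[, need]
}

#' VoteMatrix view of the consensus prediction table
#'
#' @param table2 `data.frame` from [readTable2()].
#' @return a [VoteMatrix-class] over the table's 21 miRs and six tools.
#' @export
table2VoteMatrix <- function(table2 = readTable2()) {
  mat <- as.matrix(table2[, PREDICTION_TOOLS])
  rownames(mat) <- table2$mir_id
  VoteMatrix(mat)
}
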