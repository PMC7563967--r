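# small in-code fixtures

# long count table: one row per (miR, locus, sample)
makeCounts <- function(counts, baits, replicates = 1L) {
  # counts: named list sample_id -> named numeric (mir -> count)
  do.call(rbind, lapply(seq_along(counts), function(s) {
    v <- counts[[s]]
    data.frame(mir_id = names(v), locus_id = paste0(names(v), "_L1"),
               sample_id = names(counts)[s], bait = baits[s],
               replicate = rep_len(replicates, 1L), count = unname(v),
               stringsAsFactors = FALSE)
  }))
}

randomCountTable <- function(nMirs = 20, nLociMax = 3, samples = 2,
                             seed = 1) {
  set.seed(seed)
  mirs <- sprintf("m%02d", seq_len(nMirs))
  nl <- sample(seq_len(nLociMax), nMirs, replace = TRUE)
  do.call(rbind, lapply(seq_len(samples), function(s) {
    data.frame(mir_id = rep(mirs, nl),
               locus_id = paste0(rep(mirs, nl), "_L",
                                 unlist(lapply(nl, seq_len))),
               sample_id = paste0("s", s),
               bait = c("target", "control", "input")[(s - 1) %% 3 + 1],
               replicate = (s - 1) %/% 3 + 1,
               count = rpois(sum(nl), 50),
               stringsAsFactors = FALSE)
  }))
}

# a small tool-prediction table list
makeToolTables <- function(pred) {
  # pred: logical matrix miR x tool
  lapply(setNames(colnames(pred), colnames(pred)), function(tool) {
    data.frame(mir_id = rownames(pred),
               predicted = ifelse(pred[, tool], "yes", "no"),
               stringsAsFactors = FALSE)
  })
}
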