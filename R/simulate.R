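#' @include AllClasses.R AllGenerics.R sites.R
#' @importFrom stats rmultinom rlnorm runif rnorm rgamma
NULL

#' Configure the synthetic miTRAP study
#'
#' Builds a validated [SimulationConfig-class]. The defaults are the
#' study conditions the generators emulate: a 2693-miR universe with a
#' small planted enriched subset, two biological replicates per bait at
#' one million reads each, target-bait enrichment multipliers above 50,
#' and qPCR fold changes of 700 and 50 for the two leading planted miRs.
#'
#' @param nMirs,nEnriched,depthPerSample,plantedRatioRange,nReplicates
#'   see [SimulationConfig-class].
#' @param utrLength,nPlantedSites,plantedFoldChanges,ctNoiseSd see
#'   [SimulationConfig-class].
#' @param nPatients,patientMirEffect,patientCd8Effect,rngSeed see
#'   [SimulationConfig-class].
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(nMirs = 2693L, nEnriched = 5L,
                             depthPerSample = 1e6,
                             plantedRatioRange = c(100, 200),
                             nReplicates = 2L, utrLength = 600L,
                             nPlantedSites = 2L,
                             plantedFoldChanges = numeric(0),
                             ctNoiseSd = 0.2, nPatients = 20L,
                             patientMirEffect = 2,
                             patientCd8Effect = 40, rngSeed = 42L) {
  new("SimulationConfig", nMirs = as.integer(nMirs),
      nEnriched = as.integer(nEnriched),
      depthPerSample = depthPerSample,
      plantedRatioRange = as.numeric(plantedRatioRange),
      nReplicates = as.integer(nReplicates),
      utrLength = as.integer(utrLength),
      nPlantedSites = as.integer(nPlantedSites),
      plantedFoldChanges = plantedFoldChanges,
      ctNoiseSd = ctNoiseSd, nPatients = as.integer(nPatients),
      patientMirEffect = patientMirEffect,
      patientCd8Effect = patientCd8Effect, rngSeed = as.integer(rngSeed))
}

mirUniverse <- function(config)
  sprintf("mir-%04d", seq_len(config@nMirs))

# Deterministic planted set: same for every generator under one config.
plantedSet <- function(config) {
  if (config@nEnriched == 0L) return(character(0))
  set.seed(config@rngSeed)
  sort(sample(mirUniverse(config), config@nEnriched))
}

# qPCR fold changes per planted miR: defaults 700, 50, then 100.
plantedFoldMap <- function(config, planted = plantedSet(config)) {
  if (length(planted) == 0L) return(numeric(0))
  if (length(config@plantedFoldChanges)) {
    f <- config@plantedFoldChanges
    if (is.null(names(f))) {
      f <- rep_len(f, length(planted))
      names(f) <- planted
    }
    return(f)
  }
  f <- rep(100, length(planted))
  f[1] <- 700
  if (length(planted) > 1L) f[2] <- 50
  names(f) <- planted
  f
}

# Planted miRs are anchored at a relative abundance of 5e-5 (~50 tpm in
# control/input libraries) so that the enrichment multiplier puts their
# target-bait tpm above 1000 while the control stays below 100 -- the
# regime the selection thresholds describe.
PLANTED_BASELINE_P <- 5e-5

#' Simulate miTRAP small RNA count tables with planted enrichment
#'
#' Draws per-library counts multinomially from per-bait abundance
#' vectors: control-bait and input libraries share a log-normal baseline
#' abundance profile; in the target-bait eluate, each planted miR's
#' abundance is multiplied by a factor drawn from
#' `plantedRatioRange` and the vector renormalized. Each library is one
#' multinomial draw of `depthPerSample` reads, so counts per sample are
#' conserved exactly. About 12% of miRs are encoded by 2-3 loci; their
#' abundance is split over loci so the locus-aggregation step is
#' exercised. Deterministic given `rngSeed`.
#'
#' @param config a [simulationConfig()].
#' @return list with `counts` (long locus-level count `data.frame`) and
#'   `truth` (a [PlantedTruth-class] carrying the planted miR set and the
#'   expected target/control tpm ratios from the actual abundance
#'   vectors).
#' @export
simulateMitrapCounts <- function(config) {
  validObject(config)
  mirs <- mirUniverse(config)
  planted <- plantedSet(config)
  set.seed(config@rngSeed + 1L)
  # baseline abundance: log-normal over non-planted, planted anchored
  w <- rlnorm(config@nMirs, meanlog = 0, sdlog = 1.2)
  names(w) <- mirs
  p <- w / sum(w)
  if (length(planted)) {
    rest <- setdiff(mirs, planted)
    p[rest] <- p[rest] / sum(p[rest]) *
      (1 - PLANTED_BASELINE_P * length(planted))
    p[planted] <- PLANTED_BASELINE_P
  }
  mult <- runif(length(planted), config@plantedRatioRange[1],
                config@plantedRatioRange[2])
  names(mult) <- planted
  q <- p
  q[planted] <- q[planted] * mult
  q <- q / sum(q)
  expectedRatios <- (q[planted] * 1e6) / (p[planted] * 1e6)
  # multi-locus structure
  nLoci <- sample(1:3, config@nMirs, replace = TRUE,
                  prob = c(0.88, 0.10, 0.02))
  names(nLoci) <- mirs
  locusMir <- rep(mirs, nLoci)
  locusId <- unlist(lapply(nLoci, function(k) seq_len(k)), use.names = FALSE)
  locusId <- paste0(locusMir, "_L", locusId)
  share <- rgamma(length(locusMir), shape = 2)
  shareSum <- tapply(share, locusMir, sum)
  locusFrac <- share / shareSum[locusMir]
  locusP <- p[locusMir] * locusFrac
  locusQ <- q[locusMir] * locusFrac
  samples <- expand.grid(replicate = seq_len(config@nReplicates),
                         bait = BAITS, stringsAsFactors = FALSE)
  counts <- do.call(rbind, lapply(seq_len(nrow(samples)), function(s) {
    bait <- samples$bait[s]; repl <- samples$replicate[s]
    prob <- if (bait == "target") locusQ else locusP
    cnt <- as.integer(rmultinom(1, size = config@depthPerSample,
                                prob = prob))
    data.frame(mir_id = locusMir, locus_id = locusId,
               sample_id = sprintf("%s_rep%d", bait, repl),
               bait = bait, replicate = repl, count = cnt,
               stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  truth <- new("PlantedTruth", enrichedMirs = planted,
               expectedRatios = expectedRatios,
               plantedFolds = plantedFoldMap(config, planted),
               siteCoords = data.frame(mir_id = character(0),
                                       start = integer(0),
                                       end = integer(0),
                                       seed_start = integer(0)))
  list(counts = counts, truth = truth)
}

randomRna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                      replace = TRUE), collapse = "")

rcRna <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(s)))

#' Simulate miR sequences and a bait 3'UTR with planted binding sites
#'
#' Generates 22-nt miR sequences for the planted miRs (plus a few
#' background miRs without sites) and a background UTR into which binding
#' sites are spliced. Each planted site contains the full reverse
#' complement of the miR's 8 5'-most nucleotides (hence a perfect seed
#' match at nt 2-7) preceded by reverse-complementary 3' pairing
#' (miR nt 13-18) and a 2-nt spacer -- a canonical seed plus
#' 3'-supplementary architecture. The background is rejection-sampled so
#' that no 6-mer seed complement of any planted miR occurs outside the
#' planted intervals. Sites are distributed round-robin over the planted
#' miRs. Deterministic given `rngSeed`.
#'
#' @param config a [simulationConfig()].
#' @param nBackgroundMirs decoy miRs with sequences but no planted sites
#'   (default 3).
#' @return list with `mirs` (named character, 5'->3'), `utr` (character),
#'   `truth` (a [PlantedTruth-class] whose `siteCoords` holds 0-based
#'   half-open site intervals and seed-match starts).
#' @export
simulateSequences <- function(config, nBackgroundMirs = 3L) {
  validObject(config)
  planted <- plantedSet(config)
  set.seed(config@rngSeed + 2L)
  siteMirs <- if (config@nPlantedSites > 0L) {
    if (length(planted) == 0L)
      stop("cannot plant sites with nEnriched = 0")
    planted[((seq_len(config@nPlantedSites) - 1L) %% length(planted)) + 1L]
  } else character(0)
  seqMirs <- unique(c(planted,
                      if (nBackgroundMirs > 0)
                        sprintf("bg-mir-%02d", seq_len(nBackgroundMirs))))
  siteLen <- 16L
  nS <- length(siteMirs)
  L <- config@utrLength
  if (nS > 0L) {
    slot <- L %/% nS
    if (slot < siteLen + 4L) stop("UTR too short to place sites")
    starts <- as.integer((seq_len(nS) - 1L) * slot + (slot - siteLen) %/% 2L)
  } else starts <- integer(0)
  # rejection-sample miRs + background until no stray seed complement
  # exists anywhere outside the planted intervals
  for (attempt in 1:100) {
    mirSeqs <- vapply(seqMirs, function(m) randomRna(22L), character(1))
    siteSeq <- vapply(siteMirs, function(m) {
      s <- mirSeqs[[m]]
      paste0(rcRna(substr(s, 13L, 18L)), "AA", rcRna(substr(s, 1L, 8L)))
    }, character(1))
    utr <- strsplit(randomRna(L), "")[[1]]
    for (s in seq_len(nS))
      utr[(starts[s] + 1L):(starts[s] + siteLen)] <-
        strsplit(siteSeq[s], "")[[1]]
    utrStr <- paste(utr, collapse = "")
    ok <- TRUE
    for (m in seqMirs) {
      hits <- seedMatches(mirSeqs[[m]], utrStr, "6mer")
      allowed <- if (m %in% siteMirs)
        starts[siteMirs == m] + 9L else integer(0)
      if (!setequal(hits, allowed)) { ok <- FALSE; break }
    }
    if (ok) break
    if (attempt == 100L)
      stop("could not place sites without stray seed matches")
  }
  siteCoords <- if (nS > 0L)
    data.frame(mir_id = siteMirs, start = starts,
               end = starts + siteLen, seed_start = starts + 9L,
               stringsAsFactors = FALSE)
  else data.frame(mir_id = character(0), start = integer(0),
                  end = integer(0), seed_start = integer(0))
  truth <- new("PlantedTruth", enrichedMirs = planted,
               expectedRatios = numeric(0),
               plantedFolds = plantedFoldMap(config, planted),
               siteCoords = siteCoords)
  list(mirs = mirSeqs, utr = utrStr, truth = truth)
}

#' Simulate qPCR Ct tables encoding planted miTRAP fold changes
#'
#' For every planted miR, three samples are measured (input,
#' target-bait eluate, MS2 control-bait eluate) in three technical
#' replicates: `Ct(eluate) = Ct(input) - log2(fold) + noise`, with the
#' target-bait fold taken from the planted truth and the control-bait
#' fold fixed at 1 (the MS2 bait does not enrich). The reference assay
#' (RNU6A) is constant within each sample. With `ctNoiseSd = 0` the
#' planted folds are recovered exactly by [mitrapRatio()].
#'
#' @param truth a [PlantedTruth-class] (from either generator).
#' @param config a [simulationConfig()].
#' @param baselineCt input-sample Ct for every miR assay (default 25).
#' @return `data.frame` with `sample_id`, `assay_id`, `ct`, `replicate`,
#'   `is_reference`.
#' @export
simulateQpcr <- function(truth, config, baselineCt = 25) {
  folds <- plantedFolds(truth)
  if (length(folds) == 0L) stop("no planted fold changes to encode")
  if (any(folds <= 0)) stop("planted folds must be positive")
  set.seed(config@rngSeed + 3L)
  samples <- c(input = 0, eluate_target = NA, eluate_control = 0)
  rows <- list()
  for (m in names(folds)) {
    foldBySample <- c(input = 1, eluate_target = unname(folds[m]),
                      eluate_control = 1)
    for (smp in names(foldBySample)) {
      ct0 <- baselineCt - log2(foldBySample[smp])
      for (r in 1:3) {
        noise <- if (config@ctNoiseSd > 0)
          rnorm(1, 0, config@ctNoiseSd) else 0
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = smp, assay_id = m,
          ct = min(CT_MAX, max(0, ct0 + noise)), replicate = r,
          is_reference = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  ref <- expand.grid(sample_id = names(samples), replicate = 1:3,
                     stringsAsFactors = FALSE)
  ref$assay_id <- "RNU6A"
  ref$ct <- 18
  ref$is_reference <- TRUE
  out <- rbind(do.call(rbind, rows),
               ref[, c("sample_id", "assay_id", "ct", "replicate",
                       "is_reference")])
  rownames(out) <- NULL
  out
}

#' Simulate a melanoma patient cohort with TAP1/miR/CD8 structure
#'
#' Half the patients are TAP1-high (staining frequency > 30%) with high
#' CD8+ infiltration and low miR expression; half are TAP1-low (0-10%)
#' with the inverse -- the planted inverse association between the miR
#' and its target. `patientMirEffect` is the log2 difference in miR
#' relative expression (low minus high group) and `patientCd8Effect` the
#' difference in mean CD8 counts per HPF (high minus low); both 0 gives
#' exchangeable groups.
#'
#' @param config a [simulationConfig()].
#' @param mirNoiseSd log2-scale sd of miR expression (default 0.5).
#' @param cd8Sd sd of CD8 counts (default 10).
#' @return `data.frame` with `patient_id`, `tap1_frequency`,
#'   `tap1_group`, `cd8_per_hpf`, `mir_rel_expr`.
#' @export
simulatePatients <- function(config, mirNoiseSd = 0.5, cd8Sd = 10) {
  validObject(config)
  n <- config@nPatients
  set.seed(config@rngSeed + 4L)
  half <- n %/% 2L
  grp <- rep(c("high", "low"), each = half)
  freq <- c(runif(half, 35, 95), runif(half, 0, 10))
  cd8mean <- 40 + ifelse(grp == "high", 1, -1) * config@patientCd8Effect / 2
  cd8 <- pmax(0, rnorm(n, cd8mean, cd8Sd))
  mirMu <- ifelse(grp == "low", 1, -1) * config@patientMirEffect / 2
  mir <- 2^(rnorm(n, mirMu, mirNoiseSd))
  data.frame(patient_id = sprintf("patient_%02d", seq_len(n)),
             tap1_frequency = freq, tap1_group = grp,
             cd8_per_hpf = cd8, mir_rel_expr = mir,
             stringsAsFactors = FALSE)
}

#' @rdname enrichedMirs
#' @export
setMethod("enrichedMirs", "PlantedTruth",
          function(object) object@enrichedMirs)

#' @rdname enrichedMirs
#' @export
setMethod("plantedFolds", "PlantedTruth",
          function(object) object@plantedFolds)

#' @rdname enrichedMirs
#' @export
setMethod("expectedRatios", "PlantedTruth",
          function(object) object@expectedRatios)

#' @rdname enrichedMirs
#' @export
setMethod("siteCoords", "PlantedTruth",
          function(object) object@siteCoords)

setMethod("show", "PlantedTruth", function(object) {
  cat("PlantedTruth:", length(object@enrichedMirs), "enriched miRs,",
      nrow(object@siteCoords), "planted sites\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d miRs (%d planted), depth %g, %d replicates, seed %d\n",
    object@nMirs, object@nEnriched, object@depthPerSample,
    object@nReplicates, object@rngSeed))
})

#' Write every synthetic input to an output directory
#'
#' Convenience wrapper running all four generators and writing plain-text
#' outputs: `counts.tsv`, `mirs.fasta`, `utr.fasta`, `qpcr.tsv`,
#' `patients.tsv`, `truth.json`.
#'
#' @param config a [simulationConfig()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the list of generated objects.
#' @export
writeSimulatedInputs <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cnt <- simulateMitrapCounts(config)
  seqs <- simulateSequences(config)
  qpcr <- simulateQpcr(seqs$truth, config)
  patients <- simulatePatients(config)
  utils::write.table(cnt$counts, file.path(outdir, "counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(
    Biostrings::RNAStringSet(seqs$mirs), file.path(outdir, "mirs.fasta"))
  Biostrings::writeXStringSet(
    Biostrings::RNAStringSet(c(utr = seqs$utr)),
    file.path(outdir, "utr.fasta"))
  utils::write.table(qpcr, file.path(outdir, "qpcr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(patients, file.path(outdir, "patients.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truthList <- list(enriched_mirs = enrichedMirs(cnt$truth),
                    expected_ratios = as.list(expectedRatios(cnt$truth)),
                    planted_folds = as.list(plantedFolds(seqs$truth)),
                    site_coords = siteCoords(seqs$truth))
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(truthList, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(list(counts = cnt, sequences = seqs, qpcr = qpcr,
                 patients = patients))
}
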