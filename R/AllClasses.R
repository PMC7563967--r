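#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData assay<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

BAITS <- c("target", "control", "input")

#' MitrapExperiment: miR counts from a miTRAP pull-down experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] subclass holding a
#' per-miR count matrix (rows: miRs, columns: sequencing libraries) with
#' the bait identity (`"target"` bait 3'UTR, `"control"` MS2-only bait, or
#' `"input"` lysate) and biological replicate index in `colData`. Build one
#' from a long count table with [MitrapExperiment()]; add tpm with
#' [countsToTpm()] and compute target-vs-control enrichment with
#' [computeEnrichment()].
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @name MitrapExperiment-class
#' @export
setClass("MitrapExperiment", contains = "SummarizedExperiment")

setValidity("MitrapExperiment", function(object) {
  msg <- character()
  cd <- colData(object)
  if (!all(c("sample_id", "bait", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must contain sample_id, bait and replicate")
  else if (!all(cd$bait %in% BAITS))
    msg <- c(msg, sprintf("bait must be one of: %s",
                          paste(BAITS, collapse = ", ")))
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "a 'counts' assay is required")
  else {
    cnt <- assay(object, "counts")
    if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' VoteMatrix: per-tool binding predictions and consensus votes
#'
#' A logical miR-by-tool matrix recording, for each miR, whether each
#' target-prediction tool predicts a binding site in the bait 3'UTR.
#' Missing (miR, tool) pairs default to `FALSE` ("not predicted"). The
#' per-miR vote count is the number of `TRUE` entries in its row.
#'
#' @slot predictions logical matrix, rows miRs, columns tools.
#' @seealso [loadToolPredictions()], [countVotes()], [filterByVotes()]
#' @name VoteMatrix-class
#' @export
setClass("VoteMatrix", representation(predictions = "matrix"))

setValidity("VoteMatrix", function(object) {
  p <- object@predictions
  msg <- character()
  if (!is.logical(p)) msg <- c(msg, "predictions must be a logical matrix")
  if (is.null(rownames(p)) || is.null(colnames(p)))
    msg <- c(msg, "predictions must have miR rownames and tool colnames")
  else {
    if (anyDuplicated(rownames(p))) msg <- c(msg, "duplicate miR ids")
    if (anyDuplicated(colnames(p))) msg <- c(msg, "duplicate tool names")
  }
  if (anyNA(p)) msg <- c(msg, "predictions must not contain NA")
  if (length(msg)) msg else TRUE
})

#' DuplexStructure: an intermolecular miR:target RNA duplex
#'
#' Result of the nearest-neighbor minimum-free-energy dynamic program
#' ([duplexMFE()]). Pairings are strictly monotone (miR 5'->3' against
#' target 3'->5'; no crossing, no intramolecular pairs) and each position
#' is used at most once. When no negative-energy structure exists the
#' object carries zero pairs and `deltaG` 0 ("no stable duplex").
#'
#' @slot mirSeq,targetSeq the (normalized, RNA-alphabet) input sequences.
#' @slot pairs integer matrix with columns `mir`, `target`: 0-based paired
#'   positions.
#' @slot deltaG free energy in kcal/mol (includes duplex initiation).
#' @slot structure character rendering of the duplex alignment.
#' @name DuplexStructure-class
#' @export
setClass("DuplexStructure",
         representation(mirSeq = "character", targetSeq = "character",
                        pairs = "matrix", deltaG = "numeric",
                        structure = "character"))

setValidity("DuplexStructure", function(object) {
  p <- object@pairs
  msg <- character()
  if (nrow(p)) {
    if (!identical(colnames(p), c("mir", "target")))
      msg <- c(msg, "pairs must have columns mir, target")
    else {
      if (anyDuplicated(p[, "mir"]) || anyDuplicated(p[, "target"]))
        msg <- c(msg, "each position may pair at most once")
      if (nrow(p) > 1L) {
        dm <- diff(p[, "mir"]); dt <- diff(p[, "target"])
        # antiparallel: increasing along the miR, decreasing along target
        if (any(dm <= 0) || any(dt >= 0))
          msg <- c(msg, "pairings must be strictly monotone (non-crossing)")
      }
    }
  }
  if (length(object@deltaG) != 1L) msg <- c(msg, "deltaG must be scalar")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: study conditions for the synthetic miTRAP data set
#'
#' Holds the parameters of the synthetic-data generator. Defaults mirror
#' the analysed study: a miRBase-scale universe of 2693 miRs, two
#' biological replicates per bait, one million reads per library, a small
#' planted enriched subset whose target-bait abundance is multiplied by a
#' factor > 50, and qPCR fold changes of 700 and 50 for the two leading
#' planted miRs.
#'
#' @slot nMirs miR universe size (default 2693).
#' @slot nEnriched number of planted enriched miRs (default 5).
#' @slot depthPerSample reads per library (default 1e6).
#' @slot plantedRatioRange interval of tpm-ratio multipliers, lower bound
#'   > 1 (default c(100, 200)).
#' @slot nReplicates biological replicates per bait (default 2).
#' @slot utrLength synthetic bait 3'UTR length in nt (default 600).
#' @slot nPlantedSites number of planted binding sites (default 2).
#' @slot plantedFoldChanges named numeric: qPCR fold enrichment per planted
#'   miR; empty means the defaults 700, 50, then 100 are assigned in order.
#' @slot ctNoiseSd Gaussian Ct noise sd in cycles (default 0.2).
#' @slot nPatients patient cohort size, even (default 20).
#' @slot patientMirEffect log2 difference in miR expression, TAP1-low minus
#'   TAP1-high group (default 2).
#' @slot patientCd8Effect difference in mean CD8+ counts per HPF,
#'   TAP1-high minus TAP1-low group (default 40).
#' @slot rngSeed integer seed making every generator deterministic.
#' @seealso [simulationConfig()]
#' @name SimulationConfig-class
#' @export
setClass("SimulationConfig",
         representation(nMirs = "integer", nEnriched = "integer",
                        depthPerSample = "numeric",
                        plantedRatioRange = "numeric",
                        nReplicates = "integer", utrLength = "integer",
                        nPlantedSites = "integer",
                        plantedFoldChanges = "numeric",
                        ctNoiseSd = "numeric", nPatients = "integer",
                        patientMirEffect = "numeric",
                        patientCd8Effect = "numeric", rngSeed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nEnriched > object@nMirs)
    msg <- c(msg, "nEnriched must not exceed nMirs")
  if (object@depthPerSample <= 0)
    msg <- c(msg, "depthPerSample must be positive")
  if (length(object@plantedRatioRange) != 2L ||
      object@plantedRatioRange[1] <= 1 ||
      diff(object@plantedRatioRange) < 0)
    msg <- c(msg, "plantedRatioRange must be an interval with lower bound > 1")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (object@utrLength < 30L * object@nPlantedSites)
    msg <- c(msg, "utrLength must be at least 30 x nPlantedSites")
  if (any(object@plantedFoldChanges <= 0))
    msg <- c(msg, "planted fold changes must be positive")
  if (object@ctNoiseSd < 0) msg <- c(msg, "ctNoiseSd must be >= 0")
  if (object@nPatients %% 2L != 0L)
    msg <- c(msg, "nPatients must be even (balanced TAP1 groups)")
  if (length(msg)) msg else TRUE
})

#' PlantedTruth: ground truth planted by the synthetic generator
#'
#' Records what the generator planted so recovery tests can compare
#' pipeline output against truth: the enriched miR set, the expected
#' target/control tpm ratios (computed from the actual multinomial
#' abundance vectors, i.e. after renormalization), the qPCR fold changes,
#' and the binding-site coordinates on the synthetic UTR (0-based,
#' half-open, with the seed-match start).
#'
#' @slot enrichedMirs character.
#' @slot expectedRatios named numeric.
#' @slot plantedFolds named numeric.
#' @slot siteCoords data.frame with columns `mir_id`, `start`, `end`,
#'   `seed_start`.
#' @name PlantedTruth-class
#' @export
setClass("PlantedTruth",
         representation(enrichedMirs = "character",
                        expectedRatios = "numeric",
                        plantedFolds = "numeric",
                        siteCoords = "data.frame"))

setValidity("PlantedTruth", function(object) {
  msg <- character()
  sc <- object@siteCoords
  if (nrow(sc)) {
    if (!all(c("mir_id", "start", "end", "seed_start") %in% colnames(sc)))
      msg <- c(msg, "siteCoords needs mir_id, start, end, seed_start")
    else if (any(sc$start < 0) || any(sc$end <= sc$start))
      msg <- c(msg, "siteCoords intervals must be non-empty and 0-based")
  }
  if (length(msg)) msg else TRUE
})
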