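#' @include AllClasses.R
NULL

#' Convert raw counts to transcripts per million
#'
#' Per-sample normalization of miR counts to a fixed total of 10^6. No
#' length scaling is applied: mature miRs are near-uniform in length
#' (~22 nt), so the values are counts-per-million over the miR fraction,
#' reported on the conventional tpm scale.
#'
#' @param x a long-format count `data.frame` (see [aggregateLoci()]) or a
#'   [MitrapExperiment-class] object.
#' @param ... passed to methods.
#' @return For a `data.frame`, a tpm table with columns `mir_id`,
#'   `sample_id`, `bait`, `replicate`, `tpm`; for a `MitrapExperiment`,
#'   the object with a `"tpm"` assay added.
#' @examples
#' counts <- data.frame(
#'   mir_id = c("miR-a", "miR-b"), locus_id = c("L1", "L1"),
#'   sample_id = "s1", bait = "target", replicate = 1L, count = c(1L, 3L))
#' countsToTpm(counts)$tpm  # 250000, 750000
#' @export
setGeneric("countsToTpm", function(x, ...) standardGeneric("countsToTpm"))

#' Per-miR enrichment of the target-bait eluate over the control bait
#'
#' @param x a [MitrapExperiment-class] or a tpm `data.frame`.
#' @param ... passed to methods; see [computeEnrichment,MitrapExperiment-method].
#' @export
setGeneric("computeEnrichment",
           function(x, ...) standardGeneric("computeEnrichment"))

#' Count prediction-tool votes per miR
#'
#' @param object a [VoteMatrix-class].
#' @param mir optional miR identifier(s); unknown ids are an error. When
#'   missing, votes for every miR are returned.
#' @return named integer vector of vote counts.
#' @export
setGeneric("countVotes", function(object, mir) standardGeneric("countVotes"))

#' Select miRs predicted by at least `minTools` tools
#'
#' @param object a [VoteMatrix-class].
#' @param minTools integer threshold, between 0 and the number of tools.
#' @return character vector of miR ids with vote count >= `minTools`.
#' @export
setGeneric("filterByVotes",
           function(object, minTools) standardGeneric("filterByVotes"))

#' Accessors for duplex structures
#'
#' `deltaG` returns the free energy (kcal/mol) of a predicted duplex;
#' `pairedBases` the 0-based (miR position, target position) pair matrix;
#' `isStable` whether a negative-energy structure exists.
#'
#' @param object a [DuplexStructure-class].
#' @export
setGeneric("deltaG", function(object) standardGeneric("deltaG"))

#' @rdname deltaG
#' @export
setGeneric("pairedBases", function(object) standardGeneric("pairedBases"))

#' @rdname deltaG
#' @export
setGeneric("isStable", function(object) standardGeneric("isStable"))

#' Accessors for planted simulation truth
#'
#' @param object a [PlantedTruth-class].
#' @export
setGeneric("enrichedMirs", function(object) standardGeneric("enrichedMirs"))

#' @rdname enrichedMirs
#' @export
setGeneric("plantedFolds", function(object) standardGeneric("plantedFolds"))

#' @rdname enrichedMirs
#' @export
setGeneric("expectedRatios",
           function(object) standardGeneric("expectedRatios"))

#' @rdname enrichedMirs
#' @export
setGeneric("siteCoords", function(object) standardGeneric("siteCoords"))
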