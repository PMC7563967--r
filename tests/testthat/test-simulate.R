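# small configs keep the suite fast; the full-scale conditions are
# exercised in the acceptance tests
smallCfg <- function(...) {
  args <- utils::modifyList(
    list(nMirs = 300L, nEnriched = 4L, depthPerSample = 2e5,
         utrLength = 300L, nPlantedSites = 2L, rngSeed = 101L),
    list(...))
  do.call(simulationConfig, args)
}

test_that("generators are deterministic under a fixed seed", {
  cfg <- smallCfg()
  expect_identical(simulateMitrapCounts(cfg), simulateMitrapCounts(cfg))
  expect_identical(simulateSequences(cfg), simulateSequences(cfg))
  tr <- simulateSequences(cfg)$truth
  expect_identical(simulateQpcr(tr, cfg), simulateQpcr(tr, cfg))
  expect_identical(simulatePatients(cfg), simulatePatients(cfg))
  # a different seed changes the draw
  cfg2 <- smallCfg(rngSeed = 102L)
  expect_false(identical(simulateMitrapCounts(cfg)$counts,
                         simulateMitrapCounts(cfg2)$counts))
})

test_that("each simulated library sums exactly to the configured depth", {
  cfg <- smallCfg()
  sim <- simulateMitrapCounts(cfg)
  totals <- tapply(sim$counts$count, sim$counts$sample_id, sum)
  expect_equal(as.numeric(totals), rep(2e5, 6))
  # and tpm of every sample sums to one million after quantification
  tpm <- countsToTpm(sim$counts)
  expect_equal(as.numeric(tapply(tpm$tpm, tpm$sample_id, sum)),
               rep(1e6, 6), tolerance = 1e-9)
})

test_that("without planting, ratios scatter around 1", {
  cfg <- smallCfg(nEnriched = 0L)
  sim <- simulateMitrapCounts(cfg)
  expect_length(enrichedMirs(sim$truth), 0)
  enr <- computeEnrichment(countsToTpm(MitrapExperiment(sim$counts)))
  expect_lt(abs(median(log2(enr$ratio))), 0.2)
  expect_gt(mean(enr$ratio > 0.5 & enr$ratio < 2), 0.95)
})

test_that("planted miRs realize their expected tpm ratios within 30%", {
  cfg <- simulationConfig(nMirs = 2693L, nEnriched = 5L,
                          depthPerSample = 1e6,
                          plantedRatioRange = c(100, 100), rngSeed = 103L)
  sim <- simulateMitrapCounts(cfg)
  enr <- computeEnrichment(countsToTpm(MitrapExperiment(sim$counts)))
  exp_ <- expectedRatios(sim$truth)
  for (m in names(exp_)) {
    realized <- enr$ratio[enr$mir_id == m]
    expect_lt(abs(realized / exp_[m] - 1), 0.3)
  }
  # every planted miR is flagged enriched
  expect_true(all(enr$enriched[match(names(exp_), enr$mir_id)]))
})

test_that("misconfigured simulations are rejected", {
  expect_error(simulationConfig(nMirs = 10L, nEnriched = 11L),
               "nEnriched")
  expect_error(simulationConfig(depthPerSample = 0), "positive")
  expect_error(simulationConfig(plantedRatioRange = c(0.5, 2)),
               "lower bound")
  expect_error(simulationConfig(nPatients = 7L), "even")
  expect_error(simulationConfig(utrLength = 20L, nPlantedSites = 2L),
               "30 x nPlantedSites")
})

test_that("planted UTR sites carry the seed complement; background is clean", {
  cfg <- smallCfg()
  seqs <- simulateSequences(cfg)
  sc <- siteCoords(seqs$truth)
  expect_equal(nrow(sc), 2)
  for (i in seq_len(nrow(sc))) {
    mir <- seqs$mirs[[sc$mir_id[i]]]
    # the planted interval contains the reverse complement of the seed
    seedRc <- rcOracle(substr(mir, 2, 7))
    expect_equal(substr(seqs$utr, sc$seed_start[i] + 1,
                        sc$seed_start[i] + 6), seedRc)
    # interval lies within the UTR
    expect_gte(sc$start[i], 0)
    expect_lte(sc$end[i], nchar(seqs$utr))
    # the seed scan finds exactly the planted positions
    expect_setequal(seedMatches(mir, seqs$utr),
                    sc$seed_start[sc$mir_id == sc$mir_id[i]])
  }
  # decoy miRs have no seed matches anywhere
  for (m in grep("^bg-", names(seqs$mirs), value = TRUE))
    expect_length(seedMatches(seqs$mirs[[m]], seqs$utr), 0)
})

test_that("no planted sites means no seed matches for planted miRs", {
  cfg <- smallCfg(nPlantedSites = 0L)
  seqs <- simulateSequences(cfg)
  expect_equal(nrow(siteCoords(seqs$truth)), 0)
  for (m in enrichedMirs(seqs$truth))
    expect_length(seedMatches(seqs$mirs[[m]], seqs$utr), 0)
})

test_that("patient cohorts are balanced with configurable effects", {
  cfg <- smallCfg(nPatients = 20L)
  pat <- simulatePatients(cfg)
  expect_equal(unname(table(pat$tap1_group)), c(10L, 10L),
               ignore_attr = TRUE)
  expect_true(all(pat$tap1_frequency[pat$tap1_group == "high"] > 30))
  expect_true(all(pat$tap1_frequency[pat$tap1_group == "low"] <= 10))
  expect_true(all(pat$cd8_per_hpf >= 0))

  # zero effect: group means equal in expectation (log2 scale)
  cfg0 <- smallCfg(nPatients = 2000L, patientMirEffect = 0,
                   patientCd8Effect = 0)
  p0 <- simulatePatients(cfg0)
  d <- mean(log2(p0$mir_rel_expr[p0$tap1_group == "low"])) -
    mean(log2(p0$mir_rel_expr[p0$tap1_group == "high"]))
  expect_lt(abs(d), 0.1)

  # strong planted effect is detected
  cfgS <- smallCfg(nPatients = 20L, patientMirEffect = 3)
  pS <- simulatePatients(cfgS, mirNoiseSd = 0.3)
  expect_lt(mirVsTap1Groups(pS)$test$p_value, 0.05)
})

test_that("all synthetic inputs write to plain-text files", {
  cfg <- smallCfg()
  outdir <- tempfile("sim")
  writeSimulatedInputs(cfg, outdir)
  expect_true(all(file.exists(file.path(
    outdir, c("counts.tsv", "mirs.fasta", "utr.fasta", "qpcr.tsv",
              "patients.tsv", "truth.json")))))
  back <- readCountTable(file.path(outdir, "counts.tsv"))
  expect_equal(nrow(back), nrow(simulateMitrapCounts(cfg)$counts))
})
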