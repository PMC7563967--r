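test_that("replicate combination is a pseudocounted geometric mean", {
  expect_equal(aggregateReplicates(100, pseudocount = 0.5), 100.5)
  expect_equal(aggregateReplicates(c(100, 400), pseudocount = 0), 200)
  expect_error(aggregateReplicates(numeric(0)), "no replicate")
  expect_error(aggregateReplicates(c(0, 10), pseudocount = 0),
               "undefined")
  # order invariance
  set.seed(1)
  for (i in 1:10) {
    v <- runif(4, 0, 1000)
    expect_equal(aggregateReplicates(v), aggregateReplicates(rev(v)))
  }
})

test_that("enrichment ratio follows the pseudocounted quotient", {
  expect_equal(enrichmentRatio(100, 100, pseudocount = 0), 1.0)
  expect_equal(enrichmentRatio(9210, 100, pseudocount = 0), 92.1)
  expect_error(enrichmentRatio(0, 0, pseudocount = 0), "undefined")
  set.seed(2)
  for (i in 1:10) {
    a <- runif(1, 1, 1e4); b <- runif(1, 1, 1e4)
    expect_equal(enrichmentRatio(a, b, 0) * enrichmentRatio(b, a, 0), 1)
    # monotone in target, antitone in control
    expect_gt(enrichmentRatio(a * 2, b), enrichmentRatio(a, b))
    expect_lt(enrichmentRatio(a, b * 2), enrichmentRatio(a, b))
    # pseudocount -> 0 recovers the naive quotient
    expect_equal(enrichmentRatio(a, b, 1e-12), a / b, tolerance = 1e-9)
  }
})

test_that("the enriched flag requires a strictly greater ratio", {
  rec <- data.frame(mir_id = c("a", "b", "c"), ratio = c(0.9, 1.0, 1.1))
  expect_equal(flagEnriched(rec)$mir_id, "c")
})

test_that("enrichment records combine replicates and flag zero-control miRs", {
  counts <- rbind(
    makeCounts(list(target_rep1 = c(mA = 900L, mB = 50L, mC = 50L)),
               baits = "target", replicates = 1L),
    makeCounts(list(target_rep2 = c(mA = 800L, mB = 100L, mC = 100L)),
               baits = "target", replicates = 2L),
    makeCounts(list(control_rep1 = c(mA = 10L, mB = 490L, mC = 500L)),
               baits = "control", replicates = 1L),
    makeCounts(list(control_rep2 = c(mA = 10L, mB = 480L, mC = 510L)),
               baits = "control", replicates = 2L))
  mexp <- countsToTpm(MitrapExperiment(counts))
  enr <- computeEnrichment(mexp, pseudocount = 0.01)
  expect_setequal(enr$mir_id, c("mA", "mB", "mC"))
  a <- enr[enr$mir_id == "mA", ]
  expect_true(a$enriched)
  expect_gt(a$ratio, 50)
  # combined tpm is the geometric mean of pseudocounted replicate tpm
  expect_equal(a$tpm_target,
               sqrt((9e5 + 0.01) * (8e5 + 0.01)), tolerance = 1e-9)
  expect_false(any(enr$pseudo_flag))

  # zero-control miR gets flagged, not dropped
  counts0 <- rbind(counts[counts$mir_id != "mA" | counts$bait != "control", ],
                   makeCounts(list(control_rep1 = c(mA = 0L)),
                              baits = "control", replicates = 1L),
                   makeCounts(list(control_rep2 = c(mA = 0L)),
                              baits = "control", replicates = 2L))
  enr0 <- computeEnrichment(countsToTpm(MitrapExperiment(counts0)))
  expect_true(enr0$pseudo_flag[enr0$mir_id == "mA"])
})

test_that("strict mode requires enrichment in every replicate pair", {
  counts <- rbind(
    makeCounts(list(target_rep1 = c(mA = 100L, mB = 100L)),
               baits = "target", replicates = 1L),
    makeCounts(list(target_rep2 = c(mA = 150L, mB = 50L)),
               baits = "target", replicates = 2L),
    makeCounts(list(control_rep1 = c(mA = 50L, mB = 150L)),
               baits = "control", replicates = 1L),
    makeCounts(list(control_rep2 = c(mA = 50L, mB = 150L)),
               baits = "control", replicates = 2L))
  mexp <- countsToTpm(MitrapExperiment(counts))
  lax <- computeEnrichment(mexp)
  strict <- computeEnrichment(mexp, strict = TRUE)
  expect_true(lax$enriched[lax$mir_id == "mA"])
  expect_true(strict$enriched[strict$mir_id == "mA"])
  expect_false(strict$enriched[strict$mir_id == "mB"])
})

test_that("enrichment summary reports half-up percentages per vote count", {
  # composition: 4 of 10 miRs enriched, votes 0,0,1,5 among the enriched
  rec <- data.frame(mir_id = sprintf("m%02d", 1:10),
                    ratio = c(rep(0.5, 6), rep(10, 4)))
  votes <- setNames(rep(0L, 10), rec$mir_id)
  votes[c("m09", "m10")] <- c(1L, 5L)
  s <- summarizeEnrichment(rec, votes)
  expect_equal(s$n_enriched, 4)
  expect_equal(s$pct_enriched, 40)
  expect_equal(s$breakdown$n[s$breakdown$votes == 0], 2)
  expect_equal(s$breakdown$pct[s$breakdown$votes == 0], 50)
  expect_equal(s$breakdown$pct[s$breakdown$votes == 1], 25)
  expect_equal(sum(s$breakdown$n), s$n_enriched)

  # no enrichment: zero percentage and an empty breakdown
  none <- data.frame(mir_id = c("a", "b"), ratio = c(0.5, 1.0))
  s0 <- summarizeEnrichment(none, setNames(c(1L, 2L), c("a", "b")))
  expect_equal(s0$pct_enriched, 0)
  expect_equal(nrow(s0$breakdown), 0)
})

test_that("breakdown percentages sum to 100 within rounding slack", {
  set.seed(3)
  for (i in 1:5) {
    n <- 200
    rec <- data.frame(mir_id = sprintf("m%03d", 1:n),
                      ratio = runif(n, 0, 10))
    votes <- setNames(sample(0:6, n, replace = TRUE), rec$mir_id)
    s <- summarizeEnrichment(rec, votes)
    if (s$n_enriched > 0)
      expect_lt(abs(sum(s$breakdown$pct) - 100), 0.035)
  }
})

test_that("percentage rounding is half-up to two decimals", {
  expect_equal(miTRAPseq:::roundHalfUp(100 * 175 / 352), 49.72)
  expect_equal(miTRAPseq:::roundHalfUp(100 * 7 / 352), 1.99)
  expect_equal(miTRAPseq:::roundHalfUp(0.125), 0.13)  # exact binary half
})
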