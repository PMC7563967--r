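test_that("dual-luciferase normalization maps the control to 1", {
  rec <- data.frame(
    condition = rep(c("NC", "mimic"), each = 3),
    ffl = c(100, 110, 90, 40, 50, 60),
    rl = c(200, 220, 180, 200, 250, 300))
  out <- rluNormalize(rec, "NC")
  expect_equal(out$rlu_norm[out$condition == "NC"], 1.0)
  expect_lt(out$rlu_norm[out$condition == "mimic"], 1.0)
  # per-well rlu is FFL/RL
  expect_equal(rluNormalize(data.frame(condition = "NC", ffl = 50,
                                       rl = 100), "NC")$mean_rlu, 0.5)
  # doubling every FFL leaves normalized values unchanged
  rec2 <- rec; rec2$ffl <- rec2$ffl * 2
  expect_equal(rluNormalize(rec2, "NC")$rlu_norm, out$rlu_norm)
  expect_error(rluNormalize(rec, "empty vector"), "not present")
  expect_error(rluNormalize(transform(rec, rl = 0), "NC"), "positive")
})

test_that("relative band density normalizes to loading and parental lane", {
  expect_equal(relativeDensity(10, 5, 10, 5), 1.0)
  expect_equal(relativeDensity(5, 5, 10, 5), 0.5)
  # jointly rescaling both lanes' loading controls cancels out
  expect_equal(relativeDensity(8, 4 * 3, 10, 5 * 3),
               relativeDensity(8, 4, 10, 5))
  expect_error(relativeDensity(8, 0, 10, 5), "positive")
})

test_that("specific degranulation subtracts spontaneous and floors at zero", {
  out <- specificDegranulation(12, 2, 10)
  expect_equal(out$specific, 10)
  expect_equal(out$x_fold, 1.0)
  expect_equal(specificDegranulation(3, 5, 10)$specific, 0)
  expect_warning(out0 <- specificDegranulation(12, 2, 0), "undefined")
  expect_true(is.na(out0$x_fold))
  expect_error(specificDegranulation(120, 2, 10), "\\[0, 100\\]")
  # a mimic impairing degranulation gives a fold below 1
  nc <- specificDegranulation(12, 2, 10)
  mimic <- specificDegranulation(6, 2, nc$specific)
  expect_lt(mimic$x_fold, 1)
})

test_that("IHC grading partitions [0, 100] into the four categories", {
  out <- ihcCategory(c(0, 7, 35))
  expect_equal(as.character(out$category), c("0%", "1-10%", ">30%"))
  expect_equal(as.character(out$group), c("low", "low", "high"))
  # boundary values fall in the lower bracket
  b <- ihcCategory(c(10, 10.5, 30, 30.5))
  expect_equal(as.character(b$category),
               c("1-10%", "11-30%", "11-30%", ">30%"))
  expect_equal(as.character(b$group),
               c("low", "intermediate", "intermediate", "high"))
  # no gaps or overlaps on a dense grid
  grid <- seq(0, 100, by = 0.25)
  g <- ihcCategory(grid)
  expect_false(anyNA(g$category))
  expect_false(anyNA(g$group))
  expect_error(ihcCategory(101), "\\[0, 100\\]")
  expect_error(ihcCategory(-1), "\\[0, 100\\]")
})

test_that("group comparison matches the closed-form Welch t statistic", {
  a <- c(1, 2, 3); b <- c(1, 2, 3)
  same <- groupCompare(a, b)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  a <- c(4, 6); b <- c(1, 3)
  out <- groupCompare(a, b)
  tHand <- (mean(a) - mean(b)) / sqrt(var(a) / 2 + var(b) / 2)
  expect_equal(out$statistic, tHand)

  paired <- groupCompare(c(5, 7, 10), c(4, 6, 8), paired = TRUE)
  d <- c(1, 1, 2)
  expect_equal(paired$statistic, mean(d) / (sd(d) / sqrt(3)))
  expect_error(groupCompare(1, c(1, 2)), "at least 2")
  expect_error(groupCompare(c(1, 2, 3), c(1, 2), paired = TRUE),
               "equal group sizes")
  w <- groupCompare(c(1, 2, 3, 4), c(2, 3, 4, 5), method = "wilcoxon")
  expect_true(w$p_value > 0 && w$p_value <= 1)
})

test_that("TAP1-high vs TAP1-low comparison recovers a planted inverse association", {
  cfg <- simulationConfig(nPatients = 20L, patientMirEffect = 3,
                          rngSeed = 11L)
  patients <- simulatePatients(cfg, mirNoiseSd = 0.3)
  out <- mirVsTap1Groups(patients)
  expect_gt(out$group_means["low"], out$group_means["high"])
  expect_lt(out$test$p_value, 0.05)
  expect_equal(nrow(out$overview), 20)
  # groups derived from frequencies when labels are absent
  p2 <- patients[, setdiff(colnames(patients), "tap1_group")]
  out2 <- mirVsTap1Groups(p2)
  expect_equal(out2$test$p_value, out$test$p_value)
  expect_error(mirVsTap1Groups(patients[patients$tap1_group == "low", ]),
               "non-empty")
})

test_that("intermediate TAP1 lesions are excluded from the comparison", {
  pat <- data.frame(patient_id = sprintf("p%d", 1:6),
                    tap1_group = c("high", "high", "low", "low",
                                   "intermediate", "intermediate"),
                    cd8_per_hpf = c(50, 60, 20, 10, 30, 40),
                    mir_rel_expr = c(1, 1.2, 4, 5, 100, 100))
  out <- mirVsTap1Groups(pat)
  expect_equal(nrow(out$overview), 4)
  expect_false(any(out$overview$tap1_group == "intermediate"))
})
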