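table2Report <- function(criteria, thresholds = selectionThresholds()) {
  t2 <- readTable2()
  applyCriteria(data.frame(mir_id = t2$mir_id, ratio = t2$ratio),
                votes = table2VoteMatrix(t2),
                energies = setNames(t2$energy, t2$mir_id),
                thresholds = thresholds, criteria = criteria)
}

test_that("vote + ratio criteria retain exactly the six published passers", {
  rep <- table2Report(c("votes", "ratio"))
  expect_setequal(rep$mir_id[rep$pass],
                  c("hsa-miR-21-3p", "hsa-miR-22-3p", "hsa-miR-26a-5p",
                    "hsa-miR-26b-5p", "hsa-miR-532-5p", "hsa-miR-590-3p"))
  # report is lossless and annotates non-passers
  expect_equal(nrow(rep), 21)
  expect_equal(anyDuplicated(rep$mir_id), 0)
  # unevaluated criteria are not-applicable, not failed
  expect_true(all(is.na(rep$pass_ii)))
  expect_true(all(is.na(rep$pass_v)))
})

test_that("the binding-energy criterion removes the weak-energy candidate", {
  rep <- table2Report(c("votes", "ratio", "energy"))
  expect_setequal(rep$mir_id[rep$pass],
                  c("hsa-miR-21-3p", "hsa-miR-22-3p", "hsa-miR-26a-5p",
                    "hsa-miR-26b-5p", "hsa-miR-532-5p"))
  expect_false(rep$pass[rep$mir_id == "hsa-miR-590-3p"])
  expect_false(rep$pass_v[rep$mir_id == "hsa-miR-590-3p"])  # -12.8
  expect_true(rep$pass_v[rep$mir_id == "hsa-miR-21-3p"])    # -20.3
})

test_that("candidates rank by ratio, then energy, then id", {
  rep <- table2Report(c("votes", "ratio", "energy"))
  rk <- rankCandidates(rep)
  expect_equal(rk$mir_id[1], "hsa-miR-21-3p")
  expect_equal(rk$ratio[1], 1036.0)
  expect_equal(rk$rank, seq_len(nrow(rk)))
  # permuting input rows leaves the ranking unchanged
  set.seed(41)
  perm <- rep[sample(nrow(rep)), ]
  expect_equal(rankCandidates(perm)$mir_id, rk$mir_id)
  # single passer gets rank 1
  one <- rep[rep$mir_id == "hsa-miR-21-3p", ]
  expect_equal(rankCandidates(one)$rank, 1L)
})

test_that("empty input yields an empty report", {
  rep <- applyCriteria(data.frame(mir_id = character(0),
                                  ratio = numeric(0)))
  expect_equal(nrow(rep), 0)
  expect_equal(nrow(rankCandidates(rep)), 0)
})

test_that("the audit narrates every failed criterion with observed values", {
  rep <- table2Report(c("votes", "ratio"))
  audit <- selectionAudit(rep)
  expect_equal(nrow(audit), nrow(rep))
  a140 <- audit$audit[audit$mir_id == "hsa-miR-140-3p"]
  expect_match(a140, "1\\.3")
  expect_match(a140, "50")
  passers <- audit[audit$mir_id %in% rep$mir_id[rep$pass], ]
  expect_true(all(passers$n_failed == 0))
  expect_true(all(grepl("no failed criteria", passers$audit)))
})

test_that("tightening any threshold never enlarges the passer set", {
  set.seed(42)
  n <- 60
  rec <- data.frame(mir_id = sprintf("m%02d", 1:n),
                    tpm_target = runif(n, 0, 5000),
                    tpm_control = runif(n, 0, 300),
                    ratio = runif(n, 0, 200))
  votes <- setNames(sample(0:6, n, replace = TRUE), rec$mir_id)
  energies <- setNames(runif(n, -30, -5), rec$mir_id)
  base <- selectionThresholds()
  passers <- function(th)
    with(applyCriteria(rec, votes, energies, thresholds = th),
         mir_id[pass])
  p0 <- passers(base)
  tighter <- list(
    selectionThresholds(minTools = 5),
    selectionThresholds(minTpmTarget = 2000),
    selectionThresholds(maxTpmControl = 50),
    selectionThresholds(minRatio = 100),
    selectionThresholds(maxEnergy = -25))
  for (th in tighter)
    expect_true(all(passers(th) %in% p0))
})

test_that("threshold invariants are enforced", {
  expect_error(selectionThresholds(minRatio = 1), "> 1")
  expect_error(selectionThresholds(maxEnergy = 0.5), "negative")
  expect_error(selectionThresholds(mitrapFactor = 0), "positive")
})

test_that("the miTRAP-ratio criterion compares target and control folds", {
  rec <- data.frame(mir_id = c("a", "b"), ratio = c(100, 100))
  mit <- data.frame(mir_id = c("a", "b"),
                    fold_target = c(700, 30),
                    fold_control = c(10, 20))
  rep <- applyCriteria(rec, mitrap = mit, criteria = c("ratio", "mitrap"))
  expect_true(rep$pass_vi[rep$mir_id == "a"])   # 700 > 2 x 10
  expect_false(rep$pass_vi[rep$mir_id == "b"])  # 30 <= 2 x 20
})
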