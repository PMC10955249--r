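test_that("parseInterVarEvidence reads InterVar's printed evidence layout", {
  cell <- paste0("InterVar: Uncertain significance PVS1=1 PS=[0, 0, 0, 0, 0] ",
                 "PM=[0, 1, 0, 0, 0, 0, 0] PP=[0, 0, 0, 0, 0, 0] BA1=0 ",
                 "BS=[0, 0, 0, 0, 0] BP=[0, 0, 0, 0, 0, 0, 0, 0]")
  p <- parseInterVarEvidence(cell)
  expect_equal(p$call, "Uncertain significance")
  expect_equal(pvs1Strength(p$criteria), "VeryStrong")
  expect_equal(criteriaNames(p$criteria), "PM2")

  cell2 <- paste0("InterVar: Pathogenic PVS1=1 PS=[1, 0, 0, 0, 0] ",
                  "PM=[0, 0, 0, 0, 0, 0, 0] PP=[0, 0, 0, 0, 1, 0] BA1=0 ",
                  "BS=[0, 0, 0, 0, 0] BP=[0, 0, 0, 0, 0, 0, 0, 0]")
  p2 <- parseInterVarEvidence(cell2)
  expect_equal(p2$call, "Pathogenic")
  expect_setequal(criteriaNames(p2$criteria), c("PS1", "PP5"))

  cell3 <- paste0("InterVar: Benign PVS1=0 PS=[0, 0, 0, 0, 0] ",
                  "PM=[0, 0, 0, 0, 0, 0, 0] PP=[0, 0, 0, 0, 0, 0] BA1=1 ",
                  "BS=[0, 0, 0, 0, 0] BP=[0, 0, 0, 0, 0, 0, 0, 0]")
  p3 <- parseInterVarEvidence(cell3)
  expect_equal(criteriaNames(p3$criteria), "BA1")
  expect_equal(pvs1Strength(p3$criteria), "Unmet")

  expect_error(parseInterVarEvidence("not an evidence cell"), "layout")
})

test_that("parseInterVarEvidence round-trips the serialized layout", {
  set.seed(31)
  for (i in 1:50) {
    cv <- randomCriteriaVector(0.3)
    # InterVar itself only emits PVS1 as set/unset
    pvs1Strength(cv) <- sample(c("VeryStrong", "Unmet"), 1)
    cell <- gvclass:::.formatInterVarEvidence("Uncertain significance", cv)
    p <- parseInterVarEvidence(cell)
    expect_equal(criteriaNames(p$criteria), criteriaNames(cv))
    expect_equal(pvs1Strength(p$criteria), pvs1Strength(cv))
  }
})

test_that("stripPP5BP6 clears exactly PP5 and BP6 and is idempotent", {
  cv <- criteriaVector(c("PP5"))
  expect_equal(criteriaNames(stripPP5BP6(cv)), character())

  cv <- criteriaVector(c("BP6", "BP4"))
  expect_equal(criteriaNames(stripPP5BP6(cv)), "BP4")

  cv <- criteriaVector(c("PS1", "PM2", "BP4"), pvs1 = "VeryStrong")
  expect_identical(criteriaNames(stripPP5BP6(cv)), criteriaNames(cv))
  expect_identical(stripPP5BP6(stripPP5BP6(cv)), stripPP5BP6(cv))
})

test_that("applyPVS1Strength demotes but never upgrades", {
  cv <- criteriaVector("PM2", pvs1 = "VeryStrong")
  expect_equal(pvs1Strength(applyPVS1Strength(cv, "Moderate")), "Moderate")
  expect_equal(pvs1Strength(applyPVS1Strength(cv, "Unmet")), "Unmet")

  # no grading available: strength kept, loudly
  expect_warning(out <- applyPVS1Strength(cv, NULL), "no graded PVS1")
  expect_equal(pvs1Strength(out), "VeryStrong")

  # InterVar did not flag PVS1: grading never introduces it
  cv0 <- criteriaVector("PS1", pvs1 = "Unmet")
  expect_equal(pvs1Strength(applyPVS1Strength(cv0, "Strong")), "Unmet")
  expect_error(applyPVS1Strength(cv, "Huge"), "unknown PVS1 strength")
})

test_that("stripPP5BP6 and applyPVS1Strength commute", {
  set.seed(41)
  for (i in 1:100) {
    cv <- randomCriteriaVector(0.3)
    pvs1Strength(cv) <- sample(c("VeryStrong", "Unmet"), 1)
    s <- sample(strengthLevels(), 1)
    a <- suppressWarnings(applyPVS1Strength(stripPP5BP6(cv), s))
    b <- suppressWarnings(stripPP5BP6(applyPVS1Strength(cv, s)))
    expect_identical(a, b)
  }
})

test_that("evidenceCounts routes PVS1 to the bucket named by its strength", {
  cv <- criteriaVector(c("PS1", "PM1", "PP2", "BS1", "BP4"), pvs1 = "Moderate")
  ct <- evidenceCounts(cv)
  expect_equal(ct[["very_strong"]], 0L)
  expect_equal(ct[["strong"]], 1L)
  expect_equal(ct[["moderate"]], 2L)  # PM1 + PVS1@Moderate
  expect_equal(ct[["supporting"]], 1L)
  expect_equal(ct[["strong_benign"]], 1L)
  expect_equal(ct[["supporting_benign"]], 1L)

  pvs1Strength(cv) <- "Supporting"
  expect_equal(evidenceCounts(cv)[["supporting"]], 2L)
})

test_that("combineCounts reproduces the combining-table calls", {
  expect_equal(combineCounts(1, 1, 0, 0, 0, 0, 0), "P")
  expect_equal(combineCounts(1, 0, 1, 0, 0, 0, 0), "LP")
  expect_equal(combineCounts(0, 0, 0, 0, 0, 0, 0), "VUS")
  # PVS1 downgraded to Supporting alongside one Moderate: no rule fires
  expect_equal(combineCounts(0, 0, 1, 1, 0, 0, 0), "VUS")
  # contradictory evidence: pathogenic and benign groups both fire
  expect_equal(combineCounts(1, 1, 0, 0, 1, 0, 0), "VUS")
  expect_equal(combineCounts(0, 0, 0, 0, 1, 0, 0), "B")
  expect_equal(combineCounts(0, 0, 0, 0, 0, 1, 1), "LB")

  expect_error(combineCounts(0, -1, 0, 0, 0, 0, 0), "non-negative")
  expect_error(combineCounts(2, 0, 0, 0, 0, 0, 0), "0/1")
})

test_that("combineCounts agrees with the independent oracle on a random sample", {
  set.seed(51)
  g <- oracleCountGrid()
  idx <- sample(nrow(g), 500)
  got <- combineCounts(g$vs[idx], g$s[idx], g$m[idx], g$su[idx],
                       g$ba[idx], g$bsn[idx], g$bpn[idx])
  want <- mapply(oracleCombine, g$vs[idx], g$s[idx], g$m[idx], g$su[idx],
                 g$ba[idx], g$bsn[idx], g$bpn[idx])
  expect_equal(got, unname(want))
})

test_that("intervarModifiedCall composes strip, demote and combine", {
  # raw InterVar P solely through PVS1 + PP5 collapses to VUS
  cv <- criteriaVector("PP5", pvs1 = "VeryStrong")
  expect_equal(intervarModifiedCall(cv, "VeryStrong")$call, "VUS")

  cv <- criteriaVector(c("PS1", "PM1", "PM2"))
  expect_equal(intervarModifiedCall(cv, NULL)$call, "LP")

  expect_equal(intervarModifiedCall(criteriaVector(), NULL)$call, "VUS")

  # the rule trace names the fired group and the counts
  tr <- intervarModifiedCall(criteriaVector(c("PS1", "PM1", "PM2")))$rule
  expect_match(tr, "^LP\\(")
})
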