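test_that("starsFromReviewStatus maps the fixed review-status table", {
  expect_equal(starsFromReviewStatus("practice guideline"), 4L)
  expect_equal(starsFromReviewStatus("reviewed by expert panel"), 3L)
  expect_equal(
    starsFromReviewStatus("criteria provided, multiple submitters, no conflicts"), 2L)
  expect_equal(
    starsFromReviewStatus("criteria provided, conflicting classifications"), 1L)
  expect_equal(
    starsFromReviewStatus("criteria provided, conflicting interpretations"), 1L)
  expect_equal(starsFromReviewStatus("criteria provided, single submitter"), 1L)
  expect_equal(starsFromReviewStatus("no assertion criteria provided"), 0L)
  expect_equal(starsFromReviewStatus("no classification provided"), 0L)

  # VCF CLNREVSTAT spelling
  expect_equal(
    starsFromReviewStatus("criteria_provided,_multiple_submitters,_no_conflicts"), 2L)

  expect_error(starsFromReviewStatus("five shiny stars"), "unrecognized")
})

test_that("normalizeSignificance is total over ClinVar vocabulary", {
  expect_equal(normalizeSignificance("Pathogenic"), "P")
  expect_equal(normalizeSignificance("Likely pathogenic"), "LP")
  expect_equal(normalizeSignificance("Uncertain significance"), "VUS")
  expect_equal(normalizeSignificance("Likely benign"), "LB")
  expect_equal(normalizeSignificance("benign"), "B")
  expect_equal(normalizeSignificance("Likely_pathogenic"), "LP")
  expect_equal(normalizeSignificance("Pathogenic/Likely pathogenic"), "LP")
  expect_equal(normalizeSignificance("Benign/Likely_benign"), "LB")
  expect_equal(normalizeSignificance("Affects|risk_factor"), "non_standard")
  expect_equal(normalizeSignificance("association_not_found"), "non_standard")
  expect_equal(normalizeSignificance("drug response"), "non_standard")
  expect_equal(
    normalizeSignificance("Conflicting classifications of pathogenicity"),
    "non_standard")
})

test_that("filterByConceptIds keeps intersecting submissions in order", {
  subs <- makeSubs(c("Pathogenic", "Benign", "Uncertain significance"),
                   concepts = list("C1", "C2", c("C1", "C3")))
  expect_equal(filterByConceptIds(subs, "C1")$submitter, c("Lab01", "Lab03"))
  expect_equal(nrow(filterByConceptIds(subs, "C9")), 0L)
  expect_identical(filterByConceptIds(subs, c("C1", "C2", "C3")), subs)
  expect_error(filterByConceptIds(subs, character()), "non-empty")
})

test_that("resolveConflict: majority, then tiebreaks", {
  r <- resolveConflict(makeSubs(c("Pathogenic", "Pathogenic",
                                  "Uncertain significance"),
                                dates = c("2019-01-01", "2020-01-01",
                                          "2021-01-01")))
  expect_equal(r[c("call", "method", "n_considered")],
               list(call = "P", method = "majority", n_considered = 3L))

  two <- makeSubs(c("Pathogenic", "Likely pathogenic"),
                  dates = c("2019-01-01", "2021-05-05"))
  expect_equal(resolveConflict(two, resolutionOptions())$call, "LP")
  expect_equal(resolveConflict(two, resolutionOptions())$method, "latest")
  ms <- resolveConflict(two, resolutionOptions(tiebreak = "most_severe"))
  expect_equal(ms$call, "P")
  expect_equal(ms$method, "most_severe")

  expect_error(resolveConflict(makeSubs(character())), "at least one")
})

test_that("resolveConflict exclusion steps run before the vote", {
  # no-assertion-criteria submissions never vote
  subs <- makeSubs(c("Pathogenic", "Likely benign", "Likely benign"),
                   dates = c("2021-01-01", "2019-01-01", "2018-01-01"),
                   crit = c(FALSE, TRUE, TRUE))
  expect_equal(resolveConflict(subs)$call, "LB")

  # non-standard submissions cannot be expressed on the five-level scale
  subs <- makeSubs(c("drug response", "Benign"),
                   dates = c("2022-01-01", "2020-01-01"))
  r <- resolveConflict(subs)
  expect_equal(r$call, "B")
  expect_equal(r$n_considered, 1L)

  # everything excluded: unresolved
  subs <- makeSubs(c("Pathogenic", "Likely pathogenic"), crit = FALSE)
  r <- resolveConflict(subs)
  expect_equal(r$method, "excluded_all")
  expect_true(is.na(r$call))
  expect_equal(r$n_considered, 0L)
})

test_that("resolveConflict concept filter narrows the electorate", {
  subs <- makeSubs(c("Pathogenic", "Likely pathogenic",
                     "Uncertain significance"),
                   dates = c("2019-01-01", "2020-01-01", "2021-01-01"),
                   concepts = list("C0000009", "C0000009", "C0027672"))
  r <- resolveConflict(subs, resolutionOptions(concept_ids = "C0027672"))
  expect_equal(r$call, "VUS")
  expect_equal(r$method, "majority")
  expect_equal(r$n_considered, 1L)

  # filter that matches nothing: excluded_all
  r <- resolveConflict(subs, resolutionOptions(concept_ids = "C9999999"))
  expect_equal(r$method, "excluded_all")
})

test_that("dateless submissions rank lowest for the latest tiebreak", {
  subs <- makeSubs(c("Pathogenic", "Likely benign"),
                   dates = c(NA, "2020-01-01"))
  expect_equal(resolveConflict(subs)$call, "LB")

  # all dateless: severity maximum as the deterministic fallback
  subs <- makeSubs(c("Pathogenic", "Likely benign"), dates = NA)
  expect_equal(resolveConflict(subs)$call, "P")

  # tie at the maximum date broken by severity
  subs <- makeSubs(c("Likely benign", "Pathogenic"),
                   dates = c("2020-01-01", "2020-01-01"))
  expect_equal(resolveConflict(subs)$call, "P")
})

test_that("concept superset is equivalent to no concept filter", {
  set.seed(61)
  for (i in 1:100) {
    subs <- randomSubmissionSet()
    all_ids <- unique(unlist(subs$concept_ids))
    a <- resolveConflict(subs, resolutionOptions())
    b <- resolveConflict(subs, resolutionOptions(concept_ids = all_ids))
    expect_identical(a, b)
  }
})

test_that("selectClinvarSubset applies the star-aware retention policy", {
  assertions <- data.frame(
    vid = c("1:100:A:G", "1:200:C:T", "1:300:G:A", "1:400:T:C"),
    variation_id = 1:4,
    significance = c("Pathogenic", "Pathogenic", "Affects",
                     "Conflicting classifications of pathogenicity"),
    review_status = c("reviewed by expert panel",
                      "no assertion criteria provided",
                      "criteria provided, multiple submitters, no conflicts",
                      "criteria provided, conflicting classifications"),
    stars = c(3L, 0L, 2L, 1L),
    stringsAsFactors = FALSE
  )
  subs <- list("4" = makeSubs(c("Pathogenic", "Likely pathogenic"),
                              crit = FALSE))
  out <- selectClinvarSubset(assertions, subs)

  # >= 2 stars: retained directly, submissions never consulted
  expect_equal(out$call[1], "P")
  expect_equal(out$resolution_method[1], "direct")
  # zero stars: no ClinVar classification
  expect_true(is.na(out$call[2]))
  expect_equal(out$note[2], "zero_star")
  # non-standard aggregate
  expect_true(is.na(out$call[3]))
  expect_equal(out$note[3], "non_standard")
  # conflict with everything excluded
  expect_true(is.na(out$call[4]))
  expect_equal(out$note[4], "conflict_excluded_all")

  # never emits a call outside the five-level scale
  expect_true(all(is.na(out$call) | out$call %in% callLevels()))
})
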