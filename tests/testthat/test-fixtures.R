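test_that("the default catalog covers every decision-tree branch", {
  cat <- scenarioCatalog()
  expect_gte(length(cat), 60L)
  labels <- vapply(cat, `[[`, "", "label")
  expect_equal(anyDuplicated(labels), 0L)
  states <- vapply(cat, `[[`, "", "state")
  expect_setequal(unique(states),
                  c("absent", "stars0", "stars1_single", "stars1_conflict",
                    "stars2plus", "non_standard"))
})

test_that("generateBundle is deterministic for a fixed seed", {
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  b1 <- generateBundle(scenarioCatalog()[1:12], seed = 99, out_dir = d1)
  b2 <- generateBundle(scenarioCatalog()[1:12], seed = 99, out_dir = d2)
  for (nm in names(b1$paths)) {
    expect_equal(unname(tools::md5sum(b1$paths[[nm]])),
                 unname(tools::md5sum(b2$paths[[nm]])),
                 label = paste("md5 of", nm))
  }
  # a different seed moves positions
  b3 <- generateBundle(scenarioCatalog()[1:12], seed = 100,
                       out_dir = file.path(tempdir(), "det3"))
  expect_false(identical(b1$expected$start, b3$expected$start))
})

test_that("generateBundle does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(
    generateBundle(scenarioCatalog()[1:3], seed = 5,
                   out_dir = file.path(tempdir(), "rng")))
  expect_equal(runif(1), before)
})

test_that("the generated bundle is cross-file consistent", {
  b <- getBundle()
  vep <- readVepVcf(b$paths$vep_vcf)
  ma <- readAnnovarMultianno(b$paths$multianno)
  ap <- readAutopvs1(b$paths$autopvs1)
  cl <- suppressMessages(readClinvarFiles(
    b$paths$clinvar_vcf, b$paths$variant_summary, b$paths$submission_summary))

  vids <- variantKeys(vep)$vid
  expect_equal(ma$vid, vids)                      # same universe, same order
  expect_true(all(ap$vid %in% vids))
  expect_true(all(cl$assertions$vid %in% vids))

  # every conflicting assertion has submissions to resolve
  conf <- cl$assertions[grepl("conflicting", cl$assertions$review_status), ]
  expect_true(all(as.character(conf$variation_id) %in%
                    names(cl$submissions_by_id)))
})

test_that("empty scenario list yields header-only files", {
  b <- generateBundle(list(), seed = 1,
                      out_dir = file.path(tempdir(), "empty-bundle"))
  expect_equal(length(readLines(b$paths$multianno)), 1L)
  expect_equal(length(readLines(b$paths$intervar)), 1L)
  expect_equal(nrow(b$expected), 0L)
  expect_error(
    generateBundle(scenarioCatalog()[c(1, 1)], seed = 1,
                   out_dir = file.path(tempdir(), "dup")),
    "unique")
})

test_that("randomCriteriaVector hits its flag probability", {
  set.seed(42)
  expect_equal(criteriaNames(randomCriteriaVector(0)), character())
  expect_equal(length(criteriaNames(randomCriteriaVector(1))), 27L)

  set.seed(42)
  frac <- mean(vapply(1:1000, function(i)
    length(criteriaNames(randomCriteriaVector(0.2))) / 27, numeric(1)))
  expect_lt(abs(frac - 0.2), 0.04)
})
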