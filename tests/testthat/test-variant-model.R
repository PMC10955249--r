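test_that("normalizeVariant strips chr, uppercases, and trims to minimal representation", {
  k <- normalizeVariant("chr7", 100, "AT", "A")
  expect_equal(unlist(k), c(contig = "7", pos = "100", ref = "AT", alt = "A"))

  # shared-suffix then shared-prefix trimming advances the position
  k <- normalizeVariant("1", 1000, "CAG", "CAA")
  expect_equal(k$pos, 1002L)
  expect_equal(k$ref, "G")
  expect_equal(k$alt, "A")

  # right-trim happens first and stops once an allele is a single base
  k <- normalizeVariant("2", 50, "TCGC", "TC")
  expect_equal(k$pos, 50L)
  expect_equal(k$ref, "TCG")
  expect_equal(k$alt, "T")
})

test_that("normalizeVariant trimming keeps at least one base per allele", {
  # pure deletion keeps the shared anchor base (alt cannot become empty)
  k <- normalizeVariant("2", 50, "TCG", "T")
  expect_equal(k$pos, 50L)
  expect_equal(k$ref, "TCG")
  expect_equal(k$alt, "T")

  # SNV buried in shared context
  k <- normalizeVariant("chrX", 10, "GGCAT", "GGGAT")
  expect_equal(k$pos, 12L)
  expect_equal(k$ref, "C")
  expect_equal(k$alt, "G")
})

test_that("normalizeVariant rejects invalid alleles", {
  expect_error(normalizeVariant("chrX", 5, "G", "G"), "identical")
  expect_error(normalizeVariant("1", 10, "A", "<DEL>"), "symbolic|A, C, G, T")
  expect_error(normalizeVariant("1", 10, "A", "G,T"), "multi-allelic|split")
  expect_error(normalizeVariant("1", 0, "A", "G"), ">= 1")
  expect_error(normalizeVariant("1", 10, "A", ""), "non-empty|A, C, G, T")
})

test_that("normalizeVariant is idempotent on random indels", {
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    core_r <- paste(sample(bases, sample(1:4, 1), TRUE), collapse = "")
    core_a <- paste(sample(bases, sample(1:4, 1), TRUE), collapse = "")
    pre <- paste(sample(bases, sample(0:3, 1), TRUE), collapse = "")
    suf <- paste(sample(bases, sample(0:3, 1), TRUE), collapse = "")
    ref <- paste0(pre, core_r, suf)
    alt <- paste0(pre, core_a, suf)
    if (ref == alt) next
    k1 <- normalizeVariant("chr3", 500, ref, alt)
    k2 <- normalizeVariant(k1$contig, k1$pos, k1$ref, k1$alt)
    expect_identical(k1, k2)
  }
})

test_that("severityMax follows the P > LP > VUS > LB > B order", {
  expect_equal(severityMax(c("LB", "VUS", "LP")), "LP")
  expect_equal(severityMax("B"), "B")
  expect_equal(severityMax(c("P", "B")), "P")
  expect_error(severityMax(character()), "non-empty")
  expect_error(severityMax(c("P", "pathogenic")), "unknown call")
})

test_that("severityMax is permutation-invariant and closed over its input", {
  set.seed(21)
  for (i in 1:100) {
    calls <- sample(callLevels(), sample(1:6, 1), replace = TRUE)
    m <- severityMax(calls)
    expect_true(m %in% calls)
    expect_equal(severityMax(sample(calls)), m)
    if (length(calls) == 2L)
      expect_true(severityMax(calls) %in% calls)
  }
})
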