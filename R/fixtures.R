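# Synthetic miniature input bundle: coherent versions of all seven input
# files plus a golden expected-calls table. Every scenario's expectation is
# derived by hand-tracing the classification decision tree and is stored as
# a literal in the catalog, never computed by the pipeline itself.

.sub <- function(sig, date = NA_character_, crit = TRUE,
                 concepts = "C0000001") {
  list(sig = sig, date = date, crit = crit, concepts = concepts)
}

# exp entries are c(source, call); `all` sets the same expectation for the
# plain latest run, the most_severe run and the concept-list latest run
.sc <- function(label, state, sig = NA_character_, review = NA_character_,
                subs = list(), iv = NULL, iv_pvs1 = FALSE,
                iv_call = "Uncertain significance", ap = NA_character_,
                filter = "PASS", dp = 30L, ncsq = 1L, indel = FALSE,
                all = NULL, latest = NULL, ms = NULL, concept = NULL) {
  if (!is.null(all)) { latest <- all; ms <- all; concept <- all }
  if (is.null(concept)) concept <- latest
  list(label = label, state = state, sig = sig, review = review,
       subs = subs, iv = iv, iv_pvs1 = iv_pvs1, iv_call = iv_call,
       ap = ap, filter = filter, dp = dp, ncsq = ncsq, indel = indel,
       latest = latest, ms = ms, concept = concept)
}

#' The default fixture scenario catalog
#'
#' One scenario per branch of the classification decision tree: direct
#' ClinVar retention at 2-4 stars and 1-star single submitter (all five
#' calls, plus the combined P/LP and B/LB aggregates), zero-star and
#' non-standard aggregates falling through to InterVar, variants absent
#' from ClinVar with every modified-InterVar outcome, 1-star conflicts
#' resolved by majority, by the latest/most-severe tiebreaks, with dateless
#' submissions, with no-assertion-criteria and non-standard submissions
#' excluded, fully excluded conflicts, Concept-ID-filtered conflicts, the
#' PP5-removal demotion, the graded-PVS1 downgrade ladder, evidence
#' contradictions, a non-PASS record, and an indel exercising the
#' ANNOVAR-coordinate bridge.
#'
#' Each scenario carries its hand-traced expected (source, call) under the
#' plain latest run, the most-severe run, and the concept-list latest run.
#'
#' @return List of scenario descriptors for [generateBundle()].
#' @export
scenarioCatalog <- function() {
  CV <- function(src, call) c(src, call)
  list(
    # --- direct ClinVar retention, >= 2 stars ---------------------------
    .sc("d2_P", "stars2plus", "Pathogenic",
        "criteria provided, multiple submitters, no conflicts",
        subs = list(.sub("Pathogenic", "2020-01-05"),
                    .sub("Pathogenic", "2021-03-02")),
        all = CV("ClinVar", "P")),
    .sc("d2_LP", "stars2plus", "Likely pathogenic",
        "criteria provided, multiple submitters, no conflicts",
        subs = list(.sub("Likely pathogenic", "2019-04-01"),
                    .sub("Likely pathogenic", "2020-09-09")),
        all = CV("ClinVar", "LP")),
    .sc("d2_VUS", "stars2plus", "Uncertain significance",
        "criteria provided, multiple submitters, no conflicts",
        subs = list(.sub("Uncertain significance", "2018-02-02"),
                    .sub("Uncertain significance", "2022-06-30")),
        all = CV("ClinVar", "VUS")),
    .sc("d2_LB", "stars2plus", "Likely benign",
        "criteria provided, multiple submitters, no conflicts",
        subs = list(.sub("Likely benign", "2017-11-11"),
                    .sub("Likely benign", "2019-12-12")),
        all = CV("ClinVar", "LB")),
    .sc("d2_B", "stars2plus", "Benign",
        "criteria provided, multiple submitters, no conflicts",
        subs = list(.sub("Benign", "2016-01-01"),
                    .sub("Benign", "2021-07-07")),
        all = CV("ClinVar", "B")),
    .sc("d3_P_expert", "stars2plus", "Pathogenic",
        "reviewed by expert panel",
        subs = list(.sub("Pathogenic", "2021-05-20")),
        all = CV("ClinVar", "P")),
    .sc("d4_B_guideline", "stars2plus", "Benign", "practice guideline",
        subs = list(.sub("Benign", "2015-08-14")),
        all = CV("ClinVar", "B")),
    .sc("d2_combined_PLP", "stars2plus", "Pathogenic/Likely pathogenic",
        "criteria provided, multiple submitters, no conflicts",
        subs = list(.sub("Pathogenic", "2020-02-02"),
                    .sub("Likely pathogenic", "2021-02-02")),
        all = CV("ClinVar", "LP")),
    .sc("d2_combined_BLB", "stars2plus", "Benign/Likely benign",
        "criteria provided, multiple submitters, no conflicts",
        subs = list(.sub("Benign", "2019-03-03"),
                    .sub("Likely benign", "2020-04-04")),
        all = CV("ClinVar", "LB")),

    # --- 1-star, single submitter ---------------------------------------
    .sc("s1_P", "stars1_single", "Pathogenic",
        "criteria provided, single submitter",
        subs = list(.sub("Pathogenic", "2020-10-10")),
        all = CV("ClinVar", "P")),
    .sc("s1_LP", "stars1_single", "Likely pathogenic",
        "criteria provided, single submitter",
        subs = list(.sub("Likely pathogenic", "2019-01-30")),
        all = CV("ClinVar", "LP")),
    .sc("s1_VUS", "stars1_single", "Uncertain significance",
        "criteria provided, single submitter",
        subs = list(.sub("Uncertain significance", "2021-11-01")),
        all = CV("ClinVar", "VUS")),
    .sc("s1_LB", "stars1_single", "Likely benign",
        "criteria provided, single submitter",
        subs = list(.sub("Likely benign", "2018-06-06")),
        all = CV("ClinVar", "LB")),
    .sc("s1_B", "stars1_single", "Benign",
        "criteria provided, single submitter",
        subs = list(.sub("Benign", "2017-09-09")),
        all = CV("ClinVar", "B")),

    # --- zero stars: ClinVar classification discarded -------------------
    # PVS1(VeryStrong) + PS1 -> P
    .sc("z_P", "stars0", "Pathogenic", "no assertion criteria provided",
        subs = list(.sub("Pathogenic", "2015-05-05", crit = FALSE)),
        iv = "PS1", iv_pvs1 = TRUE, iv_call = "Pathogenic",
        ap = "VeryStrong", all = CV("InterVar", "P")),
    # 1 Strong + 2 Moderate -> LP
    .sc("z_LP", "stars0", "Pathogenic", "no assertion criteria provided",
        subs = list(.sub("Pathogenic", "2014-04-04", crit = FALSE)),
        iv = c("PS1", "PM1", "PM2"), iv_call = "Likely pathogenic",
        all = CV("InterVar", "LP")),
    .sc("z_VUS", "stars0", "Likely pathogenic",
        "no assertion criteria provided",
        subs = list(.sub("Likely pathogenic", "2013-03-03", crit = FALSE)),
        iv = character(), all = CV("InterVar", "VUS")),
    # 1 strong benign + 1 supporting benign -> LB
    .sc("z_LB", "stars0", "Pathogenic", "no assertion criteria provided",
        subs = list(.sub("Pathogenic", "2012-02-02", crit = FALSE)),
        iv = c("BS1", "BP4"), iv_call = "Likely benign",
        all = CV("InterVar", "LB")),
    # BA1 standalone -> B
    .sc("z_B", "stars0", "Benign", "no assertion criteria provided",
        subs = list(.sub("Benign", "2011-01-01", crit = FALSE)),
        iv = "BA1", iv_call = "Benign", all = CV("InterVar", "B")),

    # --- non-standard aggregate calls ------------------------------------
    .sc("ns_affects", "non_standard", "Affects|risk_factor",
        "criteria provided, multiple submitters, no conflicts",
        subs = list(.sub("Affects", "2019-07-07")),
        iv = c("BS1", "BS2"), iv_call = "Benign",
        all = CV("InterVar", "B")),
    .sc("ns_drug", "non_standard", "drug response",
        "criteria provided, single submitter",
        subs = list(.sub("drug response", "2018-08-08")),
        iv = character(), all = CV("InterVar", "VUS")),
    # 3 Moderate -> LP
    .sc("ns_assoc", "non_standard", "association not found",
        "criteria provided, multiple submitters, no conflicts",
        subs = list(.sub("association not found", "2020-12-24")),
        iv = c("PM1", "PM2", "PM3"), iv_call = "Likely pathogenic",
        all = CV("InterVar", "LP")),
    .sc("ns_risk", "non_standard", "risk factor",
        "criteria provided, multiple submitters, no conflicts",
        subs = list(.sub("risk factor", "2017-10-31")),
        iv = "BA1", iv_call = "Benign", all = CV("InterVar", "B")),

    # --- absent from ClinVar ---------------------------------------------
    .sc("a_P", "absent", iv = "PS1", iv_pvs1 = TRUE, iv_call = "Pathogenic",
        ap = "VeryStrong", all = CV("InterVar", "P")),
    .sc("a_LP", "absent", iv = c("PS1", "PM1", "PM2"),
        iv_call = "Likely pathogenic", all = CV("InterVar", "LP")),
    .sc("a_VUS", "absent", iv = character(), all = CV("InterVar", "VUS")),
    .sc("a_LB", "absent", iv = c("BS1", "BP4"), iv_call = "Likely benign",
        all = CV("InterVar", "LB")),
    .sc("a_B", "absent", iv = c("BS1", "BS2"), iv_call = "Benign",
        all = CV("InterVar", "B")),

    # --- 1-star conflicts, strict plurality ------------------------------
    .sc("cm_P", "stars1_conflict",
        "Conflicting classifications of pathogenicity",
        "criteria provided, conflicting classifications",
        subs = list(.sub("Pathogenic", "2019-01-01"),
                    .sub("Pathogenic", "2020-01-01"),
                    .sub("Uncertain significance", "2021-01-01")),
        all = CV("ClinVar", "P")),
    .sc("cm_LP", "stars1_conflict",
        "Conflicting classifications of pathogenicity",
        "criteria provided, conflicting classifications",
        subs = list(.sub("Likely pathogenic", "2018-02-02"),
                    .sub("Likely pathogenic", "2020-02-02"),
                    .sub("Pathogenic", "2021-02-02")),
        all = CV("ClinVar", "LP")),
    .sc("cm_VUS", "stars1_conflict",
        "Conflicting classifications of pathogenicity",
        "criteria provided, conflicting classifications",
        subs = list(.sub("Uncertain significance", "2017-03-03"),
                    .sub("Uncertain significance", "2019-03-03"),
                    .sub("Benign", "2021-03-03")),
        all = CV("ClinVar", "VUS")),
    .sc("cm_LB", "stars1_conflict",
        "Conflicting classifications of pathogenicity",
        "criteria provided, conflicting classifications",
        subs = list(.sub("Likely benign", "2016-04-04"),
                    .sub("Likely benign", "2018-04-04"),
                    .sub("Uncertain significance", "2020-04-04"),
                    .sub("Pathogenic", "2021-04-04")),
        all = CV("ClinVar", "LB")),
    .sc("cm_B", "stars1_conflict",
        "Conflicting classifications of pathogenicity",
        "criteria provided, conflicting classifications",
        subs = list(.sub("Benign", "2015-05-05"),
                    .sub("Benign", "2017-05-05"),
                    .sub("Likely benign", "2019-05-05")),
        all = CV("ClinVar", "B")),

    # --- 1-star conflicts, no plurality: tiebreak decides ----------------
    .sc("ct_P_LP", "stars1_conflict",
        "Conflicting classifications of pathogenicity",
        "criteria provided, conflicting classifications",
        subs = list(.sub("Pathogenic", "2019-01-01"),
                    .sub("Likely pathogenic", "2021-05-05")),
        latest = CV("ClinVar", "LP"), ms = CV("ClinVar", "P")),
    .sc("ct_LP_VUS", "stars1_conflict",
        "Conflicting classifications of pathogenicity",
        "criteria provided, conflicting classifications",
        subs = list(.sub("Likely pathogenic", "2018-03-01"),
                    .sub("Uncertain significance", "2020-07-10")),
        latest = CV("ClinVar", "VUS"), ms = CV("ClinVar", "LP")),
    .sc("ct_VUS_LB", "stars1_conflict",
        "Conflicting classifications of pathogenicity",
        "criteria provided, conflicting classifications",
        subs = list(.sub("Uncertain significance", "2017-01-01"),
                    .sub("Likely benign", "2019-02-02")),
        latest = CV("ClinVar", "LB"), ms = CV("ClinVar", "VUS")),
    .sc("ct_LB_B", "stars1_conflict",
        "Conflicting classifications of pathogenicity",
        "criteria provided, conflicting classifications",
        subs = list(.sub("Likely benign", "2016-05-05"),
                    .sub("Benign", "2018-08-08")),
        latest = CV("ClinVar", "B"), ms = CV("ClinVar", "LB")),
    .sc("ct_P_B", "stars1_conflict",
        "Conflicting classifications of pathogenicity",
        "criteria provided, conflicting classifications",
        subs = list(.sub("Benign", "2022-01-01"),
                    .sub("Pathogenic", "2020-01-01")),
        latest = CV("ClinVar", "B"), ms = CV("ClinVar", "P")),

    # --- dateless submissions ---------------------------------------------
    # dateless ranks lowest, so the dated LB wins the latest tiebreak
    .sc("ct_dateless", "stars1_conflict",
        "Conflicting classifications of pathogenicity",
        "criteria provided, conflicting classifications",
        subs = list(.sub("Pathogenic"),
                    .sub("Likely benign", "2020-01-01")),
        latest = CV("ClinVar", "LB"), ms = CV("ClinVar", "P")),
    # all dateless: latest degenerates to the severity maximum
    .sc("ct_all_dateless", "stars1_conflict",
        "Conflicting classifications of pathogenicity",
        "criteria provided, conflicting classifications",
        subs = list(.sub("Pathogenic"), .sub("Likely benign")),
        all = CV("ClinVar", "P")),

    # --- no-assertion-criteria submissions are excluded first -------------
    # exclusion flips the outcome: remaining [LB, VUS, LB] -> LB majority
    .sc("cx_excl_shifts", "stars1_conflict",
        "Conflicting classifications of pathogenicity",
        "criteria provided, conflicting classifications",
        subs = list(.sub("Pathogenic", "2019-01-01", crit = FALSE),
                    .sub("Pathogenic", "2019-06-01", crit = FALSE),
                    .sub("Likely benign", "2018-01-01"),
                    .sub("Uncertain significance", "2019-02-02"),
                    .sub("Likely benign", "2020-03-03")),
        all = CV("ClinVar", "LB")),
    # after exclusion [LP@2020, VUS@2021]: no majority, tiebreak decides
    .sc("cx_excl_tiebreak", "stars1_conflict",
        "Conflicting classifications of pathogenicity",
        "criteria provided, conflicting classifications",
        subs = list(.sub("Pathogenic", "2018-01-01", crit = FALSE),
                    .sub("Likely pathogenic", "2020-01-01"),
                    .sub("Uncertain significance", "2021-01-01")),
        latest = CV("ClinVar", "VUS"), ms = CV("ClinVar", "LP")),

    # --- non-standard submissions dropped inside resolution ---------------
    .sc("cns_drop", "stars1_conflict",
        "Conflicting classifications of pathogenicity",
        "criteria provided, conflicting classifications",
        subs = list(.sub("drug response", "2020-01-01"),
                    .sub("Pathogenic", "2019-01-01"),
                    .sub("Pathogenic", "2018-01-01"),
                    .sub("Uncertain significance", "2021-01-01")),
        all = CV("ClinVar", "P")),
    # remaining [LP@2019, B@2021]: tiebreak decides
    .sc("cns_drop_tb", "stars1_conflict",
        "Conflicting classifications of pathogenicity",
        "criteria provided, conflicting classifications",
        subs = list(.sub("risk factor", "2018-01-01"),
                    .sub("Likely pathogenic", "2019-01-01"),
                    .sub("Benign", "2021-01-01")),
        latest = CV("ClinVar", "B"), ms = CV("ClinVar", "LP")),

    # --- conflicts whose submissions are all excluded ----------------------
    .sc("cex_all_nocrit", "stars1_conflict",
        "Conflicting classifications of pathogenicity",
        "criteria provided, conflicting classifications",
        subs = list(.sub("Pathogenic", "2020-01-01", crit = FALSE),
                    .sub("Likely pathogenic", "2019-01-01", crit = FALSE)),
        iv = c("BS1", "BP4"), iv_call = "Likely benign",
        all = CV("InterVar", "LB")),
    .sc("cex_all_nonstd", "stars1_conflict",
        "Conflicting classifications of pathogenicity",
        "criteria provided, conflicting classifications",
        subs = list(.sub("drug response", "2020-01-01"),
                    .sub("Affects", "2019-01-01")),
        iv = character(), all = CV("InterVar", "VUS")),

    # --- Concept-ID filtering (differs only in the concept-list run) ------
    # no-concept runs see three distinct calls; the concept run keeps only
    # the VUS submission, which is its own majority
    .sc("cc_filter_majority", "stars1_conflict",
        "Conflicting classifications of pathogenicity",
        "criteria provided, conflicting classifications",
        subs = list(.sub("Pathogenic", "2019-01-01", concepts = "C0000009"),
                    .sub("Likely pathogenic", "2020-01-01",
                         concepts = "C0000009"),
                    .sub("Uncertain significance", "2021-01-01")),
        latest = CV("ClinVar", "VUS"), ms = CV("ClinVar", "P"),
        concept = CV("ClinVar", "VUS")),
    # the concept filter empties the set -> excluded_all -> InterVar
    .sc("cc_filter_empty", "stars1_conflict",
        "Conflicting classifications of pathogenicity",
        "criteria provided, conflicting classifications",
        subs = list(.sub("Pathogenic", "2020-01-01", concepts = "C0000009"),
                    .sub("Likely pathogenic", "2021-01-01",
                         concepts = "C0000009")),
        iv = c("PS1", "PM1", "PM2"), iv_call = "Likely pathogenic",
        latest = CV("ClinVar", "LP"), ms = CV("ClinVar", "P"),
        concept = CV("InterVar", "LP")),
    # the concept filter leaves [P@2019, LP@2021]: latest tiebreak -> LP
    .sc("cc_filter_tiebreak", "stars1_conflict",
        "Conflicting classifications of pathogenicity",
        "criteria provided, conflicting classifications",
        subs = list(.sub("Pathogenic", "2019-01-01"),
                    .sub("Likely pathogenic", "2021-01-01"),
                    .sub("Uncertain significance", "2022-01-01",
                         concepts = "C0000009")),
        latest = CV("ClinVar", "VUS"), ms = CV("ClinVar", "P"),
        concept = CV("ClinVar", "LP")),

    # --- modified-InterVar regressions -------------------------------------
    # raw InterVar P solely via PVS1 + PP5; stripping PP5 leaves a lone
    # VeryStrong -> VUS
    .sc("pp5_demo", "absent", iv = "PP5", iv_pvs1 = TRUE,
        iv_call = "Pathogenic", ap = "VeryStrong",
        all = CV("InterVar", "VUS")),
    # graded-PVS1 ladder with fixed co-evidence PS1:
    # VS+S=P, S+S=P, S+M=LP, S+SU=VUS, S alone=VUS
    .sc("ladder_vs", "absent", iv = "PS1", iv_pvs1 = TRUE,
        iv_call = "Pathogenic", ap = "VeryStrong",
        all = CV("InterVar", "P")),
    .sc("ladder_strong", "absent", iv = "PS1", iv_pvs1 = TRUE,
        iv_call = "Pathogenic", ap = "Strong",
        all = CV("InterVar", "P")),
    .sc("ladder_moderate", "absent", iv = "PS1", iv_pvs1 = TRUE,
        iv_call = "Pathogenic", ap = "Moderate",
        all = CV("InterVar", "LP")),
    .sc("ladder_supporting", "absent", iv = "PS1", iv_pvs1 = TRUE,
        iv_call = "Pathogenic", ap = "Supporting",
        all = CV("InterVar", "VUS")),
    .sc("ladder_unmet", "absent", iv = "PS1", iv_pvs1 = TRUE,
        iv_call = "Pathogenic", ap = "Unmet",
        all = CV("InterVar", "VUS")),
    # PVS1 set by InterVar but no grading available: kept, with a warning
    .sc("pvs1_norec", "absent", iv = "PS1", iv_pvs1 = TRUE,
        iv_call = "Pathogenic", all = CV("InterVar", "P")),
    # grading never introduces PVS1 when InterVar did not flag it
    .sc("pvs1_noupgrade", "absent", iv = "PS1", iv_call = "Uncertain significance",
        ap = "Strong", all = CV("InterVar", "VUS")),
    # pathogenic and benign rule groups both fire -> contradictory -> VUS
    .sc("contradiction", "absent", iv = c("PS1", "BA1"), iv_pvs1 = TRUE,
        iv_call = "Uncertain significance", ap = "VeryStrong",
        all = CV("InterVar", "VUS")),
    # in neither ClinVar nor InterVar: loud VUS, never dropped
    .sc("no_evidence", "absent", all = CV("InterVar", "VUS")),

    # --- filtering and join mechanics --------------------------------------
    .sc("filt_lowgq", "absent", iv = character(), filter = "lowGQ"),
    .sc("filt_dp", "absent", iv = character(), dp = 3L,
        all = CV("InterVar", "VUS")),
    # deletion whose InterVar row uses ANNOVAR-shifted coordinates and `-`
    # alleles; joined back to the VCF key through the multianno bridge
    .sc("indel_bridge", "absent", iv = c("PS1", "PM1", "PM2"),
        iv_call = "Likely pathogenic", indel = TRUE,
        all = CV("InterVar", "LP")),
    # three CSQ transcripts; the PVS1-graded transcript (version-insensitive
    # match) becomes primary, the others are retained in csq_vep
    .sc("multi_csq", "stars2plus", "Pathogenic",
        "criteria provided, multiple submitters, no conflicts",
        subs = list(.sub("Pathogenic", "2020-06-06"),
                    .sub("Pathogenic", "2021-06-06")),
        ncsq = 3L, ap = "Unmet", all = CV("ClinVar", "P"))
  )
}

.CSQ_FORMAT <- c("Allele", "Consequence", "IMPACT", "SYMBOL", "Feature",
                 "CANONICAL", "HGVSc")

.gzWriteLines <- function(lines, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Generate a coherent miniature input bundle
#'
#' Writes all seven pipeline inputs, the Concept ID list and the golden
#' `expected_calls.tsv` to `out_dir`. Positions and alleles are drawn
#' deterministically from `seed`; all cross-file keys are consistent. The
#' golden table carries each scenario's hand-traced expectation for the
#' plain latest run, the most-severe run and the concept-list latest run.
#'
#' @param scenarios Scenario list, by default [scenarioCatalog()].
#' @param seed Integer RNG seed.
#' @param out_dir Output directory (created if needed).
#' @param prefix Per-cohort file prefix (default `"test"`).
#' @return Invisibly, a list with `paths` (named file paths) and
#'   `expected` (the golden data.frame).
#' @export
generateBundle <- function(scenarios = scenarioCatalog(), seed = 7L,
                           out_dir, prefix = "test") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  labels <- vapply(scenarios, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("scenario labels must be unique")

  oldseed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv()), add = TRUE)
  set.seed(seed)

  n <- length(scenarios)
  chroms <- rep_len(c(as.character(1:22), "X"), max(n, 1L))[seq_len(n)]
  pos <- integer(n); ref <- character(n); alt <- character(n)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    pos[i] <- 100000L * i + sample.int(50000L, 1L)
    if (isTRUE(scenarios[[i]]$indel)) {
      anchor <- sample(bases, 1L)
      ref[i] <- paste0(anchor, sample(bases, 1L))
      alt[i] <- anchor
    } else {
      ref[i] <- sample(bases, 1L)
      alt[i] <- sample(setdiff(bases, ref[i]), 1L)
    }
  }
  gene <- sprintf("GENE%03d", seq_len(n))
  transcript <- sprintf("ENST%08d.2", seq_len(n))
  variation_id <- 300000L + seq_len(n)
  allele_id <- 400000L + seq_len(n)

  # ---- VEP VCF ----------------------------------------------------------
  vcfHeader <- c(
    "##fileformat=VCFv4.2",
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FILTER=<ID=lowGQ,Description=\"Low genotype quality\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence ",
           "annotations from Ensembl VEP. Format: ",
           paste(.CSQ_FORMAT, collapse = "|"), "\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Sample depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "SAMPLE01", sep = "\t")
  )
  csqFor <- function(i) {
    s <- scenarios[[i]]
    cons <- if (isTRUE(s$iv_pvs1)) "stop_gained" else "missense_variant"
    ents <- character(s$ncsq)
    for (k in seq_len(s$ncsq)) {
      feat <- if (s$ncsq == 1L) transcript[i] else
        sprintf("ENST%08d.%d", 1000L * i + k, k)
      ents[k] <- paste(alt[i], cons, "MODERATE", gene[i], feat,
                       if (k == 1L) "YES" else "", sprintf("c.%d%s>%s", k,
                       substr(ref[i], 1L, 1L), substr(alt[i], 1L, 1L)),
                       sep = "|")
    }
    paste(ents, collapse = ",")
  }
  vcfRows <- vapply(seq_len(n), function(i) {
    s <- scenarios[[i]]
    info <- paste0("DP=", s$dp, ";AF=0.0001;CSQ=", csqFor(i))
    paste(paste0("chr", chroms[i]), pos[i], ".", ref[i], alt[i], "50",
          s$filter, info, "GT:DP", paste0("0/1:", s$dp), sep = "\t")
  }, character(1))
  paths <- list()
  paths$vep_vcf <- file.path(out_dir, paste0(prefix, "_VEP.vcf"))
  writeLines(c(vcfHeader, vcfRows), paths$vep_vcf)

  # ---- ANNOVAR-style coordinates (for multianno and InterVar) ------------
  aStart <- pos; aEnd <- pos; aRef <- ref; aAlt <- alt
  for (i in seq_len(n)) {
    if (isTRUE(scenarios[[i]]$indel)) {  # 1-bp deletion: shifted, '-' allele
      aStart[i] <- pos[i] + 1L
      aEnd[i] <- pos[i] + 1L
      aRef[i] <- substr(ref[i], 2L, 2L)
      aAlt[i] <- "-"
    }
  }

  # ---- multianno ---------------------------------------------------------
  maHeader <- paste(c("Chr", "Start", "End", "Ref", "Alt", "Func.refGene",
                      "Gene.refGene", "ExonicFunc.refGene",
                      "gnomad_genome_AF", paste0("Otherinfo", 1:13)),
                    collapse = "\t")
  maRows <- vapply(seq_len(n), function(i) {
    s <- scenarios[[i]]
    paste(chroms[i], aStart[i], aEnd[i], aRef[i], aAlt[i], "exonic",
          gene[i], "nonsynonymous SNV", "0.0001",
          "0.5", "30", "50",                      # Otherinfo1-3
          paste0("chr", chroms[i]), pos[i], ".", ref[i], alt[i], "50",
          s$filter, paste0("DP=", s$dp, ";AF=0.0001"),
          "GT:DP", paste0("0/1:", s$dp),
          sep = "\t")
  }, character(1))
  paths$multianno <- file.path(out_dir, paste0(prefix, "_hg38_multianno.txt"))
  writeLines(c(maHeader, maRows), paths$multianno)

  # ---- InterVar ----------------------------------------------------------
  ivIdx <- which(vapply(scenarios, function(s) !is.null(s$iv), logical(1)))
  ivHeader <- paste(c("#Chr", "Start", "End", "Ref", "Alt", "Ref.Gene",
                      "avsnp147", " InterVar: InterVar and Evidence "),
                    collapse = "\t")
  ivRows <- vapply(ivIdx, function(i) {
    s <- scenarios[[i]]
    cv <- criteriaVector(s$iv, pvs1 = if (isTRUE(s$iv_pvs1)) "VeryStrong" else "Unmet")
    paste(chroms[i], aStart[i], aEnd[i], aRef[i], aAlt[i], gene[i], ".",
          .formatInterVarEvidence(s$iv_call, cv), sep = "\t")
  }, character(1))
  paths$intervar <- file.path(out_dir, paste0(prefix, "_multianno.txt.intervar"))
  writeLines(c(ivHeader, ivRows), paths$intervar)

  # ---- AutoPVS1 ----------------------------------------------------------
  apIdx <- which(vapply(scenarios, function(s) !is.na(s$ap), logical(1)))
  apHeader <- paste(c("variant_id", "symbol", "trans_name", "consequence",
                      "criterion", "strength"), collapse = "\t")
  apRows <- vapply(apIdx, function(i) {
    s <- scenarios[[i]]
    # the graded transcript matches the CSQ Feature up to its version
    feat <- if (s$ncsq == 1L) sub("\\.\\d+$", ".9", transcript[i]) else
      sprintf("ENST%08d.9", 1000L * i + 2L)
    strength <- if (s$ap == "Unmet") "Unmet" else paste0("Strength.", s$ap)
    paste(paste(chroms[i], pos[i], ref[i], alt[i], sep = "-"), gene[i],
          feat, "stop_gained", "NF1", strength, sep = "\t")
  }, character(1))
  paths$autopvs1 <- file.path(out_dir, paste0(prefix, "_autopvs1.txt"))
  writeLines(c(apHeader, apRows), paths$autopvs1)

  # ---- ClinVar VCF --------------------------------------------------------
  cvIdx <- which(vapply(scenarios, function(s) s$state != "absent", logical(1)))
  cvHeader <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ALLELEID,Number=1,Type=Integer,Description=\"Allele ID\">",
    "##INFO=<ID=CLNSIG,Number=.,Type=String,Description=\"Clinical significance\">",
    "##INFO=<ID=CLNREVSTAT,Number=.,Type=String,Description=\"Review status\">",
    "##INFO=<ID=GENEINFO,Number=1,Type=String,Description=\"Gene symbol:id\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  underscore <- function(x) gsub(" ", "_", x)
  cvRows <- vapply(cvIdx, function(i) {
    s <- scenarios[[i]]
    info <- paste0("ALLELEID=", allele_id[i],
                   ";CLNSIG=", underscore(s$sig),
                   ";CLNREVSTAT=", underscore(s$review),
                   ";GENEINFO=", gene[i], ":", 9000L + i)
    paste(chroms[i], pos[i], variation_id[i], ref[i], alt[i], ".", ".",
          info, sep = "\t")
  }, character(1))
  paths$clinvar_vcf <- file.path(out_dir, "clinvar.vcf.gz")
  .gzWriteLines(c(cvHeader, cvRows), paths$clinvar_vcf)

  # ---- variant_summary ----------------------------------------------------
  vsHeader <- paste(c("#AlleleID", "Type", "Name", "GeneSymbol",
                      "ClinicalSignificance", "LastEvaluated", "ReviewStatus",
                      "Assembly", "Chromosome", "PositionVCF",
                      "ReferenceAlleleVCF", "AlternateAlleleVCF",
                      "VariationID"), collapse = "\t")
  vsRow <- function(i, assembly, position) {
    s <- scenarios[[i]]
    paste(allele_id[i], "single nucleotide variant",
          paste0("NM_0000", i, ".1(", gene[i], "):c.", i, "A>G"),
          gene[i], s$sig, "2023-01-01", s$review, assembly, chroms[i],
          position, ref[i], alt[i], variation_id[i], sep = "\t")
  }
  vsRows <- unlist(lapply(cvIdx, function(i)
    c(vsRow(i, "GRCh37", pos[i] - 1000L), vsRow(i, "GRCh38", pos[i]))))
  paths$variant_summary <- file.path(out_dir, "variant_summary.txt.gz")
  .gzWriteLines(c(vsHeader, if (length(vsRows)) vsRows else character()), paths$variant_summary)

  # ---- submission_summary -------------------------------------------------
  ssHeader <- c(
    "## ClinVar submission summary (synthetic miniature)",
    "## one row per submitter assertion",
    paste(c("#VariationID", "ClinicalSignificance", "DateLastEvaluated",
            "Description", "SubmittedPhenotypeInfo", "ReportedPhenotypeInfo",
            "ReviewStatus", "CollectionMethod", "OriginCounts", "Submitter",
            "SCV", "SubmittedGeneSymbol"), collapse = "\t")
  )
  ssRows <- character()
  for (i in cvIdx) {
    s <- scenarios[[i]]
    for (k in seq_along(s$subs)) {
      sb <- s$subs[[k]]
      rep_pheno <- paste(paste0(sb$concepts, ":Condition ", sb$concepts),
                         collapse = ";")
      ssRows <- c(ssRows, paste(
        variation_id[i], sb$sig,
        if (is.na(sb$date)) "-" else sb$date, "-", "-", rep_pheno,
        if (isTRUE(sb$crit)) "criteria provided, single submitter" else
          "no assertion criteria provided",
        "clinical testing", "germline:1",
        sprintf("Lab%02d", k), sprintf("SCV%07d.1", 10000L * i + k),
        gene[i], sep = "\t"))
    }
  }
  paths$submission_summary <- file.path(out_dir, "submission_summary.txt.gz")
  .gzWriteLines(c(ssHeader, ssRows), paths$submission_summary)

  # ---- Concept IDs and golden table --------------------------------------
  paths$concept_ids <- file.path(out_dir, "concept_ids.txt")
  writeLines(c("C0000001", "C0000002"), paths$concept_ids)

  keep <- vapply(scenarios, function(s) identical(s$filter, "PASS"), logical(1))
  expected <- data.frame(
    label = labels[keep],
    chr = sprintf("chr%s", chroms[keep]),
    start = pos[keep],
    ref = ref[keep],
    alt = alt[keep],
    source_latest = vapply(scenarios[keep], function(s) s$latest[1L], ""),
    call_latest = vapply(scenarios[keep], function(s) s$latest[2L], ""),
    source_most_severe = vapply(scenarios[keep], function(s) s$ms[1L], ""),
    call_most_severe = vapply(scenarios[keep], function(s) s$ms[2L], ""),
    source_concept_latest = vapply(scenarios[keep], function(s) s$concept[1L], ""),
    call_concept_latest = vapply(scenarios[keep], function(s) s$concept[2L], ""),
    stringsAsFactors = FALSE
  )
  paths$expected_calls <- file.path(out_dir, "expected_calls.tsv")
  utils::write.table(expected, paths$expected_calls, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  invisible(list(paths = paths, expected = expected, dir = out_dir))
}

#' Random criteria vector for property tests
#'
#' Each boolean criterion is set independently with probability `p`; the
#' PVS1 strength is uniform over the five strength levels. Uses the current
#' RNG state (seed with [set.seed()]).
#'
#' @param p Probability that each boolean criterion is set.
#' @return A [CriteriaVector-class].
#' @export
randomCriteriaVector <- function(p = 0.2) {
  stopifnot(p >= 0, p <= 1)
  new("CriteriaVector",
      pvs1 = sample(.STRENGTH_LEVELS, 1L),
      ps = stats::runif(4) < p, pm = stats::runif(6) < p,
      pp = stats::runif(5) < p, ba1 = stats::runif(1) < p,
      bs = stats::runif(4) < p, bp = stats::runif(7) < p)
}

#' Random submission set for property tests
#'
#' Draws `n` submissions with significance over the five standard calls
#' plus occasional non-standard strings, random dates (some missing),
#' random assertion-criteria flags and random Concept IDs. Uses the current
#' RNG state.
#'
#' @param n Number of submissions (default drawn from 2..6).
#' @return A submission data.frame accepted by [resolveConflict()].
#' @export
randomSubmissionSet <- function(n = sample(2:6, 1L)) {
  sigs <- sample(c("Pathogenic", "Likely pathogenic",
                   "Uncertain significance", "Likely benign", "Benign",
                   "drug response", "risk factor"),
                 n, replace = TRUE,
                 prob = c(rep(0.17, 5), 0.075, 0.075))
  dates <- as.Date("2015-01-01") + sample.int(3000L, n, replace = TRUE)
  dates[stats::runif(n) < 0.2] <- NA
  df <- data.frame(
    variation_id = 1L,
    significance = sigs,
    date_last_evaluated = dates,
    assertion_criteria_provided = stats::runif(n) < 0.8,
    submitter = sprintf("Lab%02d", seq_len(n)),
    stringsAsFactors = FALSE
  )
  df$concept_ids <- lapply(seq_len(n), function(i)
    sample(c("C0000001", "C0000002", "C0000009"),
           sample.int(2L, 1L)))
  df
}
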