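Package: gvclass
Title: Germline Variant Pathogenicity Calls from ClinVar and Modified
    ACMG-AMP Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates ClinVar assertions and InterVar ACMG-AMP evidence
    vectors into a single five-level pathogenicity call (P/LP/VUS/LB/B)
    per germline variant. ClinVar classifications are used star-aware:
    two-or-more-star and one-star single-submitter calls are kept
    directly, one-star conflicting interpretations are resolved through a
    configurable decision tree (majority vote, then latest-submission or
    most-severe tiebreak, optionally restricted to submissions matching a
    MedGen Concept ID list). Variants without a usable ClinVar
    classification fall back to a modified InterVar classification: the
    deprecated PP5/BP6 criteria are removed, the loss-of-function PVS1
    criterion is re-weighted to the graded strength reported by AutoPVS1,
    and the five-level call is re-derived from the ACMG-AMP combining
    rules. Readers for the VEP-annotated VCF, ANNOVAR multianno, InterVar
    and AutoPVS1 tables and the three ClinVar distribution files are
    included, together with a synthetic fixture generator that covers
    every branch of the decision tree.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
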