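---
title: "How gvclass classifies germline variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How gvclass classifies germline variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvclass)
```

## The model

`gvclass` produces one call per germline variant on the five-level scale
B < LB < VUS < LP < P, by composing two evidence sources hierarchically.

**ClinVar, star-aware.** ClinVar's review status maps to a 0–4 star
confidence rating (`starsFromReviewStatus()`); the mapping is a fixed
table, and an unrecognized status is a hard error rather than a silent
zero-star downgrade, so that new ClinVar vocabulary has to be added
deliberately. Assertions with two or more stars, or one star from a single
submitter, are retained directly when their aggregate significance is
expressible on the five-level scale. One-star assertions with conflicting
interpretations are resolved per variant from the submission records
(`resolveConflict()`):

1. submissions with "no assertion criteria provided" are excluded;
2. submissions whose significance is not a standard five-level call
   (drug response, risk factor, `Affects`, ...) are excluded — such a vote
   cannot be expressed on the output scale;
3. if a MedGen Concept ID list is supplied, only submissions reporting a
   matching condition are kept (filter first, then vote);
4. if nothing remains the conflict is unresolved and the variant falls
   through to the rule engine;
5. a unique strictly-most-frequent call wins (*strict plurality*, not an
   absolute majority: plurality maximizes resolution while staying
   deterministic, and P and LP are counted as distinct calls — merging
   them would invent a rule the five-level scale does not state);
6. otherwise the configured tiebreak decides: `latest` takes the call of
   the maximum last-evaluated date, `most_severe` the severity maximum
   under P > LP > VUS > LB > B.

Zero-star assertions and non-standard aggregates count as *no ClinVar
classification*. This mirrors the practice of trusting criteria-based
curation while refusing to let uncurated or unexpressible assertions set
the call.

**Modified rule-engine classification.** Variants without a usable
ClinVar classification are re-scored from the InterVar evidence vector
(`intervarModifiedCall()`):

* **PP5/BP6 removal.** These "reputable source" criteria are largely
  derived from ClinVar itself; keeping them would double-count the ClinVar
  branch of this very pipeline. `stripPP5BP6()` clears exactly those two
  flags.
* **Graded PVS1.** InterVar applies PVS1 at full strength to every
  putative loss-of-function variant in a LOF-intolerant gene. Refined
  guidance grades PVS1 per variant as
  VeryStrong/Strong/Moderate/Supporting/Unmet; `applyPVS1Strength()`
  replaces InterVar's full-strength PVS1 with the graded strength reported
  by AutoPVS1. The adjustment is *demote-only*: the modification exists to
  correct over-calling, so a PVS1 that InterVar did not set is never
  introduced, and a variant with PVS1 set but no grading available keeps
  its strength with a warning.
* **Re-combination.** `combineCounts()` implements the standard ACMG-AMP
  combining table over bucket counts (PVS1 contributes to the bucket named
  by its strength; PS criteria are strong, PM moderate, PP supporting, BA1
  standalone benign, BS strong benign, BP supporting benign). Both
  "1 VeryStrong + 1 Moderate + 1 Supporting" and "1 VeryStrong + ≥2
  Supporting" are included among the pathogenic rules. When a
  pathogenic-group rule and a benign-group rule fire simultaneously the
  evidence is contradictory and the call is VUS; when nothing fires the
  call is VUS.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `tiebreak` | `"latest"` | Conflict tiebreak after the plurality vote: most recent evaluation date, or severity maximum (`"most_severe"`). |
| `concept_ids` | none | MedGen Concept IDs restricting which submissions may vote. Absent disables filtering; an empty set is rejected rather than silently matching nothing. |
| `filter_criteria` | `""` | Conjunctive `FIELD OP VALUE` record filters on INFO/FORMAT fields (e.g. `"DP>=10,AF<0.001"`), applied on top of the mandatory `FILTER == PASS`. A record missing the field fails the criterion and is dropped, with per-reason counts in the summary log. |
| `build` | `"GRCh38"` | Assembly used to select `variant_summary` rows. |

The defaults are deliberate: `latest` reflects that a more recent
evaluation has seen more evidence, and no concept filtering keeps the tool
disease-agnostic unless the analyst narrows it.

## Numerical and tie-breaking choices

* **Variant keys.** All four per-cohort tables are joined on a normalized
  key: `chr` prefix stripped, alleles uppercased, minimal representation
  obtained by right-trimming the shared suffix then left-trimming the
  shared prefix (position advances per trimmed leading base). Coordinates
  are 1-based throughout. Multi-allelic and symbolic records are rejected
  with instructions to pre-split: silently splitting here could
  desynchronize the annotation tables, which were computed on the split
  records upstream. Output contigs are re-emitted in the input VCF's style.
* **ANNOVAR-coordinate bridge.** InterVar rows carry ANNOVAR-style
  (indel-shifted, `-`-allele) coordinates. They are mapped back to VCF keys
  through the multianno table, which shares those coordinates *and* carries
  the original VCF columns (`--vcfinput` layout); plain-allele rows fall
  back to direct normalization. ANNOVAR columns are otherwise pass-through
  annotation only — classification never depends on them.
* **Aggregate authority.** Significance and review status come from
  `variant_summary` (the per-assembly authority); the ClinVar VCF supplies
  the key-to-VariationID map. Disagreements are logged and
  `variant_summary` wins.
* **Combined aggregates.** `Pathogenic/Likely pathogenic` maps to LP and
  `Benign/Likely benign` to LB — the weaker assertion, the conservative
  reading of an aggregate that does not commit to the stronger call.
* **Dateless submissions** rank lowest for the `latest` tiebreak; ties at
  the maximum date (including the all-dateless case) are broken by the
  severity maximum, giving a deterministic total order.
* **Evidence values above 1** in InterVar's printed lists (user-upgraded
  criteria) are treated as set; surplus trailing slots in the bracketed
  lists (InterVar reserves extras) are ignored.
* **Missing InterVar rows** for a variant with no ClinVar call yield VUS
  with a `no_evidence` note and a warning — partial annotation runs stay
  loud but never silently drop records.

## What the synthetic generator emulates — and what it does not

`generateBundle()` writes a coherent miniature of all seven inputs plus a
golden `expected_calls.tsv`. The default catalog (63 scenarios, 62
surviving `PASS`) covers every branch of the decision tree: direct
retention at 1–4 stars, every five-level call from both sources, conflicts
resolved by plurality, by both tiebreaks, with dateless/criteria-less/
non-standard submissions, fully excluded conflicts, Concept-ID filtering
(including filter-to-empty), the PP5-removal demotion, the full
PVS1-downgrade ladder, evidence contradictions, a non-PASS record, an
ANNOVAR-shifted indel, and a multi-transcript record. Every expectation in
the golden table was derived by hand-tracing the scenario through the
rules above — never by running the pipeline — so the end-to-end test is an
independent check. ClinVar review-status strings use the current ClinVar
vocabulary verbatim so the star mapping is exercised against realistic
text.

The generator does **not** emulate realistic allele-frequency spectra,
sequencing artifacts, multi-sample cohorts, or the scale and annotation
noise of real ClinVar releases. Passing tests therefore demonstrate the
correctness of the decision logic and file-dialect handling, not
robustness to upstream annotation errors.

## Verification strategy and problem sizes

The test suite checks, at sizes chosen to run comfortably on one CPU:

* exhaustive agreement of `combineCounts()` with an independently coded
  brute-force enumeration of the combining table on all 47,040 bounded
  count tuples (very-strong ≤ 1, strong ≤ 5, moderate ≤ 7, supporting ≤ 6,
  standalone ≤ 1, strong-benign ≤ 4, supporting-benign ≤ 6);
* monotonicity on 10,000 seeded random criteria vectors: clearing any
  single pathogenic criterion never raises severity, clearing any benign
  criterion never lowers it;
* the modification property on 2,000 vectors: PP5 stripping plus
  demote-only PVS1 grading never raises severity relative to the raw
  combination. This holds for the *pathogenic-side* modification, as
  tested on vectors without BP6: removing BP6 deletes benign evidence and
  can legitimately raise a call (e.g. BP4+BP6 = LB becomes VUS), so the
  property is stated and tested conditional on BP6 being absent;
* the conflict-resolution order property on 1,000 random submission sets
  (`most_severe` never less severe than `latest`; plurality outcomes
  permutation-invariant);
* golden-table agreement of the full pipeline under all three run modes,
  byte-identical across repeated runs; conservation (every surviving
  record appears exactly once in both outputs, ClinVar-sourced rows carry
  ≥ 1 star).

## Known limitations

Gene-specific ClinGen VCEP rule sets are not incorporated; variants in
genes with VCEP specifications deserve manual review. The tool is for
germline analysis only, assumes pre-split single-sample VCFs on one
genome build (no liftover), and consumes — rather than computes — the
upstream VEP/ANNOVAR/InterVar/AutoPVS1 annotations.
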