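# gvclass

Germline variant pathogenicity calls from ClinVar and modified ACMG-AMP
evidence.

## The problem

Research cohorts routinely need five-level pathogenicity calls —
Pathogenic (P), Likely Pathogenic (LP), Uncertain Significance (VUS),
Likely Benign (LB), Benign (B) — for hundreds of thousands of germline
variants at once. Two complementary evidence sources exist. ClinVar holds
curated assertions, but of very uneven review quality (0–4 stars) and often
with conflicting submissions. Rule engines such as InterVar score the
ACMG-AMP criteria (PVS1, PS1–4, PM1–6, PP1–5, BA1, BS1–4, BP1–7) for any
variant, but two of their habits are now considered misclassification
risks: applying the loss-of-function criterion PVS1 at full strength to
every putative LOF variant, and crediting "reputable source" assertions via
PP5/BP6, which double-counts ClinVar.

`gvclass` integrates both sources into one deterministic call per variant:

1. **ClinVar first, star-aware.** Assertions with ≥ 2 stars, or 1 star from
   a single submitter, are kept directly. 1-star conflicting
   interpretations go through a resolution tree: drop submissions without
   assertion criteria and those not expressible on the five-level scale,
   optionally restrict to submissions matching a MedGen Concept ID list,
   take the strict-plurality call if one exists, otherwise tiebreak by the
   most recently evaluated submission (`latest`, the default) or by
   `severity_max` under P > LP > VUS > LB > B (`most_severe`). Zero-star
   and non-standard assertions (e.g. `Affects|risk_factor`) count as no
   ClinVar classification.
2. **Modified InterVar for the rest.** The InterVar evidence vector is
   re-scored: PP5/BP6 are removed, PVS1 is demoted to the graded strength
   reported by AutoPVS1 (VeryStrong/Strong/Moderate/Supporting/Unmet;
   never upgraded), and the call is re-derived from the standard ACMG-AMP
   combining rules, with contradictory evidence resolving to VUS.

Inputs are the user's VEP-annotated VCF, the ANNOVAR `--vcfinput`
multianno table, the InterVar output table, the AutoPVS1 output table, and
the three ClinVar distribution files (`clinvar.vcf.gz`,
`variant_summary.txt.gz`, `submission_summary.txt.gz`). Records are first
filtered to `FILTER == PASS` plus any user criteria (e.g. `DP>=10`).
Outputs are an abridged and a full TSV, one row per surviving variant,
annotated to a single primary transcript (the AutoPVS1-graded one when it
matches a CSQ entry) with the remaining transcript annotations retained in
`csq_vep`.

## Worked example

The package ships a synthetic fixture generator that emits a coherent
miniature version of all seven inputs (62 PASS scenarios covering every
branch of the decision tree):

```r
library(gvclass)

bundle <- generateBundle(scenarioCatalog(), seed = 7, out_dir = "demo")
cfg <- runConfig(
  vep_vcf = bundle$paths$vep_vcf,
  multianno = bundle$paths$multianno,
  intervar = bundle$paths$intervar,
  autopvs1 = bundle$paths$autopvs1,
  clinvar_vcf = bundle$paths$clinvar_vcf,
  variant_summary = bundle$paths$variant_summary,
  submission_summary = bundle$paths$submission_summary,
  tiebreak = "latest", out_prefix = "demo/out")
res <- runPipeline(cfg)
res$counts
#>               n_input              not_pass          n_classified
#>                    63                     1                    62
#>      n_clinvar_direct    n_clinvar_majority      n_clinvar_latest
#>                    15                     7                    12
#> n_clinvar_most_severe            n_intervar         n_no_evidence
#>                     0                    28                     1
head(read.delim("demo/out.abridged.tsv"), 2)
#>    chr  start ref alt    gene     transcript final_call call_source clinvar_stars resolution_method
#> 1 chr1 126067   G   T GENE001 ENST00000001.2          P     ClinVar             2            direct
#> 2 chr2 222287   C   G GENE002 ENST00000002.2         LP     ClinVar             2            direct
```

63 input records: one fails `PASS`, 34 calls come from ClinVar (15 kept
directly, 19 resolved from conflicting 1-star submissions) and 28 from the
modified InterVar re-scoring, including one variant present in neither
source, which is emitted as VUS with a `no_evidence` note rather than
dropped. A run writes `<prefix>.abridged.tsv`, `<prefix>.full.tsv`, the
resolved ClinVar subset `<prefix>.clinvar_subset.tsv` and a
machine-readable `<prefix>.summary.log`.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/gvclass` (subcommands `run`, `select-submissions`,
`make-fixtures`).

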