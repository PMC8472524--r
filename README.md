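# panelclassify

Downstream analysis toolkit for **tumor-only targeted cancer panels**,
aimed at laboratories whose patients are under-represented in public
germline databases. Without a matched normal, somatic status must be
inferred from database evidence — and when the patient's population is
missing from those databases, ordinary inherited variants masquerade as
somatic mutations. `panelclassify` implements the full downstream chain:

1. **Consensus calling** — per-caller VCFs are normalized (multi-allelic
   split, minimal anchored alleles) and merged by majority vote: an SNV is
   reported when called by ≥ 3 of 5 SNV callers, an indel by ≥ 3 of 6.
2. **Filtering** — limit of detection (keep iff VAF ≥ 0.05 **and** alt
   reads ≥ 12) and population-polymorphism removal (drop iff any database
   AF — including every subpopulation column and a local germline
   database — is strictly > 0.01).
3. **Six-category classification** — an ordered, auditable rule set over
   COSMIC / dbSNP / ClinVar / population-database / local-database
   evidence and germline VAF bands ([0.40, 0.60] het, [0.90, 1.00] hom)
   assigns `germline`, `putative_germline`, `putative_novel_germline`,
   `somatic`, `putative_somatic`, or `putative_novel_somatic`, recording a
   `rule_trail` per variant.
4. **Panel QC** — per-sample coverage fractions at 100–500×, uniformity
   (fraction of bases ≥ 0.2 × mean depth), and the pass rule: ≥ 80% of
   target regions at ≥ 300× (somatic) / ≥ 200× (germline). Failing
   samples are reported and skipped.
5. **Biomarker reporting** — somatic-family variants are matched against
   a tiered drug-evidence knowledge base
   (`fda_guidelines > clinical_guidelines > late_trials > early_trials >
   case_report > pre_clinical`), plus cohort summaries: per-category
   counts, gene × tumor-type matrices, percentage formatting, VAF and
   variant-set concordance.
6. **Synthetic cohorts** — a seeded generator emits per-caller VCFs,
   annotations, depth tables and ground truth (germline het/hom, somatic,
   low-VAF C>T/G>A FFPE artifacts) so the whole pipeline is testable
   end-to-end with no external data.

## Worked example

```r
library(panelclassify)

# simulate an 8-sample cohort and run the full pipeline on it
sim <- generate_cohort(cohort_config(seed = 42), "cohort")
res <- run_pipeline("cohort", "out",
                    run_config(kb_path = system.file(
                      "extdata", "kb_clinical.tsv",
                      package = "panelclassify")))
res$category_summary
#>                  category total unique
#> 1                germline    44     44
#> 2       putative_germline    24     24
#> 3 putative_novel_germline    14     14
#> 4                 somatic    31     31
#> 5        putative_somatic     5      5
#> 6  putative_novel_somatic     9      9
#> 7                   total   127    127

rm <- recovery_metrics(sim$truth, res$classified)
rm$ffpe_in_somatic_output
#> [1] 0
```

Reading the output: of the 216 simulated truth variants, 127 survive
consensus, the LOD filter and the polymorphism filter and get classified;
the germline rows are inherited variants correctly kept *out* of the
somatic report, and no FFPE deamination artifact reached the somatic
output. Under the generator's default (deliberately noisy) settings some
truth variants are ambiguous — e.g. a clonal somatic variant at VAF 0.50
is indistinguishable from a germline het — which is why recovery is only
perfect under the unambiguous validation regime described in the
vignette (`vignettes/panel-workflow.Rmd`).

A thin command-line wrapper ships in `exec/panelclassify`
(`simulate`, `consensus`, `classify`, `qc`, `report`, `run`).

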