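---
title: "Tumor-only panel analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-only panel analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelclassify)
```

## The problem

Targeted cancer panels are increasingly run *tumor-only*: sequencing a
matched normal doubles the cost per patient, which is exactly the barrier
such panels are meant to lower. Without a matched normal, separating
somatic mutations from germline variants has to rely on population
allele-frequency databases — and those databases under-represent many
populations (Latin American genomes in particular), so a patient's
ordinary inherited variants are easily mistaken for somatic events.
`panelclassify` implements the downstream computation of such a workflow:
merging the output of several somatic callers into consensus calls,
filtering by limit of detection and population frequency with
subpopulation awareness, classifying what remains into six origin
categories, gating samples on panel coverage QC, and matching somatic
variants to a tiered drug-evidence knowledge base.

## Consensus calling

Each caller's VCF is normalized (multi-allelic records split, alleles
reduced to the minimal anchored form) so that calls are comparable across
callers. A variant is reported when at least `min_support_snv = 3` of the
five SNV callers (default set: Mutect2, VarScan2, VarDict, LoFreq,
Strelka) support it, or at least `min_support_indel = 3` of the six indel
callers (the same five plus Scalpel). The indel set treats all six
callers as equal voters.

Two points are deliberately explicit because upstream ensemble tools
leave them implicit:

* **Non-PASS calls.** Records failing a caller's own `FILTER` are kept in
  the call table but flagged, and by default do *not* count as support
  (`count_nonpass = FALSE`). The ensemble behaviour being mirrored
  consumes caller-filtered calls, but the choice is configurable because
  it is a convention, not a law.
* **VAF aggregation.** One VAF must be reported per consensus variant.
  The default is the per-field median across supporting callers (even
  counts: mean of the two middle values; depths rounded half-up), which
  is robust to a single outlier caller. A `primary_caller` mode reports
  one designated caller's fields instead.

## Filtering

Two filters precede classification, with boundary semantics taken
literally from the validated operating point:

* **Detection limit**: keep iff `vaf >= 0.05` **and** `alt_depth >= 12`
  (both inclusive). VAF 0.05 with 12 alt reads is kept; 0.04 or 11 reads
  is dropped, with every failed criterion enumerated in the drop reason.
* **Population filter**: drop iff the *maximum* allele frequency over
  every population database column — including every subpopulation column
  (e.g. `gnomad_genome_AMR`) and, by default, a local germline database —
  is *strictly greater* than 0.01. An AF of exactly 0.01 is kept; a
  variant absent from every database is kept. Absence is represented as
  `NA` and is distinct from an AF of zero throughout the annotation I/O.

The local germline database plays two roles: it participates in the
population-filter maximum *and* it is direct germline evidence in
classification rule R1. Both uses can be decoupled with
`local_db_in_pop_filter = FALSE`; the default keeps both because a locally
common allele is exactly the kind of variant the workflow exists to stop
mislabelling as somatic.

## Six-category classification

Variants surviving both filters are classified by an ordered,
first-match-wins rule set over the available database evidence (COSMIC,
dbSNP, ClinVar, population databases, local database) and the variant's
VAF relative to two *germline bands*: `[0.40, 0.60]` (heterozygous
expectation) and `[0.90, 1.00]` (homozygous expectation). The bands are a
design choice — tumor-only data gives no numeric bands for free — and sit
where a diploid germline variant is expected in a tumor sample of
moderate purity. The rules:

| rule | condition | category |
|------|-----------|----------|
| R1 | ClinVar asserts germline, or present in local DB | germline |
| R2 | COSMIC, no PVD/dbSNP record | somatic |
| R3 | COSMIC + PVD/dbSNP, VAF outside bands | putative somatic |
| R4 | PVD/dbSNP, VAF inside a band | putative germline |
| R5 | PVD/dbSNP, no COSMIC, VAF outside bands | putative somatic |
| R6 | no database evidence | putative novel germline (in band) / putative novel somatic |

The rule set is data: an ordered list of predicates that can be permuted
or edited without code changes, and each classified variant carries a
`rule_trail` recording the evaluation path, so any assignment can be
audited. The order matters on genuinely ambiguous records (COSMIC +
dbSNP + in-band VAF resolves to R4 before R5 by default), and the tests
pin the default order with golden assignments.

A germline hard-filter stage for haplotype-caller output is provided
separately (`apply_germline_hard_filters()`): fail below call confidence
30 or when any present annotation metric violates its class-specific
bound (SNP: `QD < 2`, `FS > 60`, `MQ < 40`, `MQRankSum < -12.5`,
`ReadPosRankSum < -8`; indel: `QD < 2`, `FS > 200`,
`ReadPosRankSum < -20`); absent metrics never fail.

## Panel QC

Per sample: mean on-target depth, the fraction of target regions covered
at 100–500x, uniformity, and optional upstream read metrics (raw reads,
filtered fraction, duplication rate, on-target reads — ingested from
upstream tool summaries, since alignment is out of scope). Two
definitions are nailed down explicitly because the field often leaves
them vague:

* **Uniformity** = fraction of target bases at or above 0.2 x the mean
  target depth (the factor is configurable). This definition is invariant
  under uniform depth scaling.
* **Region coverage** uses the *mean* depth per region by default
  (per-base minimum is available), and the pass rule is inclusive:
  somatic mode requires at least 80% of regions at >= 300x, germline mode
  at least 80% at >= 200x. Failing samples stay in the QC report but are
  skipped for classification; the cohort proceeds.

## Biomarker matching

The knowledge base is a static, versioned TSV of rules (gene, exact
protein change or gene-level, drug, responsive/resistant, evidence tier,
tumor types). Tiers form a total order —
`fda_guidelines > clinical_guidelines > late_trials > early_trials >
case_report > pre_clinical` — and duplicate rules collapse to the highest
tier, as do multiple matches for one (variant, drug) pair. Exact
protein-change rules are tried first; gene-level rules apply to any
protein-affecting variant of the gene. Only somatic-family variants
(`somatic`, `putative_somatic`, `putative_novel_somatic`) are eligible by
default. A rule's tumor-type applicability is reported but never
suppresses a hit; indication filtering belongs to the consumer.
Packaged fixtures carry the panel's gene/drug associations and the
guideline-supported biomarker tables as machine-readable TSVs.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions under
which every downstream claim is demonstrated.

* **Truth variants** per sample: heterozygous germline (VAF drawn in
  `[0.42, 0.58]`), homozygous germline (`[0.92, 1.00]`), somatic (drawn
  from the grid `{0.01, 0.02, 0.05, 0.10, 0.25, 0.50}`, spanning
  below-LOD to clonal), and FFPE artifacts — always C>T or G>A at VAF
  below 0.05 (default `[0.005, 0.03]`), mimicking formalin-induced
  cytosine deamination.
* **Reads**: per sample x variant one total depth (Poisson around the
  sample mean, default 500x) and one binomial alt depth are drawn and
  shared by all callers, mirroring the fact that real callers look at the
  same alignment.
* **Detection**: each caller independently detects a variant with
  probability given by a logistic curve in the *true* VAF with a
  per-caller midpoint (defaults between 0.015 and 0.03, slope 250).
  `slope = Inf` degenerates to a step function. The logistic parameters
  are synthetic knobs, not estimates of any real caller's sensitivity.
* **Databases**: each variant carries a profile — `cosmic_only`,
  `pvd_rare` (all AFs in (0, 0.01)), `pvd_common` (some AF > 0.01),
  `local_db` (local AF in (0, 0.01]), or `novel` (no entries) — realized
  in the annotation table.

Default cohort: 8 samples x 27 variants = 216 truth variants, sized so
the full pipeline plus tests run in seconds on one CPU. The synthetic
panel uses the 25 real panel genes but two 150 bp regions per gene
(7.5 kb), a deliberately scaled-down target space; QC depth tables are
generated per base over that space.

### What the unambiguous validation regime is, and why

Several invariants are demonstrated on an "unambiguous" configuration:
step detection with every midpoint at the LOD (detection probability 1 at
or above 0.05, 0 below), somatic VAFs restricted to `{0.10, 0.25}` at
mean depth 800, germline het/hom VAFs centered at `[0.48, 0.52]` /
`[0.94, 0.97]`, and no `pvd_common` profile on somatic truth. Under this
regime end-to-end somatic-family vs germline-family recovery is 100% and
zero FFPE artifacts reach the somatic output — the latter *guaranteed*,
because an artifact below the LOD is never detected by any caller.

Each restriction removes a case that is ambiguous *by construction*, not
a weakness of the implementation: a true somatic variant at exactly VAF
0.05 realizes below the LOD about half the time through binomial noise
alone; a novel somatic variant at VAF 0.50 is mathematically
indistinguishable from a heterozygous germline variant in tumor-only
data; and a somatic variant that is also a common polymorphism is removed
by design. Under the soft default logistic, a borderline FFPE artifact
can occasionally leak past the LOD — which is also what happens with real
FFPE libraries; the tests therefore check artifact absence exactly under
step detection and empirically across seeds under the defaults.

Passing on this synthetic regime shows the plumbing and the decision
logic are correct at the stated operating point. It does not show
performance on real tumors: the generator has no mapping artifacts, no
strand bias, no correlated caller errors, no tumor purity or copy-number
effects on VAF, and database profiles are cleanly one thing or another.

## Numerical and degenerate-input choices

* Half-up rounding for reported percentages and aggregated depths
  (`percent(111, 131, 0) = 85`), not R's round-half-to-even.
* Uniformity of an all-zero depth profile is 0; empty depth vectors and
  empty region lists are errors, not silent zeros.
* Pearson correlation refuses zero-variance inputs rather than returning
  `NA`.
* Variant order in every output is `(chrom, pos, ref, alt)` with plain
  lexicographic contig order; no timestamps enter any data file, so equal
  seeds give byte-identical outputs (checksummed in `manifest.json`).
* Tabular outputs pipe-join multi-valued fields (`supporting_callers`,
  `rule_trail`) so they survive a VCF `INFO` round trip.

## Known limitations

* The six-rule tree is one concrete instantiation of the
  evidence-hierarchy approach to tumor-only classification; sites using a
  different tree can express it as a rule list, but no attempt is made to
  learn rules from data.
* Germline bands ignore tumor purity and copy number; a deletion over a
  germline het site will push it out of band and toward a putative
  somatic label.
* Biomarker matching is string-exact on HGVS-p short forms; no protein
  -level normalization (e.g. `p.` prefixes, three-letter codes) is
  attempted.
* The CLI (`exec/panelclassify`) is a thin wrapper; orchestration beyond
  one cohort directory (schedulers, containers) is out of scope.
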