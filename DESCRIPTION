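Package: panelclassify
Title: Consensus Calling, Tumor-Only Classification and Biomarker
    Reporting for Targeted Cancer Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis toolkit for tumor-only targeted
    sequencing panels. Merges per-caller VCFs into consensus somatic
    calls by majority vote, applies limit-of-detection and
    population-allele-frequency filters with subpopulation awareness,
    classifies variants into six somatic/germline origin categories
    designed for populations under-represented in germline databases,
    computes per-sample panel coverage QC with pass/fail thresholds,
    and matches somatic variants against a tiered drug-biomarker
    knowledge base. Ships a synthetic multi-caller cohort generator
    with known ground truth so every stage is testable end to end
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
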