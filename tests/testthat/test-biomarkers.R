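test_that("knowledge base loads, validates, and collapses duplicates", {
  kb <- load_knowledge_base(extdata("kb_clinical.tsv"))
  expect_true(all(kb$evidence_tier %in% evidence_tiers()))
  expect_true(all(kb$effect %in% c("responsive", "resistant")))
  kras <- kb[kb$gene == "KRAS" & kb$protein_change == "G12D", ]
  expect_setequal(kras$drug, c("Panitumumab", "Cetuximab"))
  expect_true(all(kras$effect == "resistant"))

  # duplicate rows collapse to the highest tier
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "gene\tmatch_kind\tprotein_change\tdrug\teffect\tevidence_tier\ttumor_types",
    "KRAS\texact_protein_change\tG12D\tCetuximab\tresistant\tearly_trials\t",
    "KRAS\texact_protein_change\tG12D\tCetuximab\tresistant\tfda_guidelines\t"
  ), tmp)
  collapsed <- load_knowledge_base(tmp)
  expect_equal(nrow(collapsed), 1L)
  expect_equal(collapsed$evidence_tier, "fda_guidelines")

  # unknown tier label rejected
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "gene\tmatch_kind\tprotein_change\tdrug\teffect\tevidence_tier\ttumor_types",
    "KRAS\texact_protein_change\tG12D\tCetuximab\tresistant\tphase4\t"
  ), tmp2)
  expect_error(load_knowledge_base(tmp2), "unknown evidence tier")
})

test_that("biomarker matching hits exact rules and dedups at highest tier", {
  kb <- load_knowledge_base(extdata("kb_clinical.tsv"))
  cls <- data.frame(
    sample_id = "s1", chrom = "chr12", pos = 25398284L, ref = "C", alt = "T",
    gene = c("KRAS", "TP53"), consequence = "missense",
    protein_change = c("G12D", "R175H"), vaf = 0.3,
    category = "somatic", stringsAsFactors = FALSE
  )
  hits <- match_biomarkers(cls, kb)
  expect_setequal(hits$drug, c("Panitumumab", "Cetuximab"))
  cet <- hits[hits$drug == "Cetuximab", ]
  expect_equal(cet$effect, "resistant")
  expect_equal(cet$evidence_tier, "fda_guidelines")
  # TP53 has no drug rules in this KB -> no hits
  expect_false("TP53" %in% hits$gene)

  # only somatic-family categories are eligible by default
  cls$category <- "germline"
  expect_equal(nrow(match_biomarkers(cls, kb)), 0L)

  # exact + gene-level rules for the same drug collapse to the higher tier
  kb2 <- rbind(kb[kb$gene == "KRAS" & kb$protein_change == "G12D", ][1, ],
               data.frame(gene = "KRAS", match_kind = "gene_level",
                          protein_change = "", drug = "Cetuximab",
                          effect = "resistant", evidence_tier = "case_report",
                          tumor_types = ""))
  cls$category <- "somatic"
  h2 <- match_biomarkers(cls[1, ], kb2)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$evidence_tier, "fda_guidelines")
})

test_that("gene-level rules apply only to protein-affecting variants", {
  kb <- data.frame(gene = "PTEN", match_kind = "gene_level",
                   protein_change = "", drug = "Everolimus",
                   effect = "responsive", evidence_tier = "late_trials",
                   tumor_types = "", stringsAsFactors = FALSE)
  base <- data.frame(sample_id = "s1", chrom = "chr10", pos = 1L, ref = "A",
                     alt = "T", gene = "PTEN", protein_change = "X1Y",
                     vaf = 0.2, category = "putative_novel_somatic",
                     stringsAsFactors = FALSE)
  frameshift <- base; frameshift$consequence <- "frameshift_del"
  silent <- base; silent$consequence <- "synonymous"
  expect_equal(nrow(match_biomarkers(frameshift, kb)), 1L)
  expect_equal(nrow(match_biomarkers(silent, kb)), 0L)
})

test_that("classification summary counts totals and unique keys", {
  cls <- data.frame(
    sample_id = c("s1", "s2", "s3", "s1"),
    chrom = "chr1", pos = c(10L, 10L, 10L, 20L), ref = "A", alt = "T",
    category = c("somatic", "somatic", "somatic", "germline"),
    stringsAsFactors = FALSE
  )
  tab <- summarize_classification(cls)
  expect_equal(tab$total[tab$category == "somatic"], 3L)
  expect_equal(tab$unique[tab$category == "somatic"], 1L)
  expect_equal(tab$total[tab$category == "total"], 4L)
  # all six categories always reported, zeros included
  expect_setequal(setdiff(tab$category, "total"), variant_categories())
  # permutation invariance
  perm <- summarize_classification(cls[sample(4), ])
  expect_equal(perm, tab)
  # empty input -> all-zero table
  empty <- summarize_classification(cls[0, ])
  expect_true(all(empty$total == 0L))
})

test_that("gene-by-tumor matrix counts cells and marginals correctly", {
  cls <- data.frame(
    sample_id = c("s1", "s1", "s2"), chrom = "chr1", pos = 1:3, ref = "A",
    alt = "T", gene = c("TP53", "KRAS", "TP53"), consequence = "missense",
    category = "somatic", stringsAsFactors = FALSE
  )
  meta <- data.frame(sample_id = c("s1", "s2"),
                     tumor_type = c("ovary", "breast"),
                     stringsAsFactors = FALSE)
  gm <- gene_tumor_matrix(cls, meta)
  expect_equal(gm$counts["TP53", "ovary"], 1L)
  expect_equal(unname(gm$gene_totals["TP53"]), 2L)
  expect_equal(sum(gm$counts), nrow(cls))
  expect_error(gene_tumor_matrix(cls, meta[1, , drop = FALSE]),
               "without metadata: s2")

  # cell sums equal variant count on random synthetic cohorts
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    rc <- data.frame(sample_id = sample(c("a", "b", "c"), n, replace = TRUE),
                     chrom = "chr1", pos = seq_len(n), ref = "A", alt = "T",
                     gene = sample(c("TP53", "KRAS", "PTEN"), n, TRUE),
                     consequence = sample(c("missense", "nonsense"), n, TRUE),
                     category = "somatic", stringsAsFactors = FALSE)
    mt <- data.frame(sample_id = c("a", "b", "c"),
                     tumor_type = c("ovary", "breast", "ovary"))
    gm <- gene_tumor_matrix(rc, mt)
    expect_equal(sum(gm$counts), n)
    expect_equal(sum(gm$by_consequence$n), n)
    expect_equal(unname(colSums(gm$counts)), unname(gm$type_totals))
  }
})

test_that("percent rounds half-up at the requested precision", {
  expect_equal(percent(137, 197, 1), 69.5)
  expect_equal(percent(116, 164, 0), 71)
  expect_equal(percent(1, 3, 1), 33.3)
  expect_equal(percent(1, 8, 1), 12.5)
  expect_equal(percent(1, 16, 1), 6.3)  # 6.25 rounds up, not to even
  expect_error(percent(1, 0), "denominator")
})

test_that("VAF concordance equals the textbook covariance formula", {
  x <- c(0.1, 0.2, 0.3); y <- c(0.1, 0.2, 0.3)
  expect_equal(vaf_concordance(x, y)$r, 1.0)
  expect_equal(vaf_concordance(x, -x)$r, -1.0)
  set.seed(2)
  for (rep in 1:20) {
    a <- runif(sample(3:50, 1)); b <- runif(length(a))
    r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(vaf_concordance(a, b)$r, r_oracle, tolerance = 1e-12)
  }
  expect_error(vaf_concordance(c(0.1, 0.1), c(0.1, 0.2)), "zero variance")
  expect_error(vaf_concordance(0.1, 0.2), "at least 2")
})

test_that("set concordance computes shared/only/jaccard on keys", {
  a <- sprintf("chr1:%d:A:T", 1:7)
  expect_equal(set_concordance(a, a),
               list(shared = 7L, only_a = 0L, only_b = 0L, jaccard = 1.0))
  b <- sprintf("chr2:%d:A:T", 1:3)
  expect_equal(set_concordance(a, b)$jaccard, 0.0)
  res <- set_concordance(c("v1", "v2", "v3"), c("v2", "v3", "v4"))
  expect_equal(res, list(shared = 2L, only_a = 1L, only_b = 1L,
                         jaccard = 0.5))
})
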