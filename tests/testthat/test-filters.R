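test_that("detection filter boundaries are inclusive and reasons enumerate", {
  cfg <- filter_config()
  v <- make_consensus_row(pos = c(1L, 2L, 3L, 4L),
                          vaf = c(0.05, 0.04, 0.20, 0.04),
                          alt_depth = c(12L, 30L, 11L, 11L))
  out <- apply_detection_filters(v, cfg)
  expect_equal(out$keep, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$drop_reason,
               c("", "low_vaf", "low_alt_depth", "low_vaf|low_alt_depth"))
})

test_that("max population AF spans all databases including the local one", {
  ann <- rbind(
    make_annotation(pos = 1L, gnomad_genome_ALL = 0.002,
                    gnomad_genome_AMR = 0.015),
    make_annotation(pos = 2L),
    make_annotation(pos = 3L, g1000_ALL = 0.009, local_db_af = 0.03)
  )
  m <- max_population_af(ann)
  expect_equal(m[[1]], 0.015)
  expect_true(is.na(m[[2]]))
  expect_equal(m[[3]], 0.03)
  expect_equal(max_population_af(ann, include_local = FALSE)[[3]], 0.009)
})

test_that("population filter is strict (> 0.01 drops, 0.01 keeps)", {
  cfg <- filter_config()
  ann <- rbind(
    make_annotation(pos = 1L, gnomad_genome_ALL = 0.02),
    make_annotation(pos = 2L, gnomad_genome_ALL = 0.01),
    make_annotation(pos = 3L)
  )
  v <- make_consensus_row(pos = c(1L, 2L, 3L))
  out <- apply_population_filter(v, ann, cfg)
  expect_equal(out$keep, c(FALSE, TRUE, TRUE))
  expect_equal(out$drop_reason[1], "common_polymorphism")
})

test_that("filter monotonicity: relaxing thresholds never removes variants", {
  set.seed(5)
  v <- make_consensus_row(pos = seq_len(50L), vaf = runif(50),
                          alt_depth = sample(0:60, 50, replace = TRUE))
  strict <- apply_detection_filters(v, filter_config(min_vaf = 0.10,
                                                     min_alt_reads = 20))
  lax <- apply_detection_filters(v, filter_config(min_vaf = 0.05,
                                                  min_alt_reads = 12))
  expect_true(all(which(strict$keep) %in% which(lax$keep)))
})

test_that("classification follows the ordered rules with a rule trail", {
  cfg <- filter_config()
  ann <- rbind(
    make_annotation(pos = 1L, cosmic_id = "COSM1", cosmic_count = 12L),
    make_annotation(pos = 2L),
    make_annotation(pos = 3L, dbsnp_id = "rs2", gnomad_genome_AMR = 0.004),
    make_annotation(pos = 4L, local_db_af = 0.002),
    make_annotation(pos = 5L, clinvar_sig = "pathogenic_germline"),
    make_annotation(pos = 6L, cosmic_id = "COSM6", cosmic_count = 3L,
                    dbsnp_id = "rs6"),
    make_annotation(pos = 7L, cosmic_id = "COSM7", cosmic_count = 3L,
                    dbsnp_id = "rs7")
  )
  v <- make_consensus_row(pos = 1:7,
                          vaf = c(0.12, 0.48, 0.23, 0.30, 0.95, 0.20, 0.50))
  cls <- classify_variants(v, ann, cfg)
  expect_equal(cls$category, c(
    "somatic",                  # COSMIC only, R2
    "putative_novel_germline",  # no evidence, VAF in band, R6
    "putative_somatic",         # dbSNP+PVD, no COSMIC, out of band, R5
    "germline",                 # local DB, R1
    "germline",                 # ClinVar germline, R1
    "putative_somatic",         # COSMIC + dbSNP, out of band, R3
    "putative_germline"         # COSMIC + dbSNP but VAF in band, R4
  ))
  expect_equal(cls$rule_trail[1], "R1|R2")
  expect_equal(cls$rule_trail[2], "R1|R2|R3|R4|R5|R6")
  expect_equal(cls$rule_trail[3], "R1|R2|R3|R4|R5")
  # exactly one category each; partition over categories is complete
  expect_true(all(cls$category %in% variant_categories()))
  expect_equal(sum(table(cls$category)), nrow(v))
})

test_that("permuting the rule order changes ambiguous assignments", {
  cfg <- filter_config()
  # COSMIC + dbSNP + VAF inside a band: R3 vs R4 order matters
  ann <- make_annotation(pos = 7L, cosmic_id = "COSM7", cosmic_count = 3L,
                         dbsnp_id = "rs7")
  v <- make_consensus_row(pos = 7L, vaf = 0.50)
  rules <- default_classification_rules()
  ids <- vapply(rules, `[[`, "", "id")
  permuted <- rules[match(c("R1", "R2", "R5", "R4", "R3", "R6"), ids)]
  default_cat <- classify_variants(v, ann, cfg)$category
  # R4 still precedes R3 in the permuted order here, so craft the reverse:
  swapped <- rules[match(c("R1", "R2", "R4", "R3", "R5", "R6"), ids)]
  expect_equal(default_cat, "putative_germline")
  expect_equal(classify_variants(v, ann, cfg, rules = swapped)$category,
               "putative_germline")
  # moving R3 ahead of R4 with the band test removed from R3 flips it
  r3_noband <- rules
  r3_noband[[3]]$when <- function(e) e$has_cosmic && (e$has_pvd || e$has_dbsnp)
  expect_equal(classify_variants(v, ann, cfg, rules = r3_noband)$category,
               "putative_somatic")
})

test_that("a kept variant without annotation is a classification error", {
  v <- make_consensus_row(pos = 999L)
  expect_error(classify_variants(v, make_annotation(pos = 1L),
                                 filter_config()),
               "classification error.*chr1:999")
})

test_that("germline hard filters honor qual and class-specific bounds", {
  nominal <- list(qual = 50, QD = 10, FS = 5, MQ = 60, MQRankSum = 0,
                  ReadPosRankSum = 0)
  expect_true(apply_germline_hard_filters(nominal, "snp")$pass)

  low_qual <- nominal; low_qual$qual <- 29
  res <- apply_germline_hard_filters(low_qual, "snp")
  expect_false(res$pass)
  expect_equal(res$reasons, "low_qual")

  bad_qd <- nominal; bad_qd$QD <- 1.9
  expect_equal(apply_germline_hard_filters(bad_qd, "snp")$reasons, "QD")

  # indel FS bound is 200, so FS = 100 passes for indels but not SNPs
  fs100 <- nominal; fs100$FS <- 100
  expect_true(apply_germline_hard_filters(fs100, "indel")$pass)
  expect_false(apply_germline_hard_filters(fs100, "snp")$pass)

  # absent metrics are not violations
  sparse <- list(qual = 45)
  expect_true(apply_germline_hard_filters(sparse, "indel")$pass)

  expect_error(apply_germline_hard_filters(nominal, "sv"), "unknown")
})
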