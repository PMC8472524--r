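test_that("normalization trims to the minimal anchored form", {
  expect_equal(normalize_variant("chr1", 100, "ATG", "ATA"),
               data.frame(chrom = "chr1", pos = 102L, ref = "G", alt = "A",
                          stringsAsFactors = FALSE))
  # expected form confirmed by brute-force enumeration of trim orders
  expect_equal(normalize_variant("chr1", 100, "CTT", "CT"),
               data.frame(chrom = "chr1", pos = 100L, ref = "CT", alt = "C",
                          stringsAsFactors = FALSE))
  expect_error(normalize_variant("chr1", 100, "A", "A"), "invalid variant")
  expect_error(normalize_variant("chr1", 100, "AXG", "A"), "format error")
  expect_error(normalize_variant("chr1", 0, "A", "T"), "invalid variant")
})

test_that("normalization is idempotent on randomized alleles", {
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    ref <- paste(sample(bases, sample(1:6, 1), replace = TRUE), collapse = "")
    alt <- paste(sample(bases, sample(1:6, 1), replace = TRUE), collapse = "")
    v1 <- tryCatch(normalize_variant("chr2", 500, ref, alt),
                   error = function(e) NULL)
    if (is.null(v1)) next  # degenerate ref == alt draws
    v2 <- normalize_variant(v1$chrom, v1$pos, v1$ref, v1$alt)
    expect_identical(v1, v2)
  }
})

test_that("caller VCF reading splits multi-allelics and recomputes VAF", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  recs <- data.frame(
    chrom = c("chr1", "chr1", "chr2"), pos = c(100L, 200L, 50L),
    ref = c("A", "A", "G"), alt = c("C,T", "G", "GAA"),
    filter = c("PASS", "q10", "PASS"),
    gt = c("0/1:80,12,8:100", "0/1:88,12:100", "0/1:90,30:120"),
    stringsAsFactors = FALSE
  )
  write_test_vcf(recs, tmp, format_keys = "GT:AD:DP")  # no AF tag anywhere
  calls <- read_caller_vcf(tmp, "mutect2")
  # multi-allelic split conserves allele count
  expect_equal(nrow(calls), 4L)
  first <- calls[calls$pos == 100, ]
  expect_setequal(first$alt, c("C", "T"))
  expect_equal(first$vaf[first$alt == "C"], 0.12)
  expect_equal(first$vaf[first$alt == "T"], 0.08)
  # AF absent -> vaf = alt_depth / total_depth
  expect_equal(calls$vaf[calls$pos == 200], 12 / 100)
  # non-PASS records retained but flagged
  expect_false(calls$passed_caller_filter[calls$pos == 200])
  expect_true(all(calls$passed_caller_filter[calls$pos != 200]))
  # indel normalized (GAA insertion keeps anchor) and classed
  expect_equal(calls$variant_class[calls$chrom == "chr2"], "indel")
})

test_that("empty VCF body and missing depth tags are handled", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(data.frame(), tmp)
  expect_equal(nrow(read_caller_vcf(tmp, "lofreq")), 0L)

  # record with neither AF nor usable depths is skipped with a warning
  tmp2 <- withr::local_tempfile(fileext = ".vcf")
  recs <- data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = "T",
                     filter = "PASS", gt = "0/1", stringsAsFactors = FALSE)
  write_test_vcf(recs, tmp2, format_keys = "GT")
  expect_warning(calls <- read_caller_vcf(tmp2, "lofreq"), "skipped")
  expect_equal(nrow(calls), 0L)
  expect_equal(attr(calls, "n_skipped"), 1L)

  expect_error(read_caller_vcf(tempfile(), "lofreq"), "missing file")
})

test_that("BED reading merges overlaps and conserves covered bases", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\ta", "chr1\t15\t30\tb", "chr2\t10\t20\tc"), tmp)
  bed <- read_targets_bed(tmp)
  expect_equal(nrow(bed), 2L)
  expect_equal(bed$start[bed$chrom == "chr1"], 10L)
  expect_equal(bed$end[bed$chrom == "chr1"], 30L)
  expect_equal(sum(bed$end - bed$start), 30L)

  tmp_bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t20\t10"), tmp_bad)
  expect_error(read_targets_bed(tmp_bad), "line 2")

  # merge conserves the per-base union, against a brute-force set oracle
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(1:8, 1)
    start <- sample(0:50, n, replace = TRUE)
    end <- start + sample(1:20, n, replace = TRUE)
    tmp_r <- withr::local_tempfile(fileext = ".bed")
    writeLines(paste("chrX", start, end, sep = "\t"), tmp_r)
    merged <- read_targets_bed(tmp_r)
    covered <- unique(unlist(Map(function(s, e) s:(e - 1L), start, end)))
    expect_equal(sum(merged$end - merged$start), length(covered))
  }
})

test_that("annotation table distinguishes absent AFs from zero and round-trips", {
  ann <- rbind(
    make_annotation(pos = 100L, gnomad_genome_AMR = 0.004),
    make_annotation(pos = 200L, g1000_ALL = 0),
    make_annotation(pos = 300L, dbsnp_id = "rs1", local_db_af = 0.002)
  )
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(ann, tmp)
  back <- read_annotation_table(tmp)
  expect_equal(nrow(back), 3L)
  expect_true(is.na(back$g1000_ALL[back$pos == 100]))   # absent, not zero
  expect_identical(back$g1000_ALL[back$pos == 200], 0)  # explicit zero kept
  # full round trip through the writer
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(back, tmp2)
  expect_equal(read_annotation_table(tmp2), back)

  # duplicate keys are an error naming the key
  dup <- rbind(make_annotation(pos = 100L), make_annotation(pos = 100L))
  tmp3 <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(dup, tmp3)
  expect_error(read_annotation_table(tmp3), "chr1:100:A:T")

  # unknown columns ignored with a warning
  odd <- make_annotation(); odd$mystery <- "x"
  tmp4 <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(odd, tmp4)
  expect_warning(read_annotation_table(tmp4), "mystery")
})

test_that("variant writer round-trips TSV and VCF and rejects formats", {
  recs <- make_consensus_row(pos = c(100L, 250L), vaf = c(0.12, 0.4),
                             alt_depth = c(12L, 80L))
  recs$category <- c("somatic", "germline")
  for (fmt in c("tsv", "vcf")) {
    tmp <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_variants(recs, tmp, fmt)
    back <- read_variants(tmp, fmt)
    expect_equal(back[names(recs)], recs, tolerance = 1e-12)
  }
  # empty record list still yields a valid, re-readable file
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_variants(recs[0, ], tmp, "vcf")
  expect_equal(nrow(read_variants(tmp, "vcf")), 0L)
  expect_error(write_variants(recs, tempfile(), "xml"), "unsupported")
})
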