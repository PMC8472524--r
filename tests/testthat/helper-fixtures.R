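# shared fixture builders: every test input is generated in code

write_test_vcf <- function(records, path, format_keys = "GT:AD:DP:AF",
                           sample_name = "TUMOR") {
  # records: data.frame with chrom,pos,ref,alt,filter,gt (the sample field)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_name)
  )
  body <- if (nrow(records)) {
    paste(records$chrom, records$pos, ".", records$ref, records$alt, ".",
          records$filter, ".", format_keys, records$gt, sep = "\t")
  } else character()
  writeLines(c(header, body), path)
  path
}

make_calls <- function(callers, chrom = "chr1", pos = 100L, ref = "A",
                       alt = "T", vaf = 0.2, alt_depth = 40L,
                       total_depth = 200L, passed = TRUE) {
  if (length(callers) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      variant_class = character(), caller_id = character(),
                      vaf = numeric(), alt_depth = integer(),
                      total_depth = integer(),
                      passed_caller_filter = logical(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    variant_class = variant_class_of(ref, alt),
    caller_id = callers, vaf = vaf, alt_depth = alt_depth,
    total_depth = total_depth,
    passed_caller_filter = rep_len(passed, length(callers)),
    stringsAsFactors = FALSE
  )
}

# one-row annotation builder with explicit database evidence
make_annotation <- function(chrom = "chr1", pos = 100L, ref = "A",
                            alt = "T", gene = "TP53",
                            consequence = "missense",
                            protein_change = "R175H",
                            dbsnp_id = NA_character_,
                            cosmic_id = NA_character_,
                            cosmic_count = 0L,
                            clinvar_sig = NA_character_,
                            local_db_af = NA_real_,
                            gnomad_genome_ALL = NA_real_,
                            gnomad_genome_AMR = NA_real_,
                            exac_ALL = NA_real_,
                            g1000_ALL = NA_real_,
                            esp6500_ALL = NA_real_) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             consequence = consequence, protein_change = protein_change,
             dbsnp_id = dbsnp_id, cosmic_id = cosmic_id,
             cosmic_count = cosmic_count, clinvar_sig = clinvar_sig,
             local_db_af = local_db_af,
             gnomad_genome_ALL = gnomad_genome_ALL,
             gnomad_genome_AMR = gnomad_genome_AMR, exac_ALL = exac_ALL,
             g1000_ALL = g1000_ALL, esp6500_ALL = esp6500_ALL,
             stringsAsFactors = FALSE)
}

make_consensus_row <- function(chrom = "chr1", pos = 100L, ref = "A",
                               alt = "T", vaf = 0.2, alt_depth = 40L,
                               total_depth = 200L, n_support = 3L) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             variant_class = variant_class_of(ref, alt),
             n_support = n_support, supporting_callers = "a|b|c",
             vaf = vaf, alt_depth = alt_depth, total_depth = total_depth,
             stringsAsFactors = FALSE)
}

# the unambiguous high-depth validation regime: step detection at the LOD,
# somatic VAFs away from the LOD boundary and the germline bands,
# germline VAFs centered in their bands
unambiguous_cohort_config <- function(seed, n_samples = 8L) {
  cohort_config(
    n_samples = n_samples,
    counts = c(germline_het = 8L, germline_hom = 2L, somatic = 12L,
               ffpe_artifact = 5L),
    somatic_vaf_grid = c(0.10, 0.25),
    mean_depth = 800,
    detection_slope = Inf,
    detection_midpoints = c(mutect2 = 0.05, varscan2 = 0.05,
                            vardict = 0.05, lofreq = 0.05, strelka = 0.05,
                            scalpel = 0.05),
    profile_weights = list(
      germline_het = c(local_db = 0.4, pvd_rare = 0.4, novel = 0.2),
      germline_hom = c(local_db = 0.4, pvd_rare = 0.4, novel = 0.2),
      somatic = c(cosmic_only = 0.5, novel = 0.3, pvd_rare = 0.2),
      ffpe_artifact = c(novel = 1)),
    het_vaf_range = c(0.48, 0.52),
    hom_vaf_range = c(0.94, 0.97),
    seed = seed
  )
}

extdata <- function(name) {
  system.file("extdata", name, package = "panelclassify")
}
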