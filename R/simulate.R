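#' Synthetic cohort configuration
#'
#' Parameters of the multi-caller cohort generator. The generator emulates
#' the data regime of a tumor-only targeted panel run: per-sample truth
#' variants of germline (heterozygous/homozygous), somatic, and low-VAF
#' FFPE-artifact origin; read depths drawn around a mean on-target depth;
#' per-caller detection modeled as independent logistic functions of the
#' true VAF (slope `Inf` degenerates to a step at each caller's midpoint);
#' and database annotations realized from each variant's profile
#' (`cosmic_only`, `pvd_rare`, `pvd_common`, `local_db`, `novel`).
#'
#' @param n_samples Number of tumor samples (default 8).
#' @param counts Named integer vector of per-sample truth counts for
#'   origins `germline_het, germline_hom, somatic, ffpe_artifact`.
#' @param somatic_vaf_grid VAF grid somatic variants are drawn from;
#'   default `c(0.01, 0.02, 0.05, 0.10, 0.25, 0.50)`.
#' @param mean_depth Mean on-target depth, scalar or one value per sample
#'   (default 500).
#' @param detection_slope Slope of the per-caller logistic detection curve
#'   (default 250); `Inf` makes detection a step function of VAF.
#' @param detection_midpoints Named numeric vector of per-caller logistic
#'   midpoints (VAF at 50% detection).
#' @param profile_weights Named list (per origin) of named probability
#'   weights over database profiles.
#' @param het_vaf_range,hom_vaf_range,ffpe_vaf_range VAF ranges for
#'   heterozygous germline, homozygous germline and FFPE artifacts;
#'   defaults `[0.42, 0.58]`, `[0.92, 1.00]`, `[0.005, 0.03]`. FFPE
#'   artifacts are always C>T or G>A substitutions below the LOD,
#'   mimicking formalin-induced cytosine deamination.
#' @param indel_fraction Fraction of somatic variants generated as small
#'   indels (default 0.15).
#' @param region_length Length of each synthetic target region in bp
#'   (default 150; two regions per panel gene).
#' @param seed Mandatory integer seed; all outputs are deterministic in it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 8L,
                          counts = c(germline_het = 8L, germline_hom = 2L,
                                     somatic = 12L, ffpe_artifact = 5L),
                          somatic_vaf_grid = c(0.01, 0.02, 0.05, 0.10,
                                               0.25, 0.50),
                          mean_depth = 500,
                          detection_slope = 250,
                          detection_midpoints = c(mutect2 = 0.020,
                                                  varscan2 = 0.030,
                                                  vardict = 0.025,
                                                  lofreq = 0.015,
                                                  strelka = 0.025,
                                                  scalpel = 0.030),
                          profile_weights = list(
                            germline_het = c(local_db = 0.5, pvd_rare = 0.3,
                                             pvd_common = 0.1, novel = 0.1),
                            germline_hom = c(local_db = 0.5, pvd_rare = 0.3,
                                             pvd_common = 0.1, novel = 0.1),
                            somatic = c(cosmic_only = 0.5, novel = 0.3,
                                        pvd_rare = 0.1, pvd_common = 0.1),
                            ffpe_artifact = c(novel = 1)),
                          het_vaf_range = c(0.42, 0.58),
                          hom_vaf_range = c(0.92, 1.00),
                          ffpe_vaf_range = c(0.005, 0.03),
                          indel_fraction = 0.15,
                          region_length = 150L,
                          seed) {
  if (missing(seed) || is.null(seed)) {
    stop("configuration error: seed is mandatory for reproducibility",
         call. = FALSE)
  }
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L) stop("configuration error: need >= 1 sample",
                           call. = FALSE)
  if (any(counts < 0L)) stop("configuration error: counts must be >= 0",
                             call. = FALSE)
  if (any(mean_depth <= 0)) stop("configuration error: degenerate depth",
                                 call. = FALSE)
  if (max(ffpe_vaf_range) >= 0.05) {
    stop("configuration error: FFPE artifact VAFs must lie below 0.05",
         call. = FALSE)
  }
  structure(list(
    n_samples = n_samples, counts = counts,
    somatic_vaf_grid = somatic_vaf_grid,
    mean_depth = rep_len(mean_depth, n_samples),
    detection_slope = detection_slope,
    detection_midpoints = detection_midpoints,
    profile_weights = profile_weights,
    het_vaf_range = het_vaf_range, hom_vaf_range = hom_vaf_range,
    ffpe_vaf_range = ffpe_vaf_range, indel_fraction = indel_fraction,
    region_length = as.integer(region_length), seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @keywords internal
panel_gene_table <- function() {
  utils::read.delim(system.file("extdata", "panel_genes.tsv",
                                package = "panelclassify"),
                    sep = "\t", stringsAsFactors = FALSE)
}

#' @keywords internal
synthetic_targets <- function(region_length = 150L) {
  genes <- panel_gene_table()$gene
  rows <- lapply(seq_along(genes), function(i) {
    chrom <- paste0("chr", ((i - 1L) %% 22L) + 1L)
    starts <- c(i * 1000000L, i * 1000000L + 5000L)
    data.frame(chrom = chrom, start = starts,
               end = starts + region_length, name = genes[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.aa_letters <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @keywords internal
detection_probability <- function(true_vaf, midpoint, slope) {
  if (is.infinite(slope)) return(as.numeric(true_vaf >= midpoint))
  stats::plogis(slope * (true_vaf - midpoint))
}

#' @keywords internal
fmt_num <- function(x, digits = 6) {
  format(x, digits = digits, scientific = FALSE, trim = TRUE)
}

#' Generate a synthetic multi-caller cohort with known ground truth
#'
#' Writes, under `out_dir`: one VCF per (sample, caller)
#' (`<sample>__<caller>.vcf`; the `varscan2` files carry no `AF` tag to
#' exercise VAF recomputation), `truth.tsv`, `annotations.tsv`,
#' `targets.bed`, `region_depths.tsv`, `per_base_depths.tsv` and
#' `sample_meta.tsv`. For each sample x variant one read draw is shared by
#' all callers (total depth Poisson around the sample mean, alt depth
#' binomial in the true VAF); callers then detect the variant
#' independently with probability given by their logistic curve evaluated
#' at the true VAF. Byte-identical outputs for a fixed seed.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the `truth` table, file paths, and the
#'   config.
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  targets <- synthetic_targets(config$region_length)
  # candidate variant sites: interior positions of every region (1-based)
  cand <- do.call(rbind, lapply(seq_len(nrow(targets)), function(r) {
    pos <- (targets$start[r] + 3L):(targets$end[r] - 2L)
    data.frame(chrom = targets$chrom[r], pos = pos,
               gene = targets$name[r], stringsAsFactors = FALSE)
  }))

  samples <- sprintf("S%02d", seq_len(config$n_samples))
  per_sample <- sum(config$counts)
  total <- per_sample * config$n_samples
  if (total > nrow(cand)) {
    stop("configuration error: more truth variants than candidate sites",
         call. = FALSE)
  }
  picked <- cand[sample.int(nrow(cand), total), , drop = FALSE]

  origins <- rep(rep(names(config$counts), times = config$counts),
                 times = config$n_samples)
  truth <- data.frame(
    sample_id = rep(samples, each = per_sample),
    chrom = picked$chrom, pos = picked$pos, gene = picked$gene,
    true_origin = origins, stringsAsFactors = FALSE
  )
  n <- nrow(truth)

  # alleles: FFPE artifacts are deamination-style C>T / G>A SNVs; somatic
  # variants are SNVs or small indels; germline variants are SNVs
  bases <- c("A", "C", "G", "T")
  truth$ref <- sample(bases, n, replace = TRUE)
  truth$alt <- vapply(truth$ref, function(r)
    sample(setdiff(bases, r), 1L), "")
  ffpe <- truth$true_origin == "ffpe_artifact"
  strand <- sample(c(TRUE, FALSE), sum(ffpe), replace = TRUE)
  truth$ref[ffpe] <- ifelse(strand, "C", "G")
  truth$alt[ffpe] <- ifelse(strand, "T", "A")
  make_indel <- truth$true_origin == "somatic" &
    stats::runif(n) < config$indel_fraction
  for (i in which(make_indel)) {
    if (stats::runif(1) < 0.5) {  # deletion
      truth$ref[i] <- paste0(truth$ref[i],
                             paste(sample(bases, 2L, replace = TRUE),
                                   collapse = ""))
      truth$alt[i] <- substr(truth$ref[i], 1L, 1L)
    } else {                      # insertion
      truth$alt[i] <- paste0(truth$ref[i],
                             paste(sample(bases, 2L, replace = TRUE),
                                   collapse = ""))
    }
  }
  truth$variant_class <- variant_class_of(truth$ref, truth$alt)

  truth$true_vaf <- NA_real_
  o <- truth$true_origin
  truth$true_vaf[o == "germline_het"] <-
    stats::runif(sum(o == "germline_het"), config$het_vaf_range[1],
                 config$het_vaf_range[2])
  truth$true_vaf[o == "germline_hom"] <-
    stats::runif(sum(o == "germline_hom"), config$hom_vaf_range[1],
                 config$hom_vaf_range[2])
  truth$true_vaf[o == "somatic"] <-
    sample(config$somatic_vaf_grid, sum(o == "somatic"), replace = TRUE)
  truth$true_vaf[o == "ffpe_artifact"] <-
    stats::runif(sum(o == "ffpe_artifact"), config$ffpe_vaf_range[1],
                 config$ffpe_vaf_range[2])

  truth$database_profile <- vapply(o, function(orig) {
    w <- config$profile_weights[[orig]]
    sample(names(w), 1L, prob = w)
  }, "")

  snv_cons <- c("missense", "nonsense", "splice_site")
  truth$consequence <- sample(snv_cons, n, replace = TRUE,
                              prob = c(0.75, 0.15, 0.10))
  is_ins <- truth$variant_class == "indel" &
    nchar(truth$alt) > nchar(truth$ref)
  is_del <- truth$variant_class == "indel" & !is_ins
  truth$consequence[is_ins] <- sample(c("frameshift_ins", "inframe_ins"),
                                      sum(is_ins), replace = TRUE,
                                      prob = c(0.7, 0.3))
  truth$consequence[is_del] <- sample(c("frameshift_del", "inframe_del"),
                                      sum(is_del), replace = TRUE,
                                      prob = c(0.7, 0.3))
  truth$protein_change <- sprintf(
    "%s%d%s", sample(.aa_letters, n, replace = TRUE),
    1L + truth$pos %% 900L, sample(.aa_letters, n, replace = TRUE))

  # shared read draw per sample x variant
  depth_by_sample <- stats::setNames(config$mean_depth, samples)
  truth$total_depth <- stats::rpois(n, depth_by_sample[truth$sample_id])
  truth$total_depth <- pmax(truth$total_depth, 1L)
  truth$alt_depth <- stats::rbinom(n, truth$total_depth, truth$true_vaf)
  truth$observed_vaf <- truth$alt_depth / truth$total_depth

  # per-caller detection
  callers <- names(config$detection_midpoints)
  detected <- matrix(FALSE, n, length(callers),
                     dimnames = list(NULL, callers))
  for (cl in callers) {
    p <- detection_probability(truth$true_vaf,
                               config$detection_midpoints[[cl]],
                               config$detection_slope)
    detected[, cl] <- stats::runif(n) < p
  }

  paths <- list()
  # per-caller VCFs
  for (s in samples) {
    for (cl in callers) {
      idx <- which(truth$sample_id == s & detected[, cl] &
                     truth$alt_depth > 0L)
      idx <- idx[order(truth$chrom[idx], truth$pos[idx])]
      with_af <- cl != "varscan2"
      fmt_key <- if (with_af) "GT:AD:DP:AF" else "GT:AD:DP"
      header <- c(
        "##fileformat=VCFv4.2",
        sprintf("##source=panelclassify-simulator(%s)", cl),
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
        if (with_af)
          "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR"
      )
      body <- if (length(idx)) {
        gt <- paste0("0/1:",
                     truth$total_depth[idx] - truth$alt_depth[idx], ",",
                     truth$alt_depth[idx], ":", truth$total_depth[idx],
                     if (with_af) paste0(":", fmt_num(truth$observed_vaf[idx]))
                     else "")
        paste(truth$chrom[idx], truth$pos[idx], ".", truth$ref[idx],
              truth$alt[idx], ".", "PASS",
              paste0("DP=", truth$total_depth[idx]), fmt_key, gt, sep = "\t")
      } else character()
      f <- file.path(out_dir, sprintf("%s__%s.vcf", s, cl))
      writeLines(c(header, body), f)
      paths[[sprintf("%s__%s", s, cl)]] <- f
    }
  }

  # annotation table keyed by the (globally unique) variant sites
  ann <- truth[!duplicated(variant_key(truth)),
               c("chrom", "pos", "ref", "alt", "gene", "consequence",
                 "protein_change"), drop = FALSE]
  prof <- truth$database_profile[!duplicated(variant_key(truth))]
  m <- nrow(ann)
  ann$dbsnp_id <- NA_character_
  ann$cosmic_id <- NA_character_
  ann$cosmic_count <- NA_integer_
  ann$clinvar_sig <- NA_character_
  ann$local_db_af <- NA_real_
  ann$gnomad_genome_ALL <- NA_real_
  ann$gnomad_genome_AMR <- NA_real_
  ann$gnomad_exome_ALL <- NA_real_
  ann$exac_ALL <- NA_real_
  ann$g1000_ALL <- NA_real_
  ann$esp6500_ALL <- NA_real_
  for (i in seq_len(m)) {
    p <- prof[i]
    if (p == "cosmic_only") {
      ann$cosmic_id[i] <- sprintf("COSM%d", 100000L + i)
      ann$cosmic_count[i] <- sample(1:50, 1L)
    } else if (p == "pvd_rare") {
      ann$dbsnp_id[i] <- sprintf("rs%d", 500000L + i)
      ann$gnomad_genome_AMR[i] <- stats::runif(1, 5e-4, 9e-3)
      ann$gnomad_genome_ALL[i] <- stats::runif(1, 1e-4, 9e-3)
    } else if (p == "pvd_common") {
      ann$dbsnp_id[i] <- sprintf("rs%d", 500000L + i)
      ann$gnomad_genome_ALL[i] <- stats::runif(1, 0.011, 0.30)
      ann$g1000_ALL[i] <- stats::runif(1, 0.011, 0.30)
    } else if (p == "local_db") {
      ann$local_db_af[i] <- stats::runif(1, 0.001, 0.01)
    }
  }
  ann$cosmic_count[is.na(ann$cosmic_count)] <- 0L
  ann_path <- file.path(out_dir, "annotations.tsv")
  write_annotation_table(ann, ann_path)

  # targets BED (0-based half-open)
  bed_path <- file.path(out_dir, "targets.bed")
  writeLines(paste(targets$chrom, targets$start, targets$end, targets$name,
                   sep = "\t"), bed_path)

  # depth tables: per-region mean depth and per-base depth, per sample
  rd <- list(); pb <- list()
  for (si in seq_along(samples)) {
    mu <- config$mean_depth[si]
    region_mu <- pmax(0, stats::rnorm(nrow(targets), mu, 0.06 * mu))
    n_bases <- targets$end - targets$start
    base_depths <- unlist(lapply(seq_len(nrow(targets)), function(r) {
      pmax(0L, as.integer(round(stats::rnorm(n_bases[r], region_mu[r],
                                             0.10 * mu))))
    }))
    rd[[si]] <- data.frame(
      sample_id = samples[si], chrom = targets$chrom, start = targets$start,
      end = targets$end, name = targets$name,
      mean_depth = round(region_mu, 1), stringsAsFactors = FALSE
    )
    pb[[si]] <- data.frame(
      sample_id = samples[si],
      chrom = rep(targets$chrom, n_bases),
      pos = unlist(lapply(seq_len(nrow(targets)), function(r)
        (targets$start[r] + 1L):targets$end[r])),
      depth = base_depths, stringsAsFactors = FALSE
    )
  }
  region_path <- file.path(out_dir, "region_depths.tsv")
  utils::write.table(do.call(rbind, rd), region_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  perbase_path <- file.path(out_dir, "per_base_depths.tsv")
  utils::write.table(do.call(rbind, pb), perbase_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  meta <- data.frame(
    sample_id = samples,
    tumor_type = sample(c("breast", "ovary", "gallbladder", "colorectal",
                          "gastric"), length(samples), replace = TRUE),
    stringsAsFactors = FALSE
  )
  meta_path <- file.path(out_dir, "sample_meta.tsv")
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)

  invisible(list(
    dir = out_dir, truth = truth, annotation = ann, targets = targets,
    sample_meta = meta, callers = callers, samples = samples,
    paths = c(paths, list(annotations = ann_path, targets = bed_path,
                          region_depths = region_path,
                          per_base_depths = perbase_path,
                          sample_meta = meta_path, truth = truth_path)),
    config = config
  ))
}

#' Reference-standard-like truth set
#'
#' Produces an analog of a multiplexed reference-standard control: `n`
#' variants whose expected VAFs span the requested range (endpoints always
#' included; `n = 1` gives the midpoint), suitable for
#' expected-vs-observed VAF correlation checks.
#'
#' @param n_variants Number of variants (>= 1).
#' @param vaf_range Two-element range within `(0, 1]`; default
#'   `c(0.01, 0.245)`.
#' @return A `data.frame` with `chrom, pos, ref, alt, gene, expected_vaf`.
#' @export
hd_like_truth_set <- function(n_variants, vaf_range = c(0.01, 0.245)) {
  if (length(n_variants) != 1L || is.na(n_variants) || n_variants < 1L) {
    stop("need at least one variant", call. = FALSE)
  }
  if (length(vaf_range) != 2L || any(vaf_range <= 0) || any(vaf_range > 1) ||
      vaf_range[1] > vaf_range[2]) {
    stop("vaf_range must be within (0, 1]", call. = FALSE)
  }
  n_variants <- as.integer(n_variants)
  vafs <- if (n_variants == 1L) mean(vaf_range) else
    seq(vaf_range[1], vaf_range[2], length.out = n_variants)
  genes <- c("BRAF", "KIT", "EGFR", "KRAS", "NRAS", "PIK3CA", "ARID1A",
             "BRCA2")
  refs <- rep_len(c("C", "G", "A", "T"), n_variants)
  alts <- rep_len(c("T", "A", "G", "C"), n_variants)
  data.frame(
    chrom = "chr7", pos = 55000000L + 1000L * seq_len(n_variants),
    ref = refs, alt = alts,
    gene = rep_len(genes, n_variants), expected_vaf = vafs,
    stringsAsFactors = FALSE
  )
}

#' Realize observed VAFs for a truth set by binomial sampling
#'
#' Draws a total depth (Poisson around `mean_depth`) and an alt depth
#' (binomial in the expected VAF) per variant; the observed VAF is their
#' ratio.
#'
#' @param truth Truth `data.frame` with an `expected_vaf` (or `true_vaf`)
#'   column.
#' @param mean_depth Mean total depth, default 500.
#' @param seed Optional seed.
#' @return `truth` with `total_depth`, `alt_depth`, `observed_vaf` added.
#' @export
observe_truth <- function(truth, mean_depth = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vaf <- if (!is.null(truth$expected_vaf)) truth$expected_vaf else
    truth$true_vaf
  if (is.null(vaf)) stop("truth table lacks an expected_vaf column",
                         call. = FALSE)
  truth$total_depth <- pmax(1L, stats::rpois(nrow(truth), mean_depth))
  truth$alt_depth <- stats::rbinom(nrow(truth), truth$total_depth, vaf)
  truth$observed_vaf <- truth$alt_depth / truth$total_depth
  truth
}

#' Recovery metrics: truth versus classified output
#'
#' Confusion of true origin against assigned category (truth variants
#' absent from the classified set count as `absent`), plus family-level
#' recovery rates: somatic sensitivity is the fraction of true somatic
#' variants at or above the LOD (restricted to consensus-detected keys
#' when a consensus table is supplied) assigned a somatic-family category;
#' germline recovery is the fraction of classified germline-origin
#' variants assigned a germline-family category. Also counts FFPE
#' artifacts surviving into the somatic-family output.
#'
#' @param truth Truth table from [generate_cohort()].
#' @param classified Classified variants (with `sample_id`).
#' @param consensus Optional consensus table (with `sample_id`) defining
#'   which truth variants were detected.
#' @param lod Limit of detection, default 0.05.
#' @return A list with `confusion`, `somatic_sensitivity`,
#'   `germline_recovery`, `ffpe_in_somatic_output`.
#' @export
recovery_metrics <- function(truth, classified, consensus = NULL,
                             lod = 0.05) {
  skey <- function(df) paste(df$sample_id, variant_key(df))
  tk <- skey(truth); ck <- skey(classified)
  if (!length(intersect(tk, ck))) {
    stop("disjoint key sets between truth and classified variants",
         call. = FALSE)
  }
  assigned <- classified$category[match(tk, ck)]
  assigned[is.na(assigned)] <- "absent"
  confusion <- table(true_origin = truth$true_origin, assigned = assigned)

  som <- truth$true_origin == "somatic" & truth$true_vaf >= lod
  if (!is.null(consensus)) som <- som & tk %in% skey(consensus)
  somatic_sensitivity <- if (any(som)) {
    mean(assigned[som] %in% somatic_family())
  } else NA_real_

  germ <- truth$true_origin %in% c("germline_het", "germline_hom") &
    assigned != "absent"
  germline_recovery <- if (any(germ)) {
    mean(assigned[germ] %in% germline_family())
  } else NA_real_

  ffpe <- truth$true_origin == "ffpe_artifact"
  ffpe_in_somatic <- sum(assigned[ffpe] %in% somatic_family())

  list(confusion = confusion, somatic_sensitivity = somatic_sensitivity,
       germline_recovery = germline_recovery,
       ffpe_in_somatic_output = ffpe_in_somatic)
}
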