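#' Pipeline run configuration
#'
#' Aggregates every threshold of the workflow in one validated object.
#' All defaults equal the validated panel's stated operating point:
#' LOD VAF 0.05, >= 12 alt reads, population AF cutoff 0.01, consensus
#' 3-of-5 for SNVs and 3-of-6 for indels, and sample pass rules of 300x
#' (somatic) / 200x (germline) in at least 80% of target regions.
#'
#' @param consensus A [consensus_config()].
#' @param filters A [filter_config()].
#' @param tag_maps Named list (per caller) of FORMAT/INFO tag maps for
#'   [read_caller_vcf()]; callers not listed use the default map.
#' @param qc_mode `"somatic"` or `"germline"`: which pass rule gates
#'   classification.
#' @param qc_min_fraction Minimum fraction of regions at the mode depth,
#'   default 0.80.
#' @param kb_path Optional path to a biomarker knowledge base TSV.
#' @param chr_style Contig-name harmonization passed to the VCF reader.
#' @return A list of class `run_config`.
#' @export
run_config <- function(consensus = consensus_config(),
                       filters = filter_config(),
                       tag_maps = list(),
                       qc_mode = c("somatic", "germline"),
                       qc_min_fraction = 0.80,
                       kb_path = NULL,
                       chr_style = "as-is") {
  qc_mode <- match.arg(qc_mode)
  stopifnot(inherits(consensus, "consensus_config"),
            inherits(filters, "filter_config"))
  if (!is.null(kb_path) && !file.exists(kb_path)) {
    stop(sprintf("configuration error: knowledge base not found: %s",
                 kb_path), call. = FALSE)
  }
  structure(list(consensus = consensus, filters = filters,
                 tag_maps = tag_maps, qc_mode = qc_mode,
                 qc_min_fraction = qc_min_fraction, kb_path = kb_path,
                 chr_style = chr_style),
            class = "run_config")
}

#' Read a YAML run configuration
#'
#' Schema: top-level keys `consensus`, `filters`, `tag_maps`, `qc`
#' (`mode`, `min_fraction`), `kb_path`, `chr_style`; each sub-key maps to
#' the corresponding argument of [consensus_config()], [filter_config()]
#' or [run_config()]. Missing keys take the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("configuration error: missing config file: %s", path),
         call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  cc <- do.call(consensus_config, if (is.null(y$consensus)) list() else
    y$consensus)
  fc_args <- if (is.null(y$filters)) list() else y$filters
  if (!is.null(fc_args$germline_vaf_bands)) {
    fc_args$germline_vaf_bands <- lapply(fc_args$germline_vaf_bands,
                                         as.numeric)
  }
  fc <- do.call(filter_config, fc_args)
  run_config(
    consensus = cc, filters = fc,
    tag_maps = if (is.null(y$tag_maps)) list() else y$tag_maps,
    qc_mode = if (is.null(y$qc$mode)) "somatic" else y$qc$mode,
    qc_min_fraction = if (is.null(y$qc$min_fraction)) 0.80 else
      y$qc$min_fraction,
    kb_path = y$kb_path,
    chr_style = if (is.null(y$chr_style)) "as-is" else y$chr_style
  )
}

#' @keywords internal
default_tag_map <- function() {
  list(vaf = "AF", alt_depth = "AD", total_depth = "DP")
}

#' Run the full per-cohort pipeline
#'
#' Chains consensus merging, detection and population filtering,
#' six-category classification, per-sample QC gating and biomarker
#' matching over a cohort directory laid out as produced by
#' [generate_cohort()] (per-caller VCFs named `<sample>__<caller>.vcf`,
#' `annotations.tsv`, `targets.bed`, `region_depths.tsv`,
#' `per_base_depths.tsv`, `sample_meta.tsv`). Samples failing the QC pass
#' rule appear in the QC report but are skipped for classification
#' (the cohort proceeds). Outputs are deterministic for fixed inputs; a
#' `manifest.json` lists every output file with its MD5 checksum.
#'
#' @param cohort_dir Input cohort directory.
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @return Invisibly, a list with `classified`, `qc`, `hits`,
#'   `category_summary`, `dropped`, `manifest`.
#' @export
run_pipeline <- function(cohort_dir, out_dir, config = run_config()) {
  req <- c("annotations.tsv", "targets.bed", "region_depths.tsv",
           "sample_meta.tsv")
  for (f in req) {
    if (!file.exists(file.path(cohort_dir, f))) {
      stop(sprintf("input error: missing %s in %s", f, cohort_dir),
           call. = FALSE)
    }
  }
  kb <- if (!is.null(config$kb_path)) load_knowledge_base(config$kb_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ann <- read_annotation_table(file.path(cohort_dir, "annotations.tsv"))
  meta <- utils::read.delim(file.path(cohort_dir, "sample_meta.tsv"),
                            sep = "\t", stringsAsFactors = FALSE)
  region_depths <- utils::read.delim(file.path(cohort_dir,
                                               "region_depths.tsv"),
                                     sep = "\t", stringsAsFactors = FALSE)
  perbase_file <- file.path(cohort_dir, "per_base_depths.tsv")
  per_base <- if (file.exists(perbase_file)) {
    utils::read.delim(perbase_file, sep = "\t", stringsAsFactors = FALSE)
  }

  vcfs <- list.files(cohort_dir, pattern = "__.*\\.vcf$")
  samples <- sort(unique(meta$sample_id))
  all_callers <- union(config$consensus$snv_callers,
                       config$consensus$indel_callers)

  qc_rows <- list(); classified_rows <- list(); dropped_rows <- list()
  for (s in samples) {
    rd <- region_depths[region_depths$sample_id == s, , drop = FALSE]
    pb <- if (!is.null(per_base)) {
      per_base$depth[per_base$sample_id == s]
    }
    qc <- qc_summary(s, rd$mean_depth, pb,
                     min_fraction = config$qc_min_fraction)
    qc_rows[[s]] <- qc
    passed <- if (config$qc_mode == "somatic") qc$pass_somatic else
      qc$pass_germline
    if (!passed) next

    calls <- list()
    for (cl in all_callers) {
      f <- file.path(cohort_dir, sprintf("%s__%s.vcf", s, cl))
      if (!file.exists(f)) next
      tm <- if (!is.null(config$tag_maps[[cl]])) config$tag_maps[[cl]] else
        default_tag_map()
      calls[[cl]] <- read_caller_vcf(f, cl, tm, config$chr_style)
    }
    calls <- do.call(rbind, calls)
    cons <- merge_callers(calls, config$consensus)
    if (nrow(cons) == 0L) next

    det <- apply_detection_filters(cons, config$filters)
    pop <- apply_population_filter(det[det$keep, , drop = FALSE], ann,
                                   config$filters)
    drop1 <- det[!det$keep, , drop = FALSE]
    drop2 <- pop[!pop$keep, , drop = FALSE]
    kept <- pop[pop$keep, , drop = FALSE]
    kept$keep <- NULL; kept$drop_reason <- NULL
    if (nrow(drop1) + nrow(drop2)) {
      dr <- rbind(drop1, drop2)
      dr$sample_id <- s
      dropped_rows[[s]] <- dr
    }
    if (nrow(kept) == 0L) next
    cls <- classify_variants(kept, ann, config$filters)
    cls$sample_id <- s
    classified_rows[[s]] <- cls
  }

  qc_all <- do.call(rbind, qc_rows)
  classified <- if (length(classified_rows)) {
    do.call(rbind, classified_rows)
  } else {
    data.frame()
  }
  dropped <- if (length(dropped_rows)) do.call(rbind, dropped_rows) else
    data.frame()

  qc_report(qc_all, file.path(out_dir, "qc_summary.tsv"))
  if (nrow(classified)) {
    write_variants(classified, file.path(out_dir, "classified.tsv"), "tsv")
    summary_tab <- summarize_classification(classified)
  } else {
    writeLines(paste(c("chrom", "pos", "ref", "alt", "category"),
                     collapse = "\t"),
               file.path(out_dir, "classified.tsv"))
    summary_tab <- summarize_classification(
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), category = character()))
  }
  utils::write.table(summary_tab, file.path(out_dir, "category_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(dropped)) {
    write_variants(dropped, file.path(out_dir, "dropped.tsv"), "tsv")
  }
  hits <- NULL
  if (!is.null(kb) && nrow(classified)) {
    hits <- match_biomarkers(classified, kb)
    write_variants(hits, file.path(out_dir, "biomarker_hits.tsv"), "tsv")
  }

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(files = lapply(files, function(f) list(
    name = f, md5 = unname(tools::md5sum(file.path(out_dir, f)))
  )))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(classified = classified, qc = qc_all, hits = hits,
                 category_summary = summary_tab, dropped = dropped,
                 manifest = manifest))
}

#' Simulate a cohort and run the full pipeline
#'
#' The all-in-one entry point: generates a synthetic cohort under
#' `<out_dir>/cohort` from the given seed and runs [run_pipeline()] into
#' `<out_dir>/results`. Outputs are byte-identical across runs with the
#' same seed.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param cohort A [cohort_config()] (its seed is overridden by `seed`).
#' @param config A [run_config()].
#' @return Invisibly, a list with the simulation handle and pipeline
#'   result.
#' @export
run_end_to_end <- function(seed, out_dir,
                           cohort = NULL, config = run_config()) {
  if (is.null(cohort)) cohort <- cohort_config(seed = seed)
  cohort$seed <- as.integer(seed)
  sim <- generate_cohort(cohort, file.path(out_dir, "cohort"))
  res <- run_pipeline(file.path(out_dir, "cohort"),
                      file.path(out_dir, "results"), config)
  invisible(list(sim = sim, result = res))
}
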