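#' Filtering and classification configuration
#'
#' Thresholds for the detection-limit filter, the population-polymorphism
#' filter, and the tumor-only origin classification. The defaults are the
#' validated panel's operating point: limit of detection at VAF 0.05 with at
#' least 12 alternate reads, polymorphisms removed when any population
#' database (including under-represented subpopulations and the local
#' germline database) reports an allele frequency strictly greater than
#' 0.01, and germline VAF expectation bands of [0.40, 0.60] (heterozygous)
#' and [0.90, 1.00] (homozygous) for tumor-only data.
#'
#' @param min_vaf Minimum VAF kept (inclusive), default 0.05.
#' @param min_alt_reads Minimum alternate-allele read depth (inclusive),
#'   default 12.
#' @param max_pop_af Maximum tolerated population AF (exclusive: a variant
#'   is dropped only when an AF is strictly greater), default 0.01.
#' @param germline_vaf_bands List of disjoint `[lo, hi]` bands within
#'   `[0, 1]` where a VAF is compatible with germline origin.
#' @param min_cosmic_count Minimum COSMIC sample count treated as somatic
#'   evidence, default 1.
#' @param local_db_in_pop_filter Should the local-database AF participate in
#'   the population filter (in addition to classification rule R1)?
#'   Default `TRUE`.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_vaf = 0.05, min_alt_reads = 12L,
                          max_pop_af = 0.01,
                          germline_vaf_bands = list(c(0.40, 0.60),
                                                    c(0.90, 1.00)),
                          min_cosmic_count = 1L,
                          local_db_in_pop_filter = TRUE) {
  if (!(min_vaf > 0 && min_vaf < 1)) {
    stop("configuration error: min_vaf must lie in (0, 1)", call. = FALSE)
  }
  bands <- lapply(germline_vaf_bands, as.numeric)
  for (b in bands) {
    if (length(b) != 2L || b[1] > b[2] || b[1] < 0 || b[2] > 1) {
      stop("configuration error: each germline band must be [lo, hi] within [0, 1]",
           call. = FALSE)
    }
  }
  if (length(bands) > 1L) {
    m <- do.call(rbind, bands)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[-1, 1] < m[-nrow(m), 2])) {
      stop("configuration error: germline bands must be disjoint", call. = FALSE)
    }
  }
  structure(list(
    min_vaf = min_vaf, min_alt_reads = as.integer(min_alt_reads),
    max_pop_af = max_pop_af, germline_vaf_bands = bands,
    min_cosmic_count = as.integer(min_cosmic_count),
    local_db_in_pop_filter = isTRUE(local_db_in_pop_filter)
  ), class = "filter_config")
}

#' Detection-limit filter
#'
#' Keeps a consensus variant iff `vaf >= min_vaf` **and**
#' `alt_depth >= min_alt_reads` (both boundaries inclusive). A total
#' function: every input row receives a verdict; the drop reason enumerates
#' every failed criterion.
#'
#' @param variants Consensus `data.frame` with `vaf` and `alt_depth`.
#' @param cfg A [filter_config()].
#' @return The input with logical column `keep` and character column
#'   `drop_reason` (pipe-joined, empty when kept) appended.
#' @export
apply_detection_filters <- function(variants, cfg = filter_config()) {
  low_vaf <- variants$vaf < cfg$min_vaf
  low_alt <- variants$alt_depth < cfg$min_alt_reads
  variants$keep <- !(low_vaf | low_alt)
  variants$drop_reason <- vapply(seq_len(nrow(variants)), function(i) {
    paste(c(if (low_vaf[i]) "low_vaf", if (low_alt[i]) "low_alt_depth"),
          collapse = "|")
  }, "")
  variants
}

#' Maximum population allele frequency of an annotation record
#'
#' The maximum over every present (database, subpopulation) AF column and,
#' by default, the local-database AF. Returns `NA` when no entry exists in
#' any database (absence, distinct from zero).
#'
#' @param ann Annotation `data.frame` rows ([read_annotation_table()]).
#' @param include_local Include `local_db_af` in the maximum (default TRUE).
#' @return Numeric vector, `NA` where every database is silent.
#' @export
max_population_af <- function(ann, include_local = TRUE) {
  cols <- pop_af_columns(ann)
  m <- as.matrix(as.data.frame(
    c(ann[cols], if (include_local) list(local = ann$local_db_af))
  ))
  if (is.null(dim(m)) || ncol(m) == 0L) return(rep(NA_real_, nrow(ann)))
  apply(m, 1L, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
}

#' Population-polymorphism filter
#'
#' Drops a variant iff its maximum population AF is strictly greater than
#' `max_pop_af`; an AF exactly at the threshold is kept, and a variant
#' absent from every database is kept.
#'
#' @param variants Consensus `data.frame` (normalized keys).
#' @param ann Annotation table matched by normalized key.
#' @param cfg A [filter_config()].
#' @return `variants` with `keep` / `drop_reason`
#'   (`"common_polymorphism"`) appended.
#' @export
apply_population_filter <- function(variants, ann, cfg = filter_config()) {
  maxaf <- max_population_af(ann, include_local = cfg$local_db_in_pop_filter)
  names(maxaf) <- variant_key(ann)
  v_max <- maxaf[variant_key(variants)]
  drop <- !is.na(v_max) & v_max > cfg$max_pop_af
  variants$keep <- !drop
  variants$drop_reason <- ifelse(drop, "common_polymorphism", "")
  variants
}

#' @keywords internal
in_germline_band <- function(vaf, bands) {
  vapply(vaf, function(v)
    any(vapply(bands, function(b) v >= b[1] && v <= b[2], NA)), NA)
}

#' The default ordered classification rule set
#'
#' Six-category tumor-only origin classification driven by database
#' evidence (COSMIC, dbSNP, ClinVar, population variant databases, local
#' germline database) and the germline VAF bands. Rules are evaluated in
#' order; the first match wins:
#'
#' * `R1` germline: ClinVar asserts a germline condition, or the variant is
#'   present in the local germline database.
#' * `R2` somatic: COSMIC evidence and no population-database or dbSNP
#'   record.
#' * `R3` putative somatic: COSMIC evidence plus a PVD/dbSNP record, VAF
#'   outside every germline band.
#' * `R4` putative germline: PVD/dbSNP record and VAF inside a germline
#'   band.
#' * `R5` putative somatic: PVD/dbSNP record, no COSMIC, VAF outside the
#'   bands.
#' * `R6` novel split: no database evidence at all; putative novel germline
#'   when the VAF falls in a band, putative novel somatic otherwise.
#'
#' The rule set is an ordered list of `(id, when, category)` entries, so
#' alternative trees (or permuted orders, for sensitivity analysis) can be
#' supplied to [classify_variants()] without code changes. Each `when`
#' predicate receives an evidence list with fields `has_cosmic, has_pvd,
#' has_dbsnp, clinvar_germline, has_local, in_band`.
#'
#' @return An ordered list of classification rules.
#' @export
default_classification_rules <- function() {
  list(
    list(id = "R1", category = function(e) "germline",
         when = function(e) e$clinvar_germline || e$has_local),
    list(id = "R2", category = function(e) "somatic",
         when = function(e) e$has_cosmic && !e$has_pvd && !e$has_dbsnp),
    list(id = "R3", category = function(e) "putative_somatic",
         when = function(e) e$has_cosmic && (e$has_pvd || e$has_dbsnp) &&
           !e$in_band),
    list(id = "R4", category = function(e) "putative_germline",
         when = function(e) (e$has_pvd || e$has_dbsnp) && e$in_band),
    list(id = "R5", category = function(e) "putative_somatic",
         when = function(e) (e$has_pvd || e$has_dbsnp) && !e$has_cosmic &&
           !e$in_band),
    list(id = "R6",
         category = function(e) if (e$in_band) "putative_novel_germline" else
           "putative_novel_somatic",
         when = function(e) TRUE)
  )
}

#' @keywords internal
variant_categories <- function() {
  c("germline", "putative_germline", "putative_novel_germline",
    "somatic", "putative_somatic", "putative_novel_somatic")
}

#' @keywords internal
somatic_family <- function() {
  c("somatic", "putative_somatic", "putative_novel_somatic")
}

#' @keywords internal
germline_family <- function() {
  c("germline", "putative_germline", "putative_novel_germline")
}

#' Classify filtered variants into six origin categories
#'
#' Applies the ordered rule set (first match wins) to every variant that
#' survived the detection and population filters. Each output row records
#' the assigned category and a reproducible `rule_trail`: the pipe-joined
#' ids of the rules evaluated, ending with the rule that fired.
#'
#' @param variants Filtered consensus `data.frame` (normalized keys, `vaf`).
#' @param ann Annotation table; every variant must have a matching record.
#' @param cfg A [filter_config()].
#' @param rules Ordered rule list, default
#'   [default_classification_rules()].
#' @return `variants` joined with annotation columns plus `category` and
#'   `rule_trail`.
#' @export
classify_variants <- function(variants, ann, cfg = filter_config(),
                              rules = default_classification_rules()) {
  akey <- variant_key(ann)
  vkey <- variant_key(variants)
  miss <- setdiff(vkey, akey)
  if (length(miss)) {
    stop(sprintf("classification error: no annotation for variant(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  ai <- match(vkey, akey)
  pvd_present <- if (length(pop_af_columns(ann))) {
    rowSums(!is.na(as.data.frame(ann[pop_af_columns(ann)]))) > 0L
  } else rep(FALSE, nrow(ann))

  out <- variants
  ann_cols <- c("gene", "consequence", "protein_change", "dbsnp_id",
                "cosmic_id", "cosmic_count", "clinvar_sig", "local_db_af")
  for (cn in ann_cols) out[[cn]] <- ann[[cn]][ai]
  out$category <- NA_character_
  out$rule_trail <- NA_character_

  for (i in seq_len(nrow(out))) {
    e <- list(
      has_cosmic = out$cosmic_count[i] >= cfg$min_cosmic_count,
      has_pvd = pvd_present[ai[i]],
      has_dbsnp = !is.na(out$dbsnp_id[i]) && nzchar(out$dbsnp_id[i]),
      clinvar_germline = !is.na(out$clinvar_sig[i]) &&
        grepl("germline", tolower(out$clinvar_sig[i])),
      has_local = !is.na(out$local_db_af[i]),
      in_band = in_germline_band(out$vaf[i], cfg$germline_vaf_bands)
    )
    trail <- character()
    for (rule in rules) {
      trail <- c(trail, rule$id)
      if (isTRUE(rule$when(e))) {
        out$category[i] <- rule$category(e)
        break
      }
    }
    out$rule_trail[i] <- paste(trail, collapse = "|")
  }
  if (anyNA(out$category)) {
    stop("classification error: rule set is not total (no rule fired)",
         call. = FALSE)
  }
  out
}

# GATK-style hard-filter default thresholds, per variant class
.hard_filter_defaults <- list(
  snp = list(QD = c("lt", 2.0), FS = c("gt", 60.0), MQ = c("lt", 40.0),
             MQRankSum = c("lt", -12.5), ReadPosRankSum = c("lt", -8.0)),
  indel = list(QD = c("lt", 2.0), FS = c("gt", 200.0),
               ReadPosRankSum = c("lt", -20.0))
)

#' Germline variant hard filters
#'
#' Class-specific hard filtering of germline calls following the standard
#' recommendations for haplotype-based callers: a site fails when its call
#' confidence (`qual`) is below 30 or when any *present* annotation metric
#' violates its class-specific bound. Absent metrics are never violations.
#' Default bounds — SNP: `QD < 2.0`, `FS > 60.0`, `MQ < 40.0`,
#' `MQRankSum < -12.5`, `ReadPosRankSum < -8.0`; indel: `QD < 2.0`,
#' `FS > 200.0`, `ReadPosRankSum < -20.0`.
#'
#' @param site_metrics A named list or one-row `data.frame` carrying `qual`
#'   and any of `QD, FS, MQ, MQRankSum, ReadPosRankSum`.
#' @param class `"snp"` or `"indel"`.
#' @param thresholds Optional list overriding the per-class defaults; each
#'   entry is `c(direction, bound)` with direction `"lt"` (fail when metric
#'   is below the bound) or `"gt"` (fail when above).
#' @param min_qual Minimum call confidence, default 30.
#' @return A list with logical `pass` and character vector `reasons`
#'   (empty when passing).
#' @export
apply_germline_hard_filters <- function(site_metrics,
                                        class = c("snp", "indel"),
                                        thresholds = NULL, min_qual = 30) {
  if (length(class) != 1L || !class %in% c("snp", "indel")) {
    stop(sprintf("unknown variant class: %s", paste(class, collapse = ",")),
         call. = FALSE)
  }
  th <- if (is.null(thresholds)) .hard_filter_defaults[[class]] else thresholds
  sm <- as.list(site_metrics)
  reasons <- character()
  qual <- suppressWarnings(as.numeric(sm$qual))
  if (is.null(sm$qual) || is.na(qual) || qual < min_qual) {
    reasons <- c(reasons, "low_qual")
  }
  for (metric in names(th)) {
    val <- suppressWarnings(as.numeric(sm[[metric]]))
    if (is.null(sm[[metric]]) || length(val) == 0L || is.na(val)) next
    dir <- th[[metric]][1]
    bound <- as.numeric(th[[metric]][2])
    violated <- if (dir == "lt") val < bound else val > bound
    if (violated) reasons <- c(reasons, metric)
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}
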