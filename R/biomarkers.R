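# evidence tiers, ascending: pre-clinical data up to FDA guidelines
.evidence_tiers <- c("pre_clinical", "case_report", "early_trials",
                     "late_trials", "clinical_guidelines", "fda_guidelines")

#' Ordered evidence-tier vocabulary
#'
#' @return Character vector of tiers in ascending strength:
#'   `pre_clinical < case_report < early_trials < late_trials <
#'   clinical_guidelines < fda_guidelines`.
#' @export
evidence_tiers <- function() .evidence_tiers

#' @keywords internal
tier_rank <- function(tier) match(tier, .evidence_tiers)

#' Load a drug-biomarker knowledge base
#'
#' Reads a TSV with columns `gene, match_kind, protein_change, drug,
#' effect, evidence_tier, tumor_types` (semicolon-joined tumor types).
#' Rules are validated (known tier and effect labels; exact rules carry a
#' protein change) and duplicate `(gene, protein_change, drug)` rows are
#' collapsed keeping the highest evidence tier.
#'
#' @param path Path to the knowledge-base TSV.
#' @return A validated `data.frame` of biomarker rules.
#' @export
load_knowledge_base <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing file: %s", path), call. = FALSE)
  kb <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = "",
                          check.names = FALSE)
  req <- c("gene", "match_kind", "protein_change", "drug", "effect",
           "evidence_tier", "tumor_types")
  miss <- setdiff(req, names(kb))
  if (length(miss)) {
    stop(sprintf("knowledge base lacks columns: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  bad_tier <- setdiff(unique(kb$evidence_tier), .evidence_tiers)
  if (length(bad_tier)) {
    stop(sprintf("unknown evidence tier: %s", paste(bad_tier, collapse = ", ")),
         call. = FALSE)
  }
  bad_eff <- setdiff(unique(kb$effect), c("responsive", "resistant"))
  if (length(bad_eff)) {
    stop(sprintf("unknown effect: %s", paste(bad_eff, collapse = ", ")),
         call. = FALSE)
  }
  bad_kind <- setdiff(unique(kb$match_kind),
                      c("exact_protein_change", "gene_level"))
  if (length(bad_kind)) {
    stop(sprintf("unknown match kind: %s", paste(bad_kind, collapse = ", ")),
         call. = FALSE)
  }
  exact_empty <- kb$match_kind == "exact_protein_change" &
    (is.na(kb$protein_change) | !nzchar(kb$protein_change))
  if (any(exact_empty)) {
    stop("exact_protein_change rules must carry a protein change",
         call. = FALSE)
  }
  kb$protein_change[is.na(kb$protein_change)] <- ""
  kb$tumor_types[is.na(kb$tumor_types)] <- ""
  # collapse duplicates, keeping the highest tier
  key <- paste(kb$gene, kb$protein_change, kb$drug, sep = "\r")
  ord <- order(key, -tier_rank(kb$evidence_tier))
  kb <- kb[ord, , drop = FALSE]
  kb <- kb[!duplicated(key[ord]), , drop = FALSE]
  kb <- kb[order(kb$gene, kb$protein_change, kb$drug), , drop = FALSE]
  rownames(kb) <- NULL
  kb
}

# consequences that affect the protein product (eligible for gene-level rules)
.protein_affecting <- c("missense", "nonsense", "frameshift_del",
                        "frameshift_ins", "inframe_del", "inframe_ins",
                        "splice_site")

#' Match classified variants against the knowledge base
#'
#' Exact protein-change rules are matched first; gene-level rules apply to
#' any protein-affecting variant of the gene. Only somatic-category
#' variants are eligible by default. Per `(sample, variant, drug)` a single
#' hit is kept, at the highest supporting tier. A rule's tumor-type
#' applicability is reported but never suppresses a hit.
#'
#' @param classified Classified variant `data.frame` (needs `gene`,
#'   `protein_change`, `consequence`, `category`; `sample_id` optional).
#' @param kb Knowledge base from [load_knowledge_base()].
#' @param eligible_categories Categories eligible for matching; default the
#'   somatic family.
#' @return A `data.frame` of hits: variant key columns, `sample_id`,
#'   `gene`, `protein_change`, `drug`, `effect`, `evidence_tier`,
#'   `match_kind`, `tumor_types`.
#' @export
match_biomarkers <- function(classified, kb,
                             eligible_categories = somatic_family()) {
  empty <- data.frame(
    sample_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), gene = character(),
    protein_change = character(), drug = character(), effect = character(),
    evidence_tier = character(), match_kind = character(),
    tumor_types = character(), stringsAsFactors = FALSE
  )
  v <- classified[classified$category %in% eligible_categories, , drop = FALSE]
  if (nrow(v) == 0L || nrow(kb) == 0L) return(empty)
  if (is.null(v$sample_id)) v$sample_id <- NA_character_
  v$protein_change[is.na(v$protein_change)] <- ""

  hits <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    exact <- kb$match_kind == "exact_protein_change" & kb$gene == v$gene[i] &
      kb$protein_change == v$protein_change[i] & nzchar(v$protein_change[i])
    gene_lvl <- kb$match_kind == "gene_level" & kb$gene == v$gene[i] &
      v$consequence[i] %in% .protein_affecting
    rules <- kb[exact | gene_lvl, , drop = FALSE]
    if (nrow(rules) == 0L) next
    hits[[i]] <- data.frame(
      sample_id = v$sample_id[i], chrom = v$chrom[i], pos = v$pos[i],
      ref = v$ref[i], alt = v$alt[i], gene = v$gene[i],
      protein_change = v$protein_change[i], drug = rules$drug,
      effect = rules$effect, evidence_tier = rules$evidence_tier,
      match_kind = rules$match_kind, tumor_types = rules$tumor_types,
      stringsAsFactors = FALSE
    )
  }
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  # one hit per (sample, variant, drug), highest tier wins
  key <- paste(out$sample_id, out$chrom, out$pos, out$ref, out$alt, out$drug,
               sep = "\r")
  ord <- order(key, -tier_rank(out$evidence_tier))
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(key[ord]), , drop = FALSE]
  out <- out[order(out$sample_id, out$chrom, out$pos, out$alt, out$drug), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of somatic-category variants with at least one biomarker hit
#'
#' @param classified Classified variant `data.frame`.
#' @param hits Hits from [match_biomarkers()].
#' @param eligible_categories Denominator categories, default the somatic
#'   family.
#' @return Fraction in `[0, 1]`.
#' @export
biomarker_fraction <- function(classified, hits,
                               eligible_categories = somatic_family()) {
  v <- classified[classified$category %in% eligible_categories, , drop = FALSE]
  if (nrow(v) == 0L) stop("no eligible variants", call. = FALSE)
  if (is.null(v$sample_id)) v$sample_id <- NA_character_
  vk <- paste(v$sample_id, variant_key(v))
  hk <- paste(hits$sample_id, variant_key(hits))
  mean(vk %in% hk)
}

#' Per-category variant counts (total and unique)
#'
#' For each of the six origin categories: `total` is the occurrence count
#' across samples and `unique` the number of distinct normalized genomic
#' keys. A grand-total row is appended. Categories with no variants are
#' reported with zeros.
#'
#' @param classified Classified variant `data.frame` (with `sample_id`).
#' @return A `data.frame` with columns `category, total, unique`.
#' @export
summarize_classification <- function(classified) {
  cats <- variant_categories()
  rows <- lapply(cats, function(cat) {
    v <- classified[classified$category == cat, , drop = FALSE]
    data.frame(category = cat, total = nrow(v),
               unique = length(unique(variant_key(v))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  all_unique <- length(unique(variant_key(classified)))
  rbind(out, data.frame(category = "total", total = nrow(classified),
                        unique = all_unique, stringsAsFactors = FALSE))
}

#' Gene-by-tumor-type mutation count matrix
#'
#' Counts classified variants per `(gene, tumor type)`, sub-stratified by
#' consequence class, with row and column marginals.
#'
#' @param classified Classified variant `data.frame` with `sample_id` and
#'   `gene`.
#' @param sample_meta `data.frame` mapping `sample_id` to `tumor_type`.
#' @return A list with `counts` (gene x tumor-type matrix),
#'   `by_consequence` (long `data.frame` gene/tumor_type/consequence/n),
#'   `gene_totals`, `type_totals`.
#' @export
gene_tumor_matrix <- function(classified, sample_meta) {
  missing_ids <- setdiff(unique(classified$sample_id), sample_meta$sample_id)
  if (length(missing_ids)) {
    stop(sprintf("samples without metadata: %s",
                 paste(missing_ids, collapse = ", ")), call. = FALSE)
  }
  tumor <- sample_meta$tumor_type[match(classified$sample_id,
                                        sample_meta$sample_id)]
  counts <- table(gene = classified$gene, tumor_type = tumor)
  counts <- unclass(counts)
  long <- as.data.frame(table(gene = classified$gene, tumor_type = tumor,
                              consequence = classified$consequence),
                        responseName = "n", stringsAsFactors = FALSE)
  long <- long[long$n > 0L, , drop = FALSE]
  rownames(long) <- NULL
  list(counts = counts, by_consequence = long,
       gene_totals = rowSums(counts), type_totals = colSums(counts))
}

#' Percentage with half-up rounding
#'
#' `100 * n / d`, rounded half-up to the requested number of decimals
#' (matching the reporting convention where e.g. 84.73% prints as 85%).
#'
#' @param numerator,denominator Counts; `denominator` must be positive.
#' @param decimals Decimal places, default 1.
#' @return Numeric percentage.
#' @export
percent <- function(numerator, denominator, decimals = 1L) {
  if (any(denominator <= 0)) stop("denominator must be > 0", call. = FALSE)
  scale <- 10^decimals
  floor(100 * numerator / denominator * scale + 0.5) / scale
}

#' Pearson correlation of paired VAFs
#'
#' @param vaf_a,vaf_b Paired numeric vectors of VAFs (>= 2 finite pairs).
#' @return A list with `r` (Pearson product-moment coefficient) and
#'   `n_pairs`.
#' @export
vaf_concordance <- function(vaf_a, vaf_b) {
  if (length(vaf_a) != length(vaf_b)) {
    stop("paired VAF vectors must have equal length", call. = FALSE)
  }
  ok <- is.finite(vaf_a) & is.finite(vaf_b)
  x <- vaf_a[ok]; y <- vaf_b[ok]
  if (length(x) < 2L) stop("need at least 2 finite pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in a VAF vector", call. = FALSE)
  }
  list(r = stats::cor(x, y, method = "pearson"), n_pairs = length(x))
}

#' Concordance between two variant sets
#'
#' Set operations on normalized `(chrom, pos, ref, alt)` keys.
#'
#' @param variants_a,variants_b Variant `data.frame`s (normalized keys) or
#'   character vectors of keys.
#' @return A list with `shared`, `only_a`, `only_b`, `jaccard`.
#' @export
set_concordance <- function(variants_a, variants_b) {
  ka <- if (is.data.frame(variants_a)) unique(variant_key(variants_a)) else
    unique(as.character(variants_a))
  kb <- if (is.data.frame(variants_b)) unique(variant_key(variants_b)) else
    unique(as.character(variants_b))
  shared <- length(intersect(ka, kb))
  uni <- length(union(ka, kb))
  list(shared = shared, only_a = length(setdiff(ka, kb)),
       only_b = length(setdiff(kb, ka)),
       jaccard = if (uni == 0L) NA_real_ else shared / uni)
}
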