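#' Normalize variant representations to a minimal anchored form
#'
#' Reduces `(chrom, pos, ref, alt)` to the minimal representation shared by
#' all callers so that calls from different VCFs are comparable: shared
#' trailing bases are trimmed first, then shared leading bases are trimmed
#' with `pos` advanced, always retaining a single anchor base when either
#' allele would otherwise become empty (the usual VCF indel anchor).
#' The operation is idempotent.
#'
#' @param chrom Contig identifier(s).
#' @param pos 1-based position(s), integer.
#' @param ref Reference allele string(s) over `A,C,G,T,N`.
#' @param alt Alternate allele string(s) over `A,C,G,T,N`.
#' @return A `data.frame` with columns `chrom`, `pos`, `ref`, `alt`, one row
#'   per input variant.
#' @examples
#' normalize_variant("chr1", 100, "ATG", "ATA")  # -> chr1:102 G>A
#' normalize_variant("chr1", 100, "CTT", "CT")   # -> chr1:100 CT>C
#' @export
normalize_variant <- function(chrom, pos, ref, alt) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  ref <- rep_len(toupper(as.character(ref)), n)
  alt <- rep_len(toupper(as.character(alt)), n)

  if (any(is.na(pos)) || any(pos < 1L)) {
    stop("invalid variant: pos must be a positive integer", call. = FALSE)
  }
  bad <- !grepl("^[ACGTN]+$", ref) | !grepl("^[ACGTN]+$", alt)
  if (any(bad)) {
    stop(sprintf(
      "format error: alleles must be non-empty strings over {A,C,G,T,N} (offending: %s>%s)",
      ref[which(bad)[1]], alt[which(bad)[1]]
    ), call. = FALSE)
  }

  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    # trim shared trailing bases while both alleles keep >= 1 base
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # trim shared leading bases, advancing pos, keeping the anchor base
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    if (r == a) {
      stop(sprintf("invalid variant: ref equals alt after trimming at %s:%d",
                   chrom[i], pos[i]), call. = FALSE)
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' @keywords internal
variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' @keywords internal
variant_class_of <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "snv", "indel")
}

#' @keywords internal
harmonize_contig <- function(chrom, style = c("as-is", "strip", "add")) {
  style <- match.arg(style)
  switch(style,
    "as-is" = chrom,
    "strip" = sub("^chr", "", chrom),
    "add"   = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
  )
}

#' Read one caller's VCF into a table of calls
#'
#' Parses a VCF 4.2 file produced by a single somatic caller and returns one
#' row per ALT allele with the caller's VAF and depths. Multi-allelic records
#' are split before normalization, taking per-allele alt depths from the
#' ordered `AD` field. Records failing the caller's own `FILTER` column are
#' retained but flagged `passed_caller_filter = FALSE`; the consensus stage
#' decides whether they count as support. When the VAF tag is absent the VAF
#' is recomputed as `alt_depth / total_depth`.
#'
#' @param path Path to a VCF file.
#' @param caller_id Identifier of the caller that produced the file.
#' @param tag_map Named list telling which FORMAT (first) or INFO (fallback)
#'   keys hold the VAF, alt depth and total depth; default
#'   `list(vaf = "AF", alt_depth = "AD", total_depth = "DP")`.
#' @param chr_style One of `"as-is"`, `"strip"`, `"add"`: how to harmonize
#'   `chr` prefixes across callers.
#' @return A `data.frame` of calls with columns `chrom, pos, ref, alt,
#'   variant_class, caller_id, vaf, alt_depth, total_depth,
#'   passed_caller_filter`. Records that could not be quantified are skipped
#'   with a warning; the count is available as `attr(x, "n_skipped")`.
#' @export
read_caller_vcf <- function(path, caller_id,
                            tag_map = list(vaf = "AF", alt_depth = "AD",
                                           total_depth = "DP"),
                            chr_style = "as-is") {
  if (!file.exists(path)) {
    stop(sprintf("missing file: %s", path), call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  empty <- data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), variant_class = character(), caller_id = character(),
    vaf = numeric(), alt_depth = integer(), total_depth = integer(),
    passed_caller_filter = logical(), stringsAsFactors = FALSE
  )
  if (is.null(fix) || nrow(fix) == 0L) {
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }

  get_field <- function(key) {
    val <- rep(NA_character_, nrow(fix))
    has_gt <- ncol(vcf@gt) >= 2L
    if (has_gt && any(grepl(paste0("(^|:)", key, "(:|$)"), vcf@gt[, 1L]))) {
      m <- vcfR::extract.gt(vcf, element = key, as.numeric = FALSE)
      val <- as.character(m[, 1L])
    }
    miss <- is.na(val)
    if (any(miss)) {
      info <- vcfR::extract.info(vcf, element = key)
      if (!is.null(info)) val[miss] <- info[miss]
    }
    val
  }

  ad_raw <- get_field(tag_map$alt_depth)
  dp_raw <- get_field(tag_map$total_depth)
  af_raw <- if (!is.null(tag_map$vaf)) get_field(tag_map$vaf) else
    rep(NA_character_, nrow(fix))

  out <- vector("list", nrow(fix))
  n_skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    alts <- alts[!is.na(alts)]
    ad <- suppressWarnings(as.integer(strsplit(
      ifelse(is.na(ad_raw[i]), "", ad_raw[i]), ",", fixed = TRUE)[[1]]))
    af <- suppressWarnings(as.numeric(strsplit(
      ifelse(is.na(af_raw[i]), "", af_raw[i]), ",", fixed = TRUE)[[1]]))
    dp <- suppressWarnings(as.integer(dp_raw[i]))
    filt <- fix[i, "FILTER"]
    passed <- is.na(filt) || filt %in% c("PASS", ".")

    rows <- vector("list", length(alts))
    for (j in seq_along(alts)) {
      if (grepl("[^ACGTNacgtn]", alts[j])) {  # symbolic / spanning alleles
        n_skipped <- n_skipped + 1L
        next
      }
      alt_dp <- if (length(ad) >= j + 1L) ad[j + 1L] else NA_integer_
      tot <- if (!is.na(dp)) dp else if (length(ad) >= 2L)
        sum(ad, na.rm = TRUE) else NA_integer_
      vaf <- if (length(af) >= j && !is.na(af[j])) af[j] else
        if (length(af) == 1L && !is.na(af[1L])) af[1L] else NA_real_
      if (is.na(vaf)) {
        if (!is.na(alt_dp) && !is.na(tot) && tot > 0L) {
          vaf <- alt_dp / tot
        } else {
          warning(sprintf(
            "record %s:%s %s>%s skipped: no VAF tag and depths unavailable",
            fix[i, "CHROM"], fix[i, "POS"], fix[i, "REF"], alts[j]),
            call. = FALSE)
          n_skipped <- n_skipped + 1L
          next
        }
      }
      nv <- normalize_variant(fix[i, "CHROM"], as.integer(fix[i, "POS"]),
                              fix[i, "REF"], alts[j])
      rows[[j]] <- data.frame(
        chrom = harmonize_contig(nv$chrom, chr_style), pos = nv$pos,
        ref = nv$ref, alt = nv$alt,
        variant_class = variant_class_of(nv$ref, nv$alt),
        caller_id = caller_id, vaf = vaf,
        alt_depth = alt_dp, total_depth = tot,
        passed_caller_filter = passed, stringsAsFactors = FALSE
      )
    }
    out[[i]] <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Read a target-region BED file
#'
#' Reads a BED3+ file (0-based, half-open), validates each interval, and
#' returns regions sorted and merged per chromosome (overlapping or
#' book-ended intervals are unioned). Internally the merge is done on
#' genomic ranges; coordinates in the returned table remain 0-based
#' half-open as in BED.
#'
#' @param path Path to a BED file.
#' @return A `data.frame` with columns `chrom, start, end, name`; the total
#'   target length is `sum(end - start)`.
#' @export
read_targets_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing file: %s", path), call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines[idx], "[ \t]+")
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    if (length(p) < 3L) {
      stop(sprintf("format error at line %d: expected >= 3 BED columns",
                   idx[k]), call. = FALSE)
    }
    s <- suppressWarnings(as.integer(p[2])); e <- suppressWarnings(as.integer(p[3]))
    if (is.na(s) || is.na(e) || s >= e) {
      stop(sprintf("format error at line %d: start >= end (%s >= %s)",
                   idx[k], p[2], p[3]), call. = FALSE)
    }
  }
  chrom <- vapply(parts, `[`, "", 1L)
  start0 <- vapply(parts, function(p) as.integer(p[2]), 1L)
  end0 <- vapply(parts, function(p) as.integer(p[3]), 1L)
  name <- vapply(parts, function(p) if (length(p) >= 4L) p[4] else NA_character_, "")

  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  red <- GenomicRanges::sort(red)
  revmap <- S4Vectors::mcols(red)$revmap
  merged_name <- vapply(seq_along(red), function(i) {
    nm <- name[revmap[[i]]]
    nm <- nm[!is.na(nm)]
    if (length(nm)) paste(unique(nm), collapse = ",") else
      sprintf("region_%d", i)
  }, "")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    name = merged_name, stringsAsFactors = FALSE
  )
}

# column layout of the annotation TSV dialect; everything matching
# pop_af_pattern is a (database, subpopulation) allele-frequency column
.ann_fixed_cols <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
                     "protein_change", "dbsnp_id", "cosmic_id",
                     "cosmic_count", "clinvar_sig", "local_db_af")
.pop_af_pattern <- "^(gnomad(_genome|_exome)?|exac|g1000|esp6500)_"

#' @keywords internal
pop_af_columns <- function(ann) {
  grep(.pop_af_pattern, tolower(names(ann)), value = FALSE)
}

#' Read a variant annotation table
#'
#' Ingests the tabular product of an external annotation engine: one row per
#' variant carrying gene, consequence, protein change, database identifiers
#' (dbSNP, COSMIC, ClinVar), a local-database allele frequency, and one
#' column per (population database, subpopulation) allele frequency, e.g.
#' `gnomad_genome_AMR`, `exac_ALL`, `g1000_ALL`, `esp6500_ALL`. Empty cells
#' are read as *absent* (`NA`), which is distinct from an AF of zero.
#'
#' @param path Path to a tab-separated annotation file.
#' @return A `data.frame`, variants normalized, keyed by
#'   `(chrom, pos, ref, alt)`.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing file: %s", path), call. = FALSE)
  ann <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = "",
                           check.names = FALSE)
  missing_cols <- setdiff(.ann_fixed_cols, names(ann))
  if (length(missing_cols)) {
    stop(sprintf("format error: annotation table lacks columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  known <- names(ann) %in% .ann_fixed_cols |
    grepl(.pop_af_pattern, tolower(names(ann)))
  if (any(!known)) {
    warning(sprintf("ignoring unknown annotation columns: %s",
                    paste(names(ann)[!known], collapse = ", ")),
            call. = FALSE)
    ann <- ann[, known, drop = FALSE]
  }
  nv <- normalize_variant(ann$chrom, as.integer(ann$pos), ann$ref, ann$alt)
  ann$chrom <- nv$chrom; ann$pos <- nv$pos; ann$ref <- nv$ref; ann$alt <- nv$alt
  key <- variant_key(ann)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate variant key in annotation table: %s",
                 key[duplicated(key)][1]), call. = FALSE)
  }
  ann$cosmic_count <- as.integer(ifelse(is.na(ann$cosmic_count), 0L,
                                        ann$cosmic_count))
  ann$local_db_af <- as.numeric(ann$local_db_af)
  for (j in pop_af_columns(ann)) ann[[j]] <- as.numeric(ann[[j]])
  afs <- unlist(ann[pop_af_columns(ann)], use.names = FALSE)
  afs <- c(afs, ann$local_db_af)
  if (any(afs < 0 | afs > 1, na.rm = TRUE)) {
    stop("format error: population allele frequencies must lie in [0, 1]",
         call. = FALSE)
  }
  rownames(ann) <- NULL
  ann
}

#' Write an annotation table
#'
#' Inverse of [read_annotation_table()]: absent values are written as empty
#' cells so that a read/write cycle is lossless.
#'
#' @param ann Annotation `data.frame`.
#' @param path Output path.
#' @export
write_annotation_table <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Write variant tables to TSV or a minimal VCF
#'
#' Serializes a variant table (consensus or classified) with a deterministic
#' column/field order so that [read_variants()] returns an equal table.
#' In VCF mode the required columns `chrom, pos, ref, alt` map to the fixed
#' fields and every remaining column is carried as an `INFO` `KEY=value`
#' pair; multi-valued columns must already be pipe-joined strings.
#'
#' @param records Variant `data.frame` with at least `chrom, pos, ref, alt`.
#' @param path Output path.
#' @param format `"tsv"` or `"vcf"`.
#' @export
write_variants <- function(records, path, format = c("tsv", "vcf")) {
  if (length(format) != 1L || !format %in% c("tsv", "vcf")) {
    stop(sprintf("unsupported format: %s", paste(format, collapse = ",")),
         call. = FALSE)
  }
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(records))) {
    stop("records must carry chrom, pos, ref, alt columns", call. = FALSE)
  }
  if (format == "tsv") {
    utils::write.table(records, path, sep = "\t", quote = FALSE, na = "",
                       row.names = FALSE)
    return(invisible(path))
  }
  extra <- setdiff(names(records), req)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=panelclassify",
    sprintf("##panelclassify_columns=%s", paste(extra, collapse = ",")),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"%s\">",
            toupper(extra), extra),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  fmt_val <- function(x) {
    if (is.numeric(x)) vapply(x, function(v)
      if (is.na(v)) "." else format(v, digits = 15, scientific = FALSE,
                                    trim = TRUE), "")
    else ifelse(is.na(x) | !nzchar(as.character(x)), ".", as.character(x))
  }
  info <- if (length(extra)) {
    cols <- lapply(extra, function(cn) paste0(toupper(cn), "=",
                                              fmt_val(records[[cn]])))
    do.call(function(...) paste(..., sep = ";"), cols)
  } else rep(".", nrow(records))
  body <- if (nrow(records)) {
    paste(records$chrom, records$pos, ".", records$ref, records$alt, ".",
          "PASS", info, sep = "\t")
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a variant table written by [write_variants()]
#'
#' @param path Input path.
#' @param format `"tsv"` or `"vcf"`.
#' @return A `data.frame` equal to the one written.
#' @export
read_variants <- function(path, format = c("tsv", "vcf")) {
  if (length(format) != 1L || !format %in% c("tsv", "vcf")) {
    stop(sprintf("unsupported format: %s", paste(format, collapse = ",")),
         call. = FALSE)
  }
  if (!file.exists(path)) stop(sprintf("missing file: %s", path), call. = FALSE)
  if (format == "tsv") {
    hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    # allele columns must never be type-converted ("T" is not a logical)
    cls <- rep(NA_character_, length(hdr))
    cls[hdr %in% c("chrom", "ref", "alt")] <- "character"
    out <- utils::read.delim(path, sep = "\t", header = TRUE,
                             na.strings = "", colClasses = cls,
                             stringsAsFactors = FALSE)
    return(out)
  }
  lines <- readLines(path)
  col_line <- grep("^##panelclassify_columns=", lines, value = TRUE)
  extra <- if (length(col_line) && nzchar(sub("^##panelclassify_columns=", "", col_line[1]))) {
    strsplit(sub("^##panelclassify_columns=", "", col_line[1]), ",")[[1]]
  } else character()
  body <- lines[!grepl("^#", lines)]
  base_cols <- data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          stringsAsFactors = FALSE)
  if (!length(body)) {
    for (cn in extra) base_cols[[cn]] <- character()
    return(base_cols)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(f, `[`, "", 1L),
    pos = as.integer(vapply(f, `[`, "", 2L)),
    ref = vapply(f, `[`, "", 4L),
    alt = vapply(f, `[`, "", 5L),
    stringsAsFactors = FALSE
  )
  if (length(extra)) {
    info <- vapply(f, `[`, "", 8L)
    pairs <- strsplit(info, ";", fixed = TRUE)
    for (cn in extra) {
      key <- paste0(toupper(cn), "=")
      raw <- vapply(pairs, function(p) {
        hit <- p[startsWith(p, key)]
        if (length(hit)) substring(hit[1], nchar(key) + 1L) else "."
      }, "")
      raw[raw == "."] <- NA_character_
      out[[cn]] <- utils::type.convert(raw, as.is = TRUE)
    }
  }
  out
}
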