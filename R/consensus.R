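#' Consensus configuration
#'
#' Holds the caller sets and support thresholds for majority-vote merging.
#' Defaults mirror the validated panel workflow: five SNV callers with a
#' minimum of three supporting callers, and the same five plus an
#' indel-specialist caller (six total) with a minimum of three for indels.
#'
#' @param snv_callers Ordered SNV caller identifiers.
#' @param indel_callers Ordered indel caller identifiers.
#' @param min_support_snv Minimum supporting callers for an SNV (default 3).
#' @param min_support_indel Minimum supporting callers for an indel
#'   (default 3).
#' @param count_nonpass Should calls failing the caller's own FILTER count
#'   as support? Default `FALSE`.
#' @param vaf_aggregation `"median"` (default) or `"primary_caller"`.
#' @param primary_caller Caller whose fields are reported when
#'   `vaf_aggregation = "primary_caller"`.
#' @return A list of class `consensus_config`.
#' @export
consensus_config <- function(snv_callers = c("mutect2", "varscan2", "vardict",
                                             "lofreq", "strelka"),
                             indel_callers = c(snv_callers, "scalpel"),
                             min_support_snv = 3L,
                             min_support_indel = 3L,
                             count_nonpass = FALSE,
                             vaf_aggregation = c("median", "primary_caller"),
                             primary_caller = NULL) {
  vaf_aggregation <- match.arg(vaf_aggregation)
  min_support_snv <- as.integer(min_support_snv)
  min_support_indel <- as.integer(min_support_indel)
  if (min_support_snv < 1L || min_support_snv > length(snv_callers)) {
    stop("configuration error: min_support_snv must lie in [1, |snv_callers|]",
         call. = FALSE)
  }
  if (min_support_indel < 1L || min_support_indel > length(indel_callers)) {
    stop("configuration error: min_support_indel must lie in [1, |indel_callers|]",
         call. = FALSE)
  }
  if (vaf_aggregation == "primary_caller" &&
      (is.null(primary_caller) ||
       !primary_caller %in% union(snv_callers, indel_callers))) {
    stop("configuration error: primary_caller must belong to a caller set",
         call. = FALSE)
  }
  structure(list(
    snv_callers = snv_callers, indel_callers = indel_callers,
    min_support_snv = min_support_snv, min_support_indel = min_support_indel,
    count_nonpass = count_nonpass, vaf_aggregation = vaf_aggregation,
    primary_caller = primary_caller
  ), class = "consensus_config")
}

#' Aggregate VAF and depths over supporting calls
#'
#' Default aggregation is the per-field median over supporting callers
#' (even count: mean of the two middle values; depths rounded half-up to
#' integers). In `primary_caller` mode the primary caller's fields are
#' reported verbatim; it is an error if that caller is not a supporter.
#'
#' @param supporting_calls `data.frame` of calls with `caller_id, vaf,
#'   alt_depth, total_depth`; at least one row.
#' @param config A [consensus_config()].
#' @return A list with `vaf`, `alt_depth`, `total_depth`.
#' @export
aggregate_vaf <- function(supporting_calls, config = consensus_config()) {
  if (is.null(supporting_calls) || nrow(supporting_calls) == 0L) {
    stop("empty support set", call. = FALSE)
  }
  if (config$vaf_aggregation == "primary_caller") {
    hit <- supporting_calls[supporting_calls$caller_id == config$primary_caller, ,
                            drop = FALSE]
    if (nrow(hit) == 0L) {
      stop(sprintf("primary caller %s is not a supporter",
                   config$primary_caller), call. = FALSE)
    }
    return(list(vaf = hit$vaf[1], alt_depth = as.integer(hit$alt_depth[1]),
                total_depth = as.integer(hit$total_depth[1])))
  }
  round_half_up <- function(x) as.integer(floor(x + 0.5))
  list(
    vaf = stats::median(supporting_calls$vaf),
    alt_depth = round_half_up(stats::median(supporting_calls$alt_depth)),
    total_depth = round_half_up(stats::median(supporting_calls$total_depth))
  )
}

#' Merge per-caller call sets into consensus variants
#'
#' Majority-vote consensus: a normalized variant is reported when it is
#' supported by at least `min_support_snv` callers of the SNV set (SNVs) or
#' `min_support_indel` callers of the indel set (indels). By default only
#' calls passing the caller's own FILTER count as support. Output rows are
#' ordered by `(chrom, pos, ref, alt)`.
#'
#' @param calls `data.frame` of caller calls (rows as returned by
#'   [read_caller_vcf()], possibly concatenated over callers).
#' @param config A [consensus_config()].
#' @return A `data.frame` with columns `chrom, pos, ref, alt, variant_class,
#'   n_support, supporting_callers` (pipe-joined, caller-set order),
#'   `vaf, alt_depth, total_depth`.
#' @export
merge_callers <- function(calls, config = consensus_config()) {
  all_callers <- union(config$snv_callers, config$indel_callers)
  empty <- data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), variant_class = character(), n_support = integer(),
    supporting_callers = character(), vaf = numeric(), alt_depth = integer(),
    total_depth = integer(), stringsAsFactors = FALSE
  )
  if (is.null(calls) || nrow(calls) == 0L) return(empty)
  unknown <- setdiff(unique(calls$caller_id), all_callers)
  if (length(unknown)) {
    stop(sprintf("configuration error: caller(s) outside configured sets: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (!config$count_nonpass) {
    calls <- calls[calls$passed_caller_filter, , drop = FALSE]
  }
  if (nrow(calls) == 0L) return(empty)

  # support is only counted from callers in the class-relevant set
  rel_set <- ifelse(calls$variant_class == "snv",
                    calls$caller_id %in% config$snv_callers,
                    calls$caller_id %in% config$indel_callers)
  calls <- calls[rel_set, , drop = FALSE]
  if (nrow(calls) == 0L) return(empty)

  key <- paste(variant_key(calls), calls$variant_class, sep = "@")
  groups <- split(seq_len(nrow(calls)), key)
  rows <- lapply(groups, function(ix) {
    g <- calls[ix, , drop = FALSE]
    g <- g[!duplicated(g$caller_id), , drop = FALSE]
    min_needed <- if (g$variant_class[1] == "snv") config$min_support_snv else
      config$min_support_indel
    if (nrow(g) < min_needed) return(NULL)
    set_order <- if (g$variant_class[1] == "snv") config$snv_callers else
      config$indel_callers
    agg <- aggregate_vaf(g, config)
    data.frame(
      chrom = g$chrom[1], pos = g$pos[1], ref = g$ref[1], alt = g$alt[1],
      variant_class = g$variant_class[1], n_support = nrow(g),
      supporting_callers = paste(intersect(set_order, g$caller_id),
                                 collapse = "|"),
      vaf = agg$vaf, alt_depth = agg$alt_depth,
      total_depth = agg$total_depth, stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}
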