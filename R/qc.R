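#' Fraction of target regions covered at each depth threshold
#'
#' For each threshold `t`, the fraction of target regions whose (mean)
#' depth is at least `t`.
#'
#' @param depths Numeric vector, one mean depth per target region.
#' @param thresholds Depth thresholds, default `c(100, 200, 300, 400, 500)`.
#' @return Named numeric vector of fractions in `[0, 1]`, names are the
#'   thresholds.
#' @export
region_coverage_fractions <- function(depths,
                                      thresholds = c(100, 200, 300, 400, 500)) {
  if (length(depths) == 0L) stop("empty region list", call. = FALSE)
  out <- vapply(thresholds, function(t) mean(depths >= t), 0)
  names(out) <- as.character(thresholds)
  out
}

#' Coverage uniformity
#'
#' Fraction of target bases covered at or above `min_frac` times the mean
#' target depth (the widespread panel convention, with the factor
#' configurable). Defined as 0 when the mean depth is 0.
#'
#' @param per_base_depths Numeric vector of depths over all target bases.
#' @param min_frac Fraction of the mean defining the cutoff, default 0.2.
#' @return A fraction in `[0, 1]`.
#' @export
uniformity <- function(per_base_depths, min_frac = 0.2) {
  if (length(per_base_depths) == 0L) stop("empty depth vector", call. = FALSE)
  mu <- mean(per_base_depths)
  if (mu == 0) return(0)
  mean(per_base_depths >= min_frac * mu)
}

#' Build a per-sample QC summary row
#'
#' Combines region-level and per-base depth information with optional
#' upstream read metrics (raw reads, filtered fraction, duplication rate,
#' on-target reads — ingested from upstream tool summaries, not recomputed
#' from alignments) into one summary row, and applies both pass rules.
#'
#' @param sample_id Sample identifier.
#' @param region_depths Numeric vector of per-region mean depths.
#' @param per_base_depths Optional numeric vector of per-base depths (used
#'   for uniformity; when absent, region means weighted equally stand in).
#' @param upstream Optional named list with any of `raw_reads,
#'   pct_filtered, dup_rate, on_target_reads`.
#' @param thresholds Coverage thresholds for [region_coverage_fractions()].
#' @param min_fraction Minimum fraction of regions at the mode-specific
#'   depth for a sample to pass, default 0.80.
#' @return A one-row `data.frame` (a QC summary).
#' @export
qc_summary <- function(sample_id, region_depths, per_base_depths = NULL,
                       upstream = NULL,
                       thresholds = c(100, 200, 300, 400, 500),
                       min_fraction = 0.80) {
  fr <- region_coverage_fractions(region_depths, thresholds)
  base_depths <- if (is.null(per_base_depths)) region_depths else per_base_depths
  row <- data.frame(
    sample_id = sample_id,
    raw_reads = if (!is.null(upstream$raw_reads)) upstream$raw_reads else NA,
    pct_filtered = if (!is.null(upstream$pct_filtered)) upstream$pct_filtered else NA,
    dup_rate = if (!is.null(upstream$dup_rate)) upstream$dup_rate else NA,
    on_target_reads = if (!is.null(upstream$on_target_reads))
      upstream$on_target_reads else NA,
    mean_target_depth = mean(region_depths),
    uniformity = uniformity(base_depths),
    stringsAsFactors = FALSE
  )
  for (t in names(fr)) row[[paste0("pct_regions_", t, "x")]] <- fr[[t]]
  row$pass_somatic <- sample_pass(row, "somatic", min_fraction = min_fraction)
  row$pass_germline <- sample_pass(row, "germline", min_fraction = min_fraction)
  row
}

#' Per-sample sequencing pass rule
#'
#' Somatic mode requires at least `min_fraction` (default 80%) of target
#' regions covered at 300x or more; germline mode keys the same rule to
#' 200x. Boundaries are inclusive.
#'
#' @param qc A QC summary row ([qc_summary()]) or any list carrying
#'   `pct_regions_300x` / `pct_regions_200x`.
#' @param mode `"somatic"` or `"germline"`.
#' @param min_fraction Minimum fraction of regions, default 0.80.
#' @return Logical flag.
#' @export
sample_pass <- function(qc, mode = c("somatic", "germline"),
                        min_fraction = 0.80) {
  mode <- match.arg(mode)
  col <- if (mode == "somatic") "pct_regions_300x" else "pct_regions_200x"
  val <- qc[[col]]
  if (is.null(val) || length(val) == 0L || is.na(val)) {
    stop(sprintf("required coverage threshold missing from QC summary: %s",
                 col), call. = FALSE)
  }
  as.vector(val >= min_fraction)
}

#' Write the per-sample QC report
#'
#' One row per sample with every metric and both pass flags, written as TSV
#' together with a JSON twin (`<path>.json`) that re-parses to equal
#' values.
#'
#' @param summaries `data.frame` of QC summary rows.
#' @param path Output TSV path.
#' @return Invisibly, the paths of the TSV and JSON files.
#' @export
qc_report <- function(summaries, path) {
  if (is.null(summaries) || nrow(summaries) == 0L) {
    stop("at least one QC summary is required", call. = FALSE)
  }
  utils::write.table(summaries, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  json_path <- paste0(path, ".json")
  jsonlite::write_json(summaries, json_path, dataframe = "rows", na = "null",
                       digits = NA, auto_unbox = FALSE, pretty = TRUE)
  invisible(c(tsv = path, json = json_path))
}
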