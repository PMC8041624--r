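#' Genome quality score
#'
#' The catalog quality score of a genome bin: estimated completeness minus
#' five times estimated contamination. May be negative for heavily
#' contaminated bins.
#'
#' @param completeness CheckM-style completeness estimate, percent in
#'   \[0, 100\].
#' @param contamination CheckM-style contamination estimate, percent >= 0.
#' @return numeric score (same length as the inputs).
#' @examples
#' quality_score(90, 5)   # 65
#' quality_score(50, 0)   # 50, meets the catalog bound
#' @export
quality_score <- function(completeness, contamination) {
  if (!is.numeric(completeness) || !is.numeric(contamination))
    stop("completeness and contamination must be numeric")
  if (any(!is.finite(completeness)) || any(!is.finite(contamination)))
    stop("completeness and contamination must be finite")
  if (any(completeness < 0 | completeness > 100))
    stop("completeness must be in [0, 100]")
  if (any(contamination < 0))
    stop("contamination must be >= 0")
  completeness - 5 * contamination
}

#' Catalog inclusion filter
#'
#' A MAG enters the catalog when its completeness, contamination and quality
#' score all pass their bounds (by default completeness >= 50, contamination
#' <= 5 and score >= 50; the operators are configurable via
#' [mag_thresholds()]).
#'
#' @inheritParams quality_score
#' @param cfg a [mag_thresholds()] configuration.
#' @return logical vector.
#' @export
passes_catalog_filter <- function(completeness, contamination,
                                  cfg = mag_thresholds()) {
  score <- quality_score(completeness, contamination)
  cmp_op(completeness, cfg$completeness_op, cfg$min_completeness) &
    cmp_op(contamination, cfg$contamination_op, cfg$max_contamination) &
    cmp_op(score, cfg$score_op, cfg$min_quality_score)
}

#' MIMAG quality tier
#'
#' Tiers a MAG against the MIMAG standard: `high` requires >= 90%
#' completeness, <= 5% contamination, >= 18 of the 20 standard tRNA isotypes
#' and presence of the 5S, 16S and 23S rRNA genes; `medium` passes the
#' catalog filter but not all four high-quality conditions; `fail` otherwise.
#'
#' @inheritParams passes_catalog_filter
#' @param trna_distinct number of distinct standard tRNA isotypes detected
#'   (0-20).
#' @param rrna_5s,rrna_16s,rrna_23s logical presence flags.
#' @return factor with levels `high`, `medium`, `fail`.
#' @export
mimag_tier <- function(completeness, contamination, trna_distinct,
                       rrna_5s, rrna_16s, rrna_23s,
                       cfg = mag_thresholds()) {
  if (any(trna_distinct < 0 | trna_distinct > 20))
    stop("trna_distinct must be in [0, 20]")
  pass <- passes_catalog_filter(completeness, contamination, cfg)
  high <- completeness >= cfg$mimag_completeness &
    contamination <= cfg$mimag_contamination &
    trna_distinct >= cfg$mimag_trna &
    as.logical(rrna_5s) & as.logical(rrna_16s) & as.logical(rrna_23s)
  tier <- ifelse(pass & high, "high", ifelse(pass, "medium", "fail"))
  factor(tier, levels = c("high", "medium", "fail"))
}

#' Score and tier a table of MAG metadata
#'
#' Convenience wrapper applying [quality_score()], [passes_catalog_filter()]
#' and [mimag_tier()] to a metadata data frame (one row per genome, with
#' columns `genome_id`, `completeness`, `contamination`, `trna_distinct`,
#' `rrna_5s`, `rrna_16s`, `rrna_23s`).
#'
#' @param meta data frame of per-genome metadata.
#' @param cfg a [mag_thresholds()] configuration.
#' @return the input with `quality_score`, `catalog_pass` and `tier`
#'   columns appended.
#' @export
mag_quality <- function(meta, cfg = mag_thresholds()) {
  need <- c("genome_id", "completeness", "contamination", "trna_distinct",
            "rrna_5s", "rrna_16s", "rrna_23s")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  meta$quality_score <- quality_score(meta$completeness, meta$contamination)
  meta$catalog_pass <- passes_catalog_filter(meta$completeness,
                                             meta$contamination, cfg)
  meta$tier <- mimag_tier(meta$completeness, meta$contamination,
                          meta$trna_distinct, meta$rrna_5s, meta$rrna_16s,
                          meta$rrna_23s, cfg)
  meta
}

#' Read MAG metadata from TSV
#'
#' Reads the tab-separated per-genome metadata contract: `genome_id`,
#' `completeness`, `contamination`, `trna_distinct`, `rrna_5s/16s/23s`,
#' `biome`, `sub_biome`, `latitude`, `longitude`, `sample_id`. The rRNA
#' columns are coerced to logical.
#'
#' @param path path to the TSV file (header required, UTF-8).
#' @return data frame with validated ranges.
#' @export
read_mag_metadata <- function(path) {
  meta <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  if (!"genome_id" %in% names(meta)) stop("metadata must have genome_id")
  for (col in c("rrna_5s", "rrna_16s", "rrna_23s")) {
    if (col %in% names(meta)) meta[[col]] <- as.logical(meta[[col]])
  }
  if (anyDuplicated(meta$genome_id))
    stop("duplicated genome_id in metadata")
  meta
}
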