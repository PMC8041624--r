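#' Map a detector BGC family to one of six broad groups
#'
#' Looks the detector-assigned family label up in a shipped, editable
#' mapping table covering the common antiSMASH-style family names and
#' returns one of `PKS`, `NRPS`, `terpene`, `RiPP`, `AAmodifier` or
#' `other`. Unknown families map to `other` with a warning. Matching is
#' case-insensitive.
#'
#' @param family character vector of family labels (non-empty strings).
#' @param map optional replacement mapping: data frame with columns
#'   `family` and `group` (defaults to the shipped table, see
#'   [bgc_group_map()]).
#' @return character vector of group labels.
#' @examples
#' classify_bgc_group(c("lanthipeptide", "terpene"))
#' @export
classify_bgc_group <- function(family, map = bgc_group_map()) {
  if (any(!nzchar(family))) stop("family labels must be non-empty")
  idx <- match(tolower(family), tolower(map$family))
  out <- map$group[idx]
  if (anyNA(idx)) {
    warning("unknown BGC family mapped to 'other': ",
            paste(unique(family[is.na(idx)]), collapse = ", "))
    out[is.na(idx)] <- "other"
  }
  out
}

#' The shipped BGC family-to-group mapping table
#'
#' Curated mapping from detector family labels to the six broad groups,
#' following the class groupings popularized by BGC network-analysis tools
#' (polyketide synthases, nonribosomal peptide synthetases, terpenes,
#' ribosomally synthesized and post-translationally modified peptides,
#' amino-acid-modifying systems, other). Users may edit the TSV at
#' `system.file("extdata", "bgc_group_map.tsv", package = "magcat")` or
#' pass their own table to [classify_bgc_group()].
#'
#' @return data frame with columns `family`, `group`.
#' @export
bgc_group_map <- function() {
  path <- system.file("extdata", "bgc_group_map.tsv", package = "magcat")
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Call BGC novelty against a hit table
#'
#' A region is `redundant` (seen in previous sequencing efforts) when any
#' database hit covers at least `bgc_redundant_cov` (default 80%) of the
#' query length with mean identity of at least `bgc_redundant_ident`
#' (default 75%); otherwise, including when there are no hits, it is
#' `novel`. Boundaries are inclusive. Identity is evaluated per hit
#' (length-weighted mean over that hit's segments, precomputed in the
#' input).
#'
#' @param hits data frame of hits for one region with columns `coverage`
#'   (fraction of the query length matched) and `identity` (mean identity
#'   fraction); zero rows mean no hits.
#' @param cfg a [mag_thresholds()] configuration.
#' @return `"redundant"` or `"novel"`.
#' @export
bgc_novelty <- function(hits, cfg = mag_thresholds()) {
  if (is.null(hits) || nrow(hits) == 0) return("novel")
  redundant <- any(hits$coverage >= cfg$bgc_redundant_cov &
                   hits$identity >= cfg$bgc_redundant_ident)
  if (redundant) "redundant" else "novel"
}

#' Flag regions intersecting a contig boundary
#'
#' `TRUE` when the region touches either contig end (likely fragmented).
#' Coordinates are 0-based half-open: `start == 0` or
#' `end == contig_length`.
#'
#' @param start,end region coordinates (0-based half-open).
#' @param contig_length contig length in bp.
#' @return logical vector.
#' @export
contig_edge_flag <- function(start, end, contig_length) {
  if (any(start < 0 | end <= start | end > contig_length))
    stop("invalid region coordinates (need 0 <= start < end <= contig_length)")
  start == 0 | end == contig_length
}

#' Screen a table of BGC regions
#'
#' Applies [classify_bgc_group()], [bgc_novelty()] and
#' [contig_edge_flag()] to a regions table plus its hit table.
#'
#' @param regions data frame with columns `region_id`, `contig_id`,
#'   `start`, `end`, `family`, `contig_length`.
#' @param hits data frame with columns `region_id`, `coverage`, `identity`
#'   (fractions); regions without rows here are novel.
#' @param cfg a [mag_thresholds()] configuration.
#' @return `regions` with `group`, `novelty` and `contig_edge` appended.
#' @export
bgc_screen <- function(regions, hits = NULL, cfg = mag_thresholds()) {
  regions$group <- classify_bgc_group(regions$family)
  regions$novelty <- vapply(regions$region_id, function(r) {
    h <- if (is.null(hits)) NULL else hits[hits$region_id == r, , drop = FALSE]
    bgc_novelty(h, cfg)
  }, character(1))
  regions$contig_edge <- contig_edge_flag(regions$start, regions$end,
                                          regions$contig_length)
  regions
}
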