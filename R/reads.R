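#' Post-alignment read filters
#'
#' Drops low-quality reads (mean base quality below Q30, shorter than
#' 70 bp, or any ambiguous base call) and poor alignments (edit distance
#' exceeding 5 per 100 bp of read length, i.e. below 95% identity; the
#' bound scales proportionally with read length and is a strict
#' comparison `edit_distance > 0.05 * read_length`). The filters commute:
#' the kept set is independent of application order.
#'
#' @param records data frame with columns `read_length`,
#'   `mean_base_quality`, `ambiguous_bases`, `edit_distance`.
#' @param cfg a [mag_thresholds()] configuration.
#' @return the input with logical `keep` and character `drop_reason`
#'   (first failing filter, `NA` when kept) appended.
#' @export
filter_alignment <- function(records, cfg = mag_thresholds()) {
  q_bad <- records$mean_base_quality < cfg$read_min_qual
  l_bad <- records$read_length < cfg$read_min_len
  a_bad <- records$ambiguous_bases > 0
  e_bad <- records$edit_distance >
    (cfg$read_max_edit_per_100 / 100) * records$read_length
  records$keep <- !(q_bad | l_bad | a_bad | e_bad)
  records$drop_reason <- ifelse(q_bad, "quality",
                         ifelse(l_bad, "length",
                         ifelse(a_bad, "ambiguous",
                         ifelse(e_bad, "edit_distance", NA))))
  records
}

#' Per-sample mapped fractions and fold change between databases
#'
#' For each sample, the mapped fraction for a database is the number of
#' reads kept by [filter_alignment()] and mapped to that database, divided
#' by the total number of (subsampled) reads in the sample. The fold
#' change divides the first database's fraction by the second's; a zero
#' denominator yields an `Inf` sentinel. A read counts as mapped when any
#' of its retained alignments to the database passes the filters.
#'
#' @param records data frame with columns `sample_id`, `read_id`,
#'   `mapped_to` (database id or `NA`), plus the [filter_alignment()]
#'   quality columns. One row per retained alignment; unmapped reads
#'   appear with `mapped_to = NA`.
#' @param db1,db2 database identifiers to compare.
#' @param cfg a [mag_thresholds()] configuration.
#' @return data frame with one row per sample: `sample_id`, `n_reads`,
#'   `frac_db1`, `frac_db2`, `fold_change`.
#' @export
mapped_fraction <- function(records, db1, db2, cfg = mag_thresholds()) {
  if (nrow(records) == 0) stop("empty record table")
  records <- filter_alignment(records, cfg)
  out <- lapply(split(records, records$sample_id), function(rs) {
    n <- length(unique(rs$read_id))
    if (n == 0) stop("empty sample")
    hit <- function(db) {
      ok <- rs$keep & !is.na(rs$mapped_to) & rs$mapped_to == db
      length(unique(rs$read_id[ok])) / n
    }
    f1 <- hit(db1)
    f2 <- hit(db2)
    data.frame(sample_id = rs$sample_id[1], n_reads = n,
               frac_db1 = f1, frac_db2 = f2,
               fold_change = if (f2 > 0) f1 / f2 else Inf,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
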