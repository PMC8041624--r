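#' Anchor-chain average nucleotide identity
#'
#' Desk-scale whole-genome ANI: k-mers unique in both genomes (on either
#' strand) seed anchors; collinear anchors on the same diagonal are chained
#' into gap-free blocks; blocks claim positions greedily by decreasing
#' length so retained runs are one-to-one on both genomes. ANI is the
#' fraction of identical columns over all retained aligned positions, and
#' the aligned fractions divide aligned bp by each genome's total residue
#' length. The statistic is symmetric: swapping the genomes swaps
#' `af_query`/`af_target` and leaves `ani` unchanged.
#'
#' @param genome_a,genome_b character vectors of contig sequences (or
#'   `DNAStringSet`s). `genome_a` is the query.
#' @param anchor_k anchor k-mer size (default 21).
#' @param max_gap largest same-diagonal gap (bp) bridged when chaining
#'   anchors into a block (default 1000).
#' @param min_block shortest aligned run retained (default `anchor_k`).
#' @param query_id,target_id identifiers used in the result row.
#' @return one-row data frame: `query_id`, `target_id`, `ani`, `af_query`,
#'   `af_target`, `aligned_bp`. With no shared anchors all values are 0
#'   (not an error).
#' @examples
#' g <- gen_genome(20000, seed = 7)
#' align_ani(g, g)$ani  # 1
#' @export
align_ani <- function(genome_a, genome_b, anchor_k = 21, max_gap = 1000,
                      min_block = anchor_k,
                      query_id = "query", target_id = "target") {
  a <- as_contigs(genome_a)
  b <- as_contigs(genome_b)
  res <- align_ani_cpp(a, b, as.integer(anchor_k), as.integer(max_gap),
                       as.integer(min_block))
  data.frame(query_id = query_id, target_id = target_id,
             ani = res$ani, af_query = res$af_query,
             af_target = res$af_target, aligned_bp = res$aligned_bp,
             stringsAsFactors = FALSE)
}

#' Two-stage pairwise ANI graph
#'
#' Computes Mash-style sketch distances for all genome pairs, then runs the
#' alignment-based [align_ani()] only on pairs whose sketch ANI estimate is
#' within a slack margin of the species threshold
#' (`ani_estimate >= cfg$ani_species - slack`). This mirrors the two-stage
#' strategy of sketch prefilter plus alignment ANI.
#'
#' @param genomes named list of genomes (each a character vector of contigs
#'   or a `DNAStringSet`).
#' @param cfg a [mag_thresholds()] configuration (supplies the species ANI
#'   threshold, sketch parameters and slack).
#' @param anchor_k,max_gap passed to [align_ani()].
#' @param slack prefilter margin subtracted from the species ANI threshold
#'   (default `cfg$mash_slack`); 0 keeps only pairs estimated at or above
#'   the threshold.
#' @return data frame of [align_ani()] rows for pairs passing the
#'   prefilter; the full sketch-stage table is attached as attribute
#'   `"mash"`.
#' @export
pairwise_ani_graph <- function(genomes, cfg = mag_thresholds(),
                               anchor_k = cfg$sketch_k, max_gap = 1000,
                               slack = cfg$mash_slack) {
  if (length(genomes) < 2) stop("need at least 2 genomes")
  ids <- names(genomes)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    stop("genomes must be uniquely named")
  sketches <- lapply(ids, function(g)
    sketch(genomes[[g]], k = cfg$sketch_k, s = cfg$sketch_size,
           seed = cfg$hash_seed, genome_id = g))
  names(sketches) <- ids

  pairs <- utils::combn(ids, 2)
  mash <- data.frame(query_id = pairs[1, ], target_id = pairs[2, ],
                     jaccard = NA_real_, mash_distance = NA_real_,
                     ani_estimate = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    md <- mash_distance(sketches[[pairs[1, i]]], sketches[[pairs[2, i]]])
    mash$jaccard[i] <- md$jaccard
    mash$mash_distance[i] <- md$distance
    mash$ani_estimate[i] <- md$ani_estimate
  }

  keep <- mash$ani_estimate >= cfg$ani_species - slack
  edges <- lapply(which(keep), function(i) {
    align_ani(genomes[[mash$query_id[i]]], genomes[[mash$target_id[i]]],
              anchor_k = anchor_k, max_gap = max_gap,
              query_id = mash$query_id[i], target_id = mash$target_id[i])
  })
  out <- if (length(edges)) do.call(rbind, edges) else
    data.frame(query_id = character(), target_id = character(),
               ani = numeric(), af_query = numeric(), af_target = numeric(),
               aligned_bp = numeric(), stringsAsFactors = FALSE)
  attr(out, "mash") <- mash
  out
}
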