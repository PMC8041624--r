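#' MinHash sketch of a genome
#'
#' Builds a bottom-s MinHash sketch over canonical k-mers (the
#' lexicographically smaller of each k-mer and its reverse complement).
#' K-mers containing non-ACGT characters are skipped. The hash family is a
#' fixed 64-bit mixer seeded for reproducibility, so identical genomes (or a
#' genome and its reverse complement) always yield identical sketches.
#'
#' @param genome character vector of contig sequences, a single string, or a
#'   `Biostrings::DNAStringSet`.
#' @param k k-mer size (default 21).
#' @param s sketch size: the number of smallest hash values retained
#'   (default 10000).
#' @param seed hash seed (default 42); not a source of randomness, only a
#'   parameter of the fixed hash family.
#' @param genome_id optional identifier stored in the sketch.
#' @return an object of class `mag_sketch` with fields `genome_id`, `k`,
#'   `s` and `hashes` (sorted, strictly increasing).
#' @examples
#' sk <- sketch(gen_genome(1000, seed = 1), k = 15, s = 100)
#' length(sk$hashes)
#' @export
sketch <- function(genome, k = 21, s = 10000, seed = 42, genome_id = NULL) {
  genome <- as_contigs(genome)
  if (sum(nchar(genome)) < k)
    stop("empty sketch: total sequence length shorter than k")
  hashes <- sketch_hashes_cpp(genome, as.integer(k), as.integer(s),
                              as.numeric(seed))
  if (length(hashes) == 0)
    stop("empty sketch: no valid k-mers (non-ACGT content?)")
  structure(list(genome_id = genome_id, k = as.integer(k), s = as.integer(s),
                 hashes = hashes),
            class = "mag_sketch")
}

#' Mash distance between two sketches
#'
#' Estimates the Jaccard index from the merged bottom-s sketch (the s
#' smallest hashes of the union, counting how many are shared) and converts
#' it to a Mash distance `d = -ln(2j / (1 + j)) / k` and an ANI estimate
#' `max(0, 1 - d)`. Disjoint sketches give `j = 0` and an infinite distance.
#'
#' @param a,b `mag_sketch` objects built with the same `k`.
#' @return list with `jaccard`, `distance` and `ani_estimate`.
#' @export
mash_distance <- function(a, b) {
  stopifnot(inherits(a, "mag_sketch"), inherits(b, "mag_sketch"))
  if (a$k != b$k) stop("sketches built with different k: ", a$k, " vs ", b$k)
  s <- min(a$s, b$s)
  merged <- sort(unique(c(a$hashes, b$hashes)))
  merged <- merged[seq_len(min(s, length(merged)))]
  shared <- sum(merged %in% a$hashes & merged %in% b$hashes)
  j <- shared / length(merged)
  if (j <= 0) {
    return(list(jaccard = 0, distance = Inf, ani_estimate = 0))
  }
  d <- max(0, -log(2 * j / (1 + j)) / a$k)
  list(jaccard = j, distance = d, ani_estimate = max(0, 1 - d))
}

#' @export
print.mag_sketch <- function(x, ...) {
  cat(sprintf("<mag_sketch> %s k=%d s=%d |hashes|=%d\n",
              if (is.null(x$genome_id)) "?" else x$genome_id,
              x$k, x$s, length(x$hashes)))
  invisible(x)
}

# coerce genome input (character / DNAStringSet) to character contig vector
as_contigs <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  if (!is.character(genome) || length(genome) == 0)
    stop("genome must be a non-empty character vector or DNAStringSet")
  unname(genome)
}
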