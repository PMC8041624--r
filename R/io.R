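#' Read genomes from a directory of FASTA files
#'
#' Each `.fa`/`.fna`/`.fasta` file becomes one genome (a character vector
#' of contigs) named by its file stem.
#'
#' @param dir directory containing FASTA files.
#' @return named list of genomes.
#' @export
read_genome_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|fna|fasta)$", full.names = TRUE)
  if (!length(files)) stop("no FASTA files in ", dir)
  genomes <- lapply(files, function(f) {
    ss <- Biostrings::readDNAStringSet(f)
    stats::setNames(as.character(ss), names(ss))
  })
  names(genomes) <- sub("\\.(fa|fna|fasta)$", "", basename(files))
  genomes
}

#' Write a genome to FASTA
#'
#' @param genome character vector of contig sequences (named or not).
#' @param path output file path.
#' @export
write_genome_fasta <- function(genome, path) {
  ids <- names(genome)
  genome <- as_contigs(genome)
  if (is.null(ids)) ids <- sprintf("contig_%03d", seq_along(genome))
  ss <- Biostrings::DNAStringSet(genome)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a table as TSV
#'
#' Plain tab-separated output with header, no quoting, no row names —
#' the dialect every pipeline table in this package uses.
#'
#' @param x data frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract one rank from GTDB-style taxonomy strings
#'
#' Parses strings like `d__Bacteria;p__...;c__...;o__...;f__...;g__...;s__...`
#' and returns the label at the requested rank, named by genome id.
#' Missing or empty rank fields yield `NA`.
#'
#' @param taxonomy data frame with columns `genome_id` and `taxonomy`.
#' @param rank one of `domain`, `phylum`, `class`, `order`, `family`,
#'   `genus`, `species`.
#' @return named character vector (NA entries removed).
#' @export
extract_rank <- function(taxonomy,
                         rank = c("domain", "phylum", "class", "order",
                                  "family", "genus", "species")) {
  rank <- match.arg(rank)
  prefix <- c(domain = "d__", phylum = "p__", class = "c__", order = "o__",
              family = "f__", genus = "g__", species = "s__")[rank]
  labs <- vapply(strsplit(taxonomy$taxonomy, ";"), function(parts) {
    parts <- trimws(parts)
    hit <- parts[startsWith(parts, prefix)]
    if (length(hit) && nchar(hit[1]) > 3) hit[1] else NA_character_
  }, character(1))
  out <- stats::setNames(labs, taxonomy$genome_id)
  out[!is.na(out)]
}
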