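#' Generate a random genome sequence
#'
#' I.i.d. bases at a target GC content; deterministic for a given seed.
#'
#' @param length genome length in bp (>= 1).
#' @param gc target GC fraction (default 0.5).
#' @param seed RNG seed.
#' @return a single-element character vector (one contig).
#' @export
gen_genome <- function(length, gc = 0.5, seed = 1) {
  if (length < 1) stop("length must be >= 1")
  withr_seed(seed, {
    bases <- sample(c("A", "T", "G", "C"), length, replace = TRUE,
                    prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
    paste(bases, collapse = "")
  })
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG;
# seed is forced first so a seed drawn lazily from the caller's RNG is
# consumed before the state snapshot
withr_seed <- function(seed, expr) {
  force(seed)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Mutate a genome by per-site substitution
#'
#' Each site is substituted with probability `sub_rate` to a uniformly
#' chosen different base, and the site-level truth is returned so that the
#' Hamming identity of the (position-preserving) alignment is the true
#' ANI. Substitution-only: no indels, so the truth alignment length equals
#' the genome length.
#'
#' @param genome single sequence string (or character vector of length 1).
#' @param sub_rate per-site substitution probability in \[0, 0.5).
#' @param seed RNG seed.
#' @return list with `seq` (mutated copy), `positions` (mutated sites),
#'   `n_sub` and `true_identity`.
#' @export
mutate_genome <- function(genome, sub_rate, seed = 1) {
  if (sub_rate < 0 || sub_rate >= 0.5) stop("sub_rate must be in [0, 0.5)")
  genome <- paste(as_contigs(genome), collapse = "")
  L <- nchar(genome)
  withr_seed(seed, {
    hit <- which(runif(L) < sub_rate)
    chars <- strsplit(genome, "")[[1]]
    if (length(hit)) {
      alt <- vapply(chars[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      chars[hit] <- alt
    }
    list(seq = paste(chars, collapse = ""), positions = hit,
         n_sub = length(hit), true_identity = 1 - length(hit) / L)
  })
}

#' Fragment a genome into contigs with dropout and contamination
#'
#' Emulates binning artifacts: the genome is cut at random breakpoints
#' into `n_contigs` pieces, contigs are optionally dropped until about
#' `dropout` of the length is removed (the completeness truth), and
#' contaminant contigs cut from a foreign genome are appended so they make
#' up roughly `fraction` of the retained host length. Per-contig truth
#' labels are returned.
#'
#' @param genome host genome (single string or character vector).
#' @param n_contigs number of host contigs to cut (each >= 1 bp;
#'   `n_contigs` must not exceed length/1000).
#' @param contaminant foreign genome sequence, or `NULL` for none.
#' @param fraction contaminant fraction of retained host length in
#'   \[0, 1).
#' @param dropout fraction of host length to drop in \[0, 1).
#' @param seed RNG seed.
#' @return list with `contigs` (named character vector), `truth` (data
#'   frame: contig, source, length), `completeness_truth`,
#'   `contamination_truth`.
#' @export
fragment_and_contaminate <- function(genome, n_contigs, contaminant = NULL,
                                     fraction = 0, dropout = 0, seed = 1) {
  if (fraction >= 1) stop("contaminant fraction must be < 1")
  genome <- paste(as_contigs(genome), collapse = "")
  L <- nchar(genome)
  if (n_contigs > L / 1000) stop("too many contigs for genome length")
  withr_seed(seed, {
    cuts <- if (n_contigs > 1) sort(sample(L - 1, n_contigs - 1)) else integer(0)
    starts <- c(1, cuts + 1)
    ends <- c(cuts, L)
    contigs <- substring(genome, starts, ends)
    names(contigs) <- sprintf("host_%03d", seq_along(contigs))

    kept <- rep(TRUE, length(contigs))
    if (dropout > 0) {
      ord <- sample(length(contigs))
      dropped <- 0
      for (i in ord) {
        if (dropped / L >= dropout) break
        if (sum(kept) == 1) break
        kept[i] <- FALSE
        dropped <- dropped + nchar(contigs[i])
      }
    }
    contigs <- contigs[kept]
    host_len <- sum(nchar(contigs))

    contam <- character(0)
    if (!is.null(contaminant) && fraction > 0) {
      cseq <- paste(as_contigs(contaminant), collapse = "")
      want <- round(fraction * host_len)
      want <- min(want, nchar(cseq))
      if (want >= 1) {
        st <- sample(nchar(cseq) - want + 1, 1)
        piece <- substr(cseq, st, st + want - 1)
        # split the contaminant piece into a couple of contigs
        n_c <- max(1, min(3, want %/% 1000))
        cc <- if (n_c > 1) sort(sample(want - 1, n_c - 1)) else integer(0)
        contam <- substring(piece, c(1, cc + 1), c(cc, want))
        names(contam) <- sprintf("contam_%03d", seq_along(contam))
      }
    }
    all_contigs <- c(contigs, contam)
    truth <- data.frame(contig = names(all_contigs),
                        source = rep(c("host", "contaminant"),
                                     c(length(contigs), length(contam))),
                        length = nchar(all_contigs),
                        stringsAsFactors = FALSE)
    list(contigs = all_contigs, truth = truth,
         completeness_truth = host_len / L,
         contamination_truth = if (host_len > 0)
           sum(nchar(contam)) / host_len else 0)
  })
}

#' Plant CRISPR arrays and prophages into a host genome
#'
#' Inserts repeat-spacer arrays whose spacers are substrings of viruses
#' from the pool (with a configured number of planted mismatches), and
#' optionally inserts prophage copies of pool viruses, returning complete
#' truth tables for downstream recovery tests.
#'
#' @param host host genome (single string or character vector; the array
#'   and prophages are inserted into the first contig).
#' @param virus_pool named character vector of viral genome sequences.
#' @param crispr list with `n_spacers` (default 4), `repeat_length`
#'   (default 30), `spacer_length` (default 32), `planted_mismatches`
#'   (default 0).
#' @param prophage optional list with `n` (number of prophages, default 0)
#'   and `sub_rate` (per-site divergence of the inserted copy, default 0).
#' @param seed RNG seed.
#' @return list with `contigs`, `arrays` (long-format table for
#'   [filter_crispr_arrays()]), `spacer_truth` (spacer_id, virus_id,
#'   virus_pos, mismatches) and `prophage_truth` (virus_id, contig,
#'   insert_pos, length).
#' @export
plant_crispr_and_prophage <- function(host, virus_pool,
                                      crispr = list(), prophage = list(),
                                      seed = 1) {
  if (!length(virus_pool)) stop("virus pool must be non-empty")
  if (is.null(names(virus_pool))) stop("virus pool must be named")
  cfg <- modifyList(list(n_spacers = 4, repeat_length = 30,
                         spacer_length = 32, planted_mismatches = 0), crispr)
  pcfg <- modifyList(list(n = 0, sub_rate = 0), prophage)
  host <- as_contigs(host)
  if (any(nchar(virus_pool) < cfg$spacer_length))
    stop("spacer longer than a virus in the pool")

  withr_seed(seed, {
    rep_seq <- paste(sample(c("A", "C", "G", "T"), cfg$repeat_length,
                            replace = TRUE), collapse = "")
    spacer_truth <- list()
    spacers <- character(cfg$n_spacers)
    for (i in seq_len(cfg$n_spacers)) {
      vid <- sample(names(virus_pool), 1)
      vseq <- virus_pool[[vid]]
      pos <- sample(nchar(vseq) - cfg$spacer_length + 1, 1)
      sp <- substr(vseq, pos, pos + cfg$spacer_length - 1)
      mm <- 0
      if (cfg$planted_mismatches > 0) {
        ch <- strsplit(sp, "")[[1]]
        sites <- sample(length(ch), cfg$planted_mismatches)
        for (s in sites)
          ch[s] <- sample(setdiff(c("A", "C", "G", "T"), ch[s]), 1)
        sp <- paste(ch, collapse = "")
        mm <- cfg$planted_mismatches
      }
      spacers[i] <- sp
      spacer_truth[[i]] <- data.frame(
        spacer_id = sprintf("sp%03d", i), virus_id = vid, virus_pos = pos,
        mismatches = mm, stringsAsFactors = FALSE)
    }
    array_seq <- paste0(rep_seq,
                        paste(vapply(spacers, function(s)
                          paste0(s, rep_seq), character(1)), collapse = ""))
    ins <- sample(nchar(host[1]), 1)
    host[1] <- paste0(substr(host[1], 1, ins), array_seq,
                      substring(host[1], ins + 1))

    arrays <- rbind(
      data.frame(array_id = "arr001", mag_id = "mag001",
                 contig_id = names(host)[1] %||% "contig_1",
                 type = "repeat", seq = rep(rep_seq, cfg$n_spacers + 1),
                 stringsAsFactors = FALSE),
      data.frame(array_id = "arr001", mag_id = "mag001",
                 contig_id = names(host)[1] %||% "contig_1",
                 type = "spacer", seq = spacers, stringsAsFactors = FALSE))

    prophage_truth <- NULL
    if (pcfg$n > 0) {
      picks <- sample(names(virus_pool), pcfg$n, replace = TRUE)
      rows <- list()
      for (j in seq_along(picks)) {
        vseq <- virus_pool[[picks[j]]]
        if (pcfg$sub_rate > 0)
          vseq <- mutate_genome(vseq, pcfg$sub_rate,
                                seed = sample.int(2^30, 1))$seq
        at <- sample(nchar(host[1]), 1)
        host[1] <- paste0(substr(host[1], 1, at), vseq,
                          substring(host[1], at + 1))
        rows[[j]] <- data.frame(virus_id = picks[j],
                                contig = names(host)[1] %||% "contig_1",
                                insert_pos = at, length = nchar(vseq),
                                stringsAsFactors = FALSE)
      }
      prophage_truth <- do.call(rbind, rows)
    }
    list(contigs = host, arrays = arrays,
         spacer_truth = do.call(rbind, spacer_truth),
         prophage_truth = prophage_truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a labelled tree with planted RED rank cutoffs
#'
#' Draws a random bifurcating tree with exponential branch lengths and
#' derives taxonomy labels per rank by running [cluster_by_red()] at the
#' planted cutoffs (all supports 1), so that RED-cutoff calibration has an
#' exact optimum at the planted values.
#'
#' @param n_leaves number of leaves (>= 4).
#' @param rank_cutoffs named numeric vector of strictly increasing planted
#'   cutoffs in (0, 1), e.g. `c(order = 0.5, genus = 0.8)`.
#' @param seed RNG seed.
#' @param br_rate rate of the exponential branch-length distribution
#'   (default 10).
#' @return list with `tree` (rooted `phylo`), `red`, `taxonomy` (data
#'   frame: leaf plus one column per rank).
#' @export
gen_labelled_tree <- function(n_leaves, rank_cutoffs, seed = 1,
                              br_rate = 10) {
  if (n_leaves < 4) stop("need at least 4 leaves")
  if (is.null(names(rank_cutoffs)) || any(diff(rank_cutoffs) <= 0) ||
      any(rank_cutoffs <= 0 | rank_cutoffs >= 1))
    stop("rank_cutoffs must be named, strictly increasing, in (0, 1)")
  withr_seed(seed, {
    tree <- ape::rtree(n_leaves, br = function(n) rexp(n, rate = br_rate))
    red <- compute_red(tree)
    tax <- data.frame(leaf = tree$tip.label, stringsAsFactors = FALSE)
    for (rk in names(rank_cutoffs)) {
      cl <- cluster_by_red(tree, red, rank_cutoffs[[rk]], support_min = 0,
                           default_support = 1)
      tax[[rk]] <- paste0(substr(rk, 1, 1), "__",
                          cl$group[match(tax$leaf, cl$leaf)])
    }
    list(tree = tree, red = red, taxonomy = tax)
  })
}

#' Generate a planted multi-species MAG cohort
#'
#' Builds `n_species` ancestor genomes and, for each, `genomes_per_species`
#' mutated copies at `intra_divergence`, giving a cohort with known
#' species structure (intra-species ANI about `1 - intra_divergence`,
#' inter-species ANI governed by independent random ancestors). Quality
#' scores are drawn uniformly so that centroid choice is exercised.
#'
#' @param n_species number of planted species.
#' @param genomes_per_species genomes per species.
#' @param genome_length ancestor genome length (bp).
#' @param intra_divergence per-site divergence within a species
#'   (default 0.02).
#' @param seed RNG seed.
#' @return list with `genomes` (named list of sequences), `truth` (data
#'   frame: genome_id, species), `qualities` (named numeric).
#' @export
gen_species_cohort <- function(n_species, genomes_per_species,
                               genome_length = 50000,
                               intra_divergence = 0.02, seed = 1) {
  withr_seed(seed, {
    genomes <- list()
    truth <- list()
    for (s in seq_len(n_species)) {
      anc <- gen_genome(genome_length, seed = sample.int(2^30, 1))
      for (g in seq_len(genomes_per_species)) {
        id <- sprintf("sp%02d_g%02d", s, g)
        genomes[[id]] <- if (g == 1) anc else
          mutate_genome(anc, intra_divergence,
                        seed = sample.int(2^30, 1))$seq
        truth[[id]] <- data.frame(genome_id = id,
                                  species = sprintf("species_%02d", s),
                                  stringsAsFactors = FALSE)
      }
    }
    qualities <- setNames(runif(length(genomes), 50, 100), names(genomes))
    list(genomes = genomes, truth = do.call(rbind, truth),
         qualities = qualities)
  })
}

#' Write a full synthetic analysis cohort to disk
#'
#' Generates every input the command-line pipeline consumes — MAG FASTA
#' files with metadata, a virus pool, a labelled tree, CRISPR arrays and
#' Cas counts, virus alignment hits, BGC regions and read records — all
#' deterministic for a given seed, and writes them under `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed controlling the whole cohort.
#' @param n_species,genomes_per_species planted species structure
#'   (defaults 5 x 4 = 20 MAGs).
#' @param genome_length ancestor genome length (default 30000 bp).
#' @param n_viruses size of the virus pool (default 5).
#' @param n_tree_leaves leaves in the labelled tree (default 40).
#' @return invisibly, a named list of the paths written.
#' @export
synth_cohort <- function(out_dir, seed = 1, n_species = 5,
                         genomes_per_species = 4, genome_length = 30000,
                         n_viruses = 5, n_tree_leaves = 40) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mag_dir <- file.path(out_dir, "mags")
  dir.create(mag_dir, showWarnings = FALSE)

  cohort <- gen_species_cohort(n_species, genomes_per_species,
                               genome_length, seed = seed)
  for (id in names(cohort$genomes))
    write_genome_fasta(stats::setNames(cohort$genomes[[id]],
                                       paste0(id, "_c1")),
                       file.path(mag_dir, paste0(id, ".fna")))

  ids <- names(cohort$genomes)
  n <- length(ids)
  meta <- withr_seed(seed + 1, data.frame(
    genome_id = ids,
    completeness = round(runif(n, 55, 100), 1),
    contamination = round(runif(n, 0, 4), 2),
    trna_distinct = sample(10:20, n, replace = TRUE),
    rrna_5s = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.7, 0.3)),
    rrna_16s = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.7, 0.3)),
    rrna_23s = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.7, 0.3)),
    biome = sample(c("Aquatic", "Terrestrial", "Host-associated"), n,
                   replace = TRUE),
    sub_biome = sample(c("Marine", "Soil", "Gut", "Freshwater"), n,
                       replace = TRUE),
    latitude = round(runif(n, -60, 60), 3),
    longitude = round(runif(n, -180, 180), 3),
    sample_id = sprintf("S%03d", sample(1:8, n, replace = TRUE)),
    stringsAsFactors = FALSE))
  write_tsv(meta, file.path(out_dir, "meta.tsv"))

  viruses <- withr_seed(seed + 2, {
    v <- vapply(seq_len(n_viruses), function(i)
      gen_genome(sample(3000:8000, 1), seed = sample.int(2^30, 1)),
      character(1))
    stats::setNames(v, sprintf("virus_%02d", seq_len(n_viruses)))
  })
  write_genome_fasta(viruses, file.path(out_dir, "viruses.fna"))

  planted <- plant_crispr_and_prophage(
    stats::setNames(cohort$genomes[[1]], "host_c1"), viruses,
    crispr = list(n_spacers = 4), seed = seed + 3)
  arrays <- planted$arrays
  arrays$mag_id <- ids[1]
  write_tsv(arrays, file.path(out_dir, "arrays.tsv"))
  write_tsv(data.frame(mag_id = ids,
                       cas_count = c(6, rep(4, n - 1))),
            file.path(out_dir, "cas.tsv"))

  contigs <- data.frame(contig_id = paste0(ids, "_c1"), mag_id = ids,
                        length = vapply(cohort$genomes, function(g)
                          sum(nchar(g)), numeric(1)),
                        stringsAsFactors = FALSE)
  write_tsv(contigs, file.path(out_dir, "contigs.tsv"))
  hits <- withr_seed(seed + 4, data.frame(
    contig_id = sample(contigs$contig_id, 6, replace = TRUE),
    virus_id = sample(names(viruses), 6, replace = TRUE),
    identity = round(runif(6, 0.85, 1), 3),
    length = sample(c(300, 600, 1200, 4000), 6, replace = TRUE),
    stringsAsFactors = FALSE))
  write_tsv(hits, file.path(out_dir, "virus_hits.tsv"))

  tt <- gen_labelled_tree(n_tree_leaves,
                          c(order = 0.4, genus = 0.7), seed = seed + 5)
  ape::write.tree(tt$tree, file.path(out_dir, "tree.nwk"))
  write_tsv(data.frame(
    genome_id = tt$taxonomy$leaf,
    taxonomy = sprintf("d__Bacteria;p__P1;c__C1;%s;f__F1;%s;s__",
                       tt$taxonomy$order, tt$taxonomy$genus),
    stringsAsFactors = FALSE), file.path(out_dir, "taxonomy.tsv"))

  regions <- withr_seed(seed + 6, {
    k <- 8
    clens <- sample(contigs$length, k, replace = TRUE)
    st <- ifelse(runif(k) < 0.4, 0, pmax(0, round(clens * runif(k, 0.1, 0.4))))
    en <- pmin(clens, st + sample(5000:20000, k, replace = TRUE))
    data.frame(region_id = sprintf("R%03d", 1:k),
               contig_id = sample(contigs$contig_id, k, replace = TRUE),
               start = st, end = en, contig_length = clens,
               family = sample(c("T1PKS", "NRPS", "terpene", "lanthipeptide",
                                 "ectoine", "weirdfam"), k, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  regions <- regions[regions$end > regions$start, ]
  write_tsv(regions, file.path(out_dir, "bgc_regions.tsv"))
  bgc_hits <- withr_seed(seed + 7, data.frame(
    region_id = sample(regions$region_id, 5, replace = TRUE),
    coverage = round(runif(5, 0.5, 1), 2),
    identity = round(runif(5, 0.6, 1), 2),
    stringsAsFactors = FALSE))
  write_tsv(bgc_hits, file.path(out_dir, "bgc_hits.tsv"))

  reads <- withr_seed(seed + 8, {
    m <- 400
    data.frame(sample_id = sprintf("S%02d", sample(1:4, m, replace = TRUE)),
               read_id = sprintf("r%05d", seq_len(m)),
               read_length = sample(c(60, 100, 150), m, replace = TRUE,
                                    prob = c(0.1, 0.6, 0.3)),
               mean_base_quality = round(runif(m, 20, 40), 1),
               ambiguous_bases = sample(c(0, 0, 0, 1), m, replace = TRUE),
               edit_distance = sample(0:8, m, replace = TRUE),
               mapped_to = sample(c("catalog", "isolates", NA), m,
                                  replace = TRUE, prob = c(0.4, 0.2, 0.4)),
               stringsAsFactors = FALSE)
  })
  write_tsv(reads, file.path(out_dir, "reads.tsv"))

  invisible(list(mag_dir = mag_dir,
                 meta = file.path(out_dir, "meta.tsv"),
                 viruses = file.path(out_dir, "viruses.fna"),
                 arrays = file.path(out_dir, "arrays.tsv"),
                 cas = file.path(out_dir, "cas.tsv"),
                 contigs = file.path(out_dir, "contigs.tsv"),
                 virus_hits = file.path(out_dir, "virus_hits.tsv"),
                 tree = file.path(out_dir, "tree.nwk"),
                 taxonomy = file.path(out_dir, "taxonomy.tsv"),
                 bgc_regions = file.path(out_dir, "bgc_regions.tsv"),
                 bgc_hits = file.path(out_dir, "bgc_hits.tsv"),
                 reads = file.path(out_dir, "reads.tsv")))
}
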