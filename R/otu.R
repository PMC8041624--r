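#' Greedy centroid clustering into species-level OTUs
#'
#' Genomes are visited in order of decreasing quality score (ties broken by
#' ascending genome id). Each unassigned genome becomes the centroid of a
#' new OTU and recruits every still-unassigned genome connected to it by an
#' edge at or above the species ANI threshold whose aligned fractions pass
#' (by default both genomes must have AF >= 0.30). Singleton OTUs are
#' allowed; the member sets partition the input.
#'
#' @param edges data frame of pairwise comparisons with columns `query_id`,
#'   `target_id`, `ani`, `af_query`, `af_target` (as produced by
#'   [pairwise_ani_graph()]). Edges are treated as symmetric.
#' @param qualities named numeric vector of quality scores covering every
#'   genome to be clustered (singletons included); an edge genome missing
#'   from `qualities` is an error naming the genome.
#' @param cfg a [mag_thresholds()] configuration.
#' @param source provenance label stored on each cluster: `"gem"`,
#'   `"reference"` or `"mixed"`.
#' @return data frame with columns `otu_id`, `centroid_id`, `member_id`,
#'   `source` (one row per member).
#' @export
greedy_cluster <- function(edges, qualities, cfg = mag_thresholds(),
                           source = "gem") {
  genomes <- names(qualities)
  if (is.null(genomes) || anyDuplicated(genomes))
    stop("qualities must be a uniquely named numeric vector")
  edge_ids <- unique(c(edges$query_id, edges$target_id))
  missing <- setdiff(edge_ids, genomes)
  if (length(missing))
    stop("missing quality score for genome(s): ",
         paste(missing, collapse = ", "))

  ok <- edge_passes(edges, cfg)
  adj <- split(c(edges$target_id[ok], edges$query_id[ok]),
               c(edges$query_id[ok], edges$target_id[ok]))

  ord <- genomes[order(-qualities, genomes)]
  assigned <- setNames(rep(FALSE, length(genomes)), genomes)
  rows <- vector("list", length(genomes))
  n_otu <- 0L
  for (g in ord) {
    if (assigned[[g]]) next
    n_otu <- n_otu + 1L
    members <- g
    nb <- adj[[g]]
    if (!is.null(nb)) members <- c(g, unique(nb[!assigned[nb]]))
    assigned[members] <- TRUE
    rows[[n_otu]] <- data.frame(
      otu_id = sprintf("OTU%05d", n_otu), centroid_id = g,
      member_id = members, source = source, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows[seq_len(n_otu)])
}

# species-level edge acceptance: ANI bound (catalog operator) + AF condition
edge_passes <- function(edges, cfg) {
  cmp_op(edges$ani, cfg$ani_op_catalog, cfg$ani_species) &
    af_passes(edges$af_query, edges$af_target, cfg)
}

af_passes <- function(af_query, af_target, cfg) {
  m <- cfg$af_min
  switch(cfg$af_mode,
    both   = af_query >= m & af_target >= m,
    either = af_query >= m | af_target >= m,
    query  = af_query >= m,
    target = af_target >= m)
}

#' Novelty calling of OTU centroids against reference genomes
#'
#' For each centroid, the sketch prefilter ranks the references and the best
#' candidates are aligned with [align_ani()]. A centroid is `known` when
#' its best reference alignment exceeds the species ANI threshold (strict
#' `>` by default, per `cfg$ani_op_reference`) with passing aligned
#' fractions; otherwise it is `novel`. With an empty reference set every
#' centroid is novel.
#'
#' @param centroids named list of centroid genomes.
#' @param references named list of reference genomes (may be empty).
#' @param cfg a [mag_thresholds()] configuration.
#' @param top_n number of sketch-ranked references aligned per centroid
#'   (default 1: the single best prefilter hit).
#' @return data frame with columns `otu_id`, `status`, `best_ref_id`,
#'   `best_ani`, `best_af_query`, `best_af_target`.
#' @export
recruit_to_references <- function(centroids, references,
                                  cfg = mag_thresholds(), top_n = 1) {
  ids <- names(centroids)
  if (is.null(ids)) stop("centroids must be named")
  empty_call <- function(id) data.frame(
    otu_id = id, status = "novel", best_ref_id = NA_character_,
    best_ani = 0, best_af_query = 0, best_af_target = 0,
    stringsAsFactors = FALSE)
  if (length(references) == 0)
    return(do.call(rbind, lapply(ids, empty_call)))

  ref_ids <- names(references)
  ref_sk <- lapply(ref_ids, function(r)
    sketch(references[[r]], k = cfg$sketch_k, s = cfg$sketch_size,
           seed = cfg$hash_seed, genome_id = r))
  names(ref_sk) <- ref_ids

  calls <- lapply(ids, function(cid) {
    csk <- sketch(centroids[[cid]], k = cfg$sketch_k, s = cfg$sketch_size,
                  seed = cfg$hash_seed, genome_id = cid)
    est <- vapply(ref_sk, function(rs) mash_distance(csk, rs)$ani_estimate,
                  numeric(1))
    cand <- ref_ids[order(-est)][seq_len(min(top_n, length(ref_ids)))]
    best <- NULL
    for (r in cand) {
      res <- align_ani(centroids[[cid]], references[[r]],
                       anchor_k = cfg$sketch_k,
                       query_id = cid, target_id = r)
      if (is.null(best) || res$ani > best$ani) best <- res
    }
    known <- cmp_op(best$ani, cfg$ani_op_reference, cfg$ani_species) &&
      af_passes(best$af_query, best$af_target, cfg)
    data.frame(otu_id = cid, status = if (known) "known" else "novel",
               best_ref_id = best$target_id, best_ani = best$ani,
               best_af_query = best$af_query, best_af_target = best$af_target,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, calls)
}

#' Cluster unrecruited reference genomes into additional OTUs
#'
#' Same greedy contract as [greedy_cluster()], applied to the reference
#' genomes not recruited to any catalog OTU. Pairwise edges are computed
#' with [pairwise_ani_graph()] and clusters carry `source = "reference"`.
#'
#' @param references named list of reference genomes; an empty list yields
#'   an empty cluster table.
#' @param qualities optional named quality scores; when `NULL` all
#'   references score 0 and ties resolve by ascending id.
#' @param cfg a [mag_thresholds()] configuration.
#' @return data frame as in [greedy_cluster()].
#' @export
cluster_references <- function(references, qualities = NULL,
                               cfg = mag_thresholds()) {
  empty <- data.frame(otu_id = character(), centroid_id = character(),
                      member_id = character(), source = character(),
                      stringsAsFactors = FALSE)
  if (length(references) == 0) return(empty)
  ids <- names(references)
  if (is.null(qualities)) qualities <- setNames(rep(0, length(ids)), ids)
  if (length(references) == 1) {
    return(data.frame(otu_id = "OTU00001", centroid_id = ids,
                      member_id = ids, source = "reference",
                      stringsAsFactors = FALSE))
  }
  edges <- pairwise_ani_graph(references, cfg)
  greedy_cluster(edges, qualities, cfg, source = "reference")
}

#' Habitat and geography summary of OTUs
#'
#' For every multi-genome OTU, reports whether all members share a single
#' biome and a single sub-biome, and whether they span more than one
#' distinct sampling location (latitude/longitude pair). Also returns the
#' global fractions over multi-genome OTUs and the fraction of OTUs that
#' are singletons (singletons are excluded from the biome-range fractions).
#'
#' @param clusters cluster table from [greedy_cluster()].
#' @param metadata data frame keyed by `genome_id` with columns `biome`,
#'   `sub_biome`, `latitude`, `longitude`; must cover every member.
#' @return list with `per_otu` (one row per multi-genome OTU) and
#'   `summary` (named numeric vector of fractions and counts).
#' @export
summarize_distribution <- function(clusters, metadata) {
  miss <- setdiff(clusters$member_id, metadata$genome_id)
  if (length(miss))
    stop("metadata missing for genome(s): ", paste(miss, collapse = ", "))
  md <- metadata[match(clusters$member_id, metadata$genome_id), ]
  md$otu_id <- clusters$otu_id
  sizes <- table(md$otu_id)
  multi <- names(sizes)[sizes > 1]

  per_otu <- do.call(rbind, lapply(multi, function(o) {
    rows <- md[md$otu_id == o, ]
    loc <- unique(paste(rows$latitude, rows$longitude))
    loc <- loc[!grepl("NA", loc, fixed = TRUE)]
    data.frame(otu_id = o, n_members = nrow(rows),
               single_biome = length(unique(rows$biome)) == 1,
               single_subbiome = length(unique(rows$sub_biome)) == 1,
               multi_location = length(loc) > 1,
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_otu))
    per_otu <- data.frame(otu_id = character(), n_members = integer(),
                          single_biome = logical(), single_subbiome = logical(),
                          multi_location = logical(), stringsAsFactors = FALSE)
  n_otu <- length(sizes)
  summary <- c(
    n_otus = n_otu,
    n_multi = nrow(per_otu),
    frac_single_biome = if (nrow(per_otu)) mean(per_otu$single_biome) else NA,
    frac_single_subbiome = if (nrow(per_otu)) mean(per_otu$single_subbiome) else NA,
    frac_multi_location = if (nrow(per_otu)) mean(per_otu$multi_location) else NA,
    singleton_fraction = sum(sizes == 1) / n_otu)
  list(per_otu = per_otu, summary = summary)
}
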