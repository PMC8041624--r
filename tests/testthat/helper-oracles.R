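# Independent naive re-implementations used as oracles. These deliberately
# share no code with the package internals they check.

# -- greedy clustering: literal while-loop trace of the centroid rule -------
naive_greedy_cluster <- function(edges, qualities, ani_min = 0.95,
                                 af_min = 0.30) {
  unassigned <- names(qualities)
  clusters <- list()
  while (length(unassigned)) {
    best <- unassigned[order(-qualities[unassigned], unassigned)][1]
    members <- best
    for (g in setdiff(unassigned, best)) {
      hit <- which((edges$query_id == best & edges$target_id == g) |
                   (edges$query_id == g & edges$target_id == best))
      if (length(hit)) {
        e <- edges[hit[1], ]
        if (e$ani >= ani_min && e$af_query >= af_min && e$af_target >= af_min)
          members <- c(members, g)
      }
    }
    clusters[[length(clusters) + 1]] <- list(centroid = best,
                                             members = sort(members))
    unassigned <- setdiff(unassigned, members)
  }
  clusters
}

# canonical form of a greedy_cluster() table for comparison with the oracle
cluster_table_to_list <- function(tab) {
  out <- lapply(split(tab, tab$otu_id), function(rows)
    list(centroid = rows$centroid_id[1], members = sort(rows$member_id)))
  unname(out[order(vapply(out, `[[`, character(1), "centroid"))])
}

# random clustering instance: n genomes, random symmetric edges
random_cluster_instance <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("g%02d", seq_len(n))
  qual <- setNames(round(runif(n, 0, 100), 3), ids)
  pairs <- t(combn(ids, 2))
  pick <- runif(nrow(pairs)) < 0.4
  if (!any(pick)) pick[1] <- TRUE
  edges <- data.frame(
    query_id = pairs[pick, 1], target_id = pairs[pick, 2],
    ani = round(runif(sum(pick), 0.90, 1.0), 4),
    af_query = round(runif(sum(pick), 0, 1), 3),
    af_target = round(runif(sum(pick), 0, 1), 3),
    aligned_bp = 1000, stringsAsFactors = FALSE)
  list(edges = edges, qualities = qual)
}

# -- spacer matching: brute-force all-substring scanner ---------------------
revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# mismatch count of `sub` against every window of `v` (integer-coded)
window_mismatches <- function(vint, subint) {
  nwin <- length(vint) - length(subint) + 1
  if (nwin < 1) return(integer(0))
  mm <- integer(nwin)
  for (off in seq_along(subint))
    mm <- mm + (vint[seq(off, off + nwin - 1)] != subint[off])
  mm
}

naive_spacer_scan <- function(sp, vseq, max_mm = 1, min_cov = 0.95) {
  L <- nchar(sp)
  minlen <- ceiling(min_cov * L)
  budget <- L - minlen
  vlen <- nchar(vseq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") vseq else revcomp_chr(vseq)
    vint <- utf8ToInt(s)
    spint <- utf8ToInt(sp)
    for (a in 0:budget) {
      for (b in 0:(budget - a)) {
        sub <- spint[seq(a + 1, L - b)]
        mm <- window_mismatches(vint, sub)
        for (st in which(mm <= max_mm)) {
          en <- st + length(sub) - 1
          rows[[length(rows) + 1]] <- data.frame(
            strand = strand,
            full_start = st - a,
            position = if (strand == "+") st else vlen - en + 1,
            mismatches = mm[st], coverage = length(sub) / L,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(strand = character(), position = integer(),
                      mismatches = integer(), coverage = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res <- res[order(-res$coverage, res$mismatches), ]
  res <- res[!duplicated(paste(res$strand, res$full_start)), ]
  res <- res[order(res$position, res$strand), c("strand", "position",
                                                "mismatches", "coverage")]
  rownames(res) <- NULL
  res
}

# -- misc -------------------------------------------------------------------
naive_medoid <- function(m) {
  n <- nrow(m)
  if (n == 1) return(1L)
  best <- 1L
  best_mean <- -Inf
  for (i in seq_len(n)) {
    mu <- mean(m[i, -i])
    if (mu > best_mean + 1e-15) {
      best <- i
      best_mean <- mu
    }
  }
  best
}

# random rooted tree with exponential branch lengths
random_tree <- function(n, seed) {
  set.seed(seed)
  ape::rtree(n, br = function(k) rexp(k, 10))
}

# two-domain tree: two rooted clades joined at an unrooted base
two_domain_tree <- function(n_each, seed) {
  set.seed(seed)
  t1 <- ape::rtree(n_each, tip.label = sprintf("A%02d", 1:n_each))
  t2 <- ape::rtree(n_each, tip.label = sprintf("B%02d", 1:n_each))
  nwk <- sprintf("(%s:0.4,%s:0.4);",
                 sub(";$", "", ape::write.tree(t1)),
                 sub(";$", "", ape::write.tree(t2)))
  ape::unroot(ape::read.tree(text = nwk))
}
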