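#' Filter CRISPR arrays for host-prediction use
#'
#' Applies the array-level filters: an array is kept when it has at least
#' `crispr_min_spacers` spacers (default 3), its repeats average at least
#' `crispr_repeat_ident` identity (default 97%) to the consensus repeat,
#' and its MAG carries at least `crispr_min_cas` CRISPR-associated proteins
#' (default 4). Spacers at or below 25 bp (`spacer_min_len - 1`) are then
#' removed from kept arrays. The filters are order-independent.
#'
#' The consensus repeat is the per-column majority base over repeats of the
#' modal length (ties resolved alphabetically); repeats of other lengths
#' are compared to the consensus after end-anchored trimming to the shorter
#' length.
#'
#' @param arrays long-format data frame with columns `array_id`, `mag_id`,
#'   `contig_id`, `type` (`"repeat"` or `"spacer"`), `seq` and optionally
#'   `start`, `end`.
#' @param cas_counts named integer vector: CRISPR-associated protein count
#'   per MAG; an array on a MAG absent from `cas_counts` is an error.
#' @param cfg a [mag_thresholds()] configuration.
#' @return list with `kept` (the filtered long-format table, short spacers
#'   removed) and `rejected` (data frame of `array_id`, `reason`).
#' @export
filter_crispr_arrays <- function(arrays, cas_counts, cfg = mag_thresholds()) {
  need <- c("array_id", "mag_id", "contig_id", "type", "seq")
  miss <- setdiff(need, names(arrays))
  if (length(miss)) stop("arrays missing column(s): ",
                         paste(miss, collapse = ", "))
  unknown <- setdiff(unique(arrays$mag_id), names(cas_counts))
  if (length(unknown))
    stop("array on MAG(s) with unknown cas count: ",
         paste(unknown, collapse = ", "))

  keep_rows <- rep(FALSE, nrow(arrays))
  rejected <- list()
  for (aid in unique(arrays$array_id)) {
    rows <- which(arrays$array_id == aid)
    sub <- arrays[rows, ]
    spacers <- sub$seq[sub$type == "spacer"]
    repeats <- sub$seq[sub$type == "repeat"]
    mag <- sub$mag_id[1]
    reasons <- character(0)
    if (length(spacers) < cfg$crispr_min_spacers)
      reasons <- c(reasons, "spacer count")
    if (length(repeats) &&
        mean_repeat_identity(repeats) < cfg$crispr_repeat_ident)
      reasons <- c(reasons, "nonconserved repeats")
    if (cas_counts[[mag]] < cfg$crispr_min_cas)
      reasons <- c(reasons, "cas count")
    if (length(reasons)) {
      rejected[[aid]] <- data.frame(array_id = aid,
                                    reason = paste(reasons, collapse = "; "),
                                    stringsAsFactors = FALSE)
    } else {
      short <- sub$type == "spacer" & nchar(sub$seq) < cfg$spacer_min_len
      keep_rows[rows[!short]] <- TRUE
    }
  }
  list(kept = arrays[keep_rows, , drop = FALSE],
       rejected = if (length(rejected)) do.call(rbind, rejected) else
         data.frame(array_id = character(), reason = character(),
                    stringsAsFactors = FALSE))
}

#' Consensus repeat of a CRISPR array
#'
#' Majority base per column over repeats of the modal length (base ties
#' resolved alphabetically).
#'
#' @param repeats character vector of repeat sequences.
#' @return consensus sequence (single string).
#' @export
consensus_repeat <- function(repeats) {
  if (!length(repeats)) stop("no repeats supplied")
  lens <- nchar(repeats)
  modal <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
  grp <- repeats[lens == modal]
  mat <- do.call(rbind, strsplit(toupper(grp), ""))
  paste(apply(mat, 2, function(col) {
    tt <- sort(table(col), decreasing = TRUE)
    cands <- names(tt)[tt == max(tt)]
    sort(cands)[1]
  }), collapse = "")
}

# mean identity of repeats to the consensus; off-length repeats are
# end-anchored (5') and compared over the shorter length
mean_repeat_identity <- function(repeats) {
  cons <- consensus_repeat(repeats)
  cch <- strsplit(toupper(cons), "")[[1]]
  idents <- vapply(toupper(repeats), function(r) {
    rch <- strsplit(r, "")[[1]]
    L <- min(length(rch), length(cch))
    sum(rch[seq_len(L)] == cch[seq_len(L)]) / L
  }, numeric(1))
  mean(idents)
}

#' Match CRISPR spacers to viral genomes (protospacer search)
#'
#' Scans both strands of each viral genome for near-perfect spacer matches:
#' a spacer substring covering at least `spacer_min_cov` (default 95%) of
#' the spacer length, truncated only at the spacer ends, matching with at
#' most `spacer_max_mismatch` (default 1) mismatches. By default a match
#' may use truncation and the mismatch budget simultaneously; `strict`
#' forbids mismatches in truncated matches.
#'
#' @param spacers data frame with columns `spacer_id` and `seq` (all
#'   longer than 25 bp), or a named character vector.
#' @param viruses named character vector (or `DNAStringSet`) of viral
#'   genome sequences.
#' @param cfg a [mag_thresholds()] configuration.
#' @param strict when `TRUE`, truncated matches must be mismatch-free.
#' @return data frame of accepted matches: `spacer_id`, `virus_id`,
#'   `position` (1-based start of the matched window on the virus forward
#'   strand), `strand`, `mismatches`, `coverage`.
#' @export
match_spacers <- function(spacers, viruses, cfg = mag_thresholds(),
                          strict = FALSE) {
  if (is.character(spacers))
    spacers <- data.frame(spacer_id = names(spacers), seq = unname(spacers),
                          stringsAsFactors = FALSE)
  if (methods::is(viruses, "DNAStringSet")) {
    v <- as.character(viruses)
  } else v <- viruses
  if (is.null(names(v))) stop("viruses must be named")

  hits <- list()
  for (si in seq_len(nrow(spacers))) {
    sp <- toupper(spacers$seq[si])
    L <- nchar(sp)
    min_len <- ceiling(cfg$spacer_min_cov * L)
    budget <- L - min_len
    for (vid in names(v)) {
      vseq <- toupper(v[[vid]])
      fwd <- Biostrings::DNAString(vseq)
      rev <- Biostrings::reverseComplement(fwd)
      for (a in 0:budget) {
        for (b in 0:(budget - a)) {
          sub <- substr(sp, a + 1, L - b)
          mm_allow <- if (strict && (a + b) > 0) 0 else cfg$spacer_max_mismatch
          for (strand in c("+", "-")) {
            subj <- if (strand == "+") fwd else rev
            m <- Biostrings::matchPattern(sub, subj, max.mismatch = mm_allow)
            if (length(m) == 0) next
            st <- Biostrings::start(m)
            en <- Biostrings::end(m)
            ok <- st >= 1 & en <= length(subj)
            for (h in which(ok)) {
              window <- as.character(Biostrings::subseq(subj, st[h], en[h]))
              mm <- sum(strsplit(window, "")[[1]] != strsplit(sub, "")[[1]])
              if (mm > mm_allow) next
              pos_fwd <- if (strand == "+") st[h] else
                nchar(vseq) - en[h] + 1
              hits[[length(hits) + 1]] <- data.frame(
                spacer_id = spacers$spacer_id[si], virus_id = vid,
                position = pos_fwd, strand = strand, mismatches = mm,
                coverage = nchar(sub) / L,
                full_start = st[h] - a,
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  if (!length(hits))
    return(data.frame(spacer_id = character(), virus_id = character(),
                      position = integer(), strand = character(),
                      mismatches = integer(), coverage = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, hits)
  # the same placement can be reached with several truncation choices;
  # keep the best record per (spacer, virus, strand, full-spacer placement)
  res <- res[order(-res$coverage, res$mismatches), ]
  key <- paste(res$spacer_id, res$virus_id, res$strand, res$full_start)
  res <- res[!duplicated(key), ]
  res <- res[order(res$spacer_id, res$virus_id, res$position, res$strand), ]
  res$full_start <- NULL
  rownames(res) <- NULL
  res
}

#' Classify virus-to-contig alignment hits
#'
#' A hit at more than `linkage_min_ident` identity (default 90%) over more
#' than `linkage_min_len` bp (default 500) marks the virus as `integrated`
#' in the MAG when the contig exceeds `prophage_len_ratio` (default 1.5)
#' times the virus length; shorter contigs are `full_viral_discard`
#' (likely a free viral sequence binned by its own composition, carrying no
#' host information). Hits failing the identity or length bound are
#' `none`.
#'
#' @param hits data frame with columns `contig_id`, `virus_id`, `identity`
#'   (fraction) and `length` (aligned bp).
#' @param contig_lengths,virus_lengths named numeric vectors (bp); a hit
#'   referencing an unknown contig or virus is an error.
#' @param cfg a [mag_thresholds()] configuration.
#' @return the input with a `verdict` column (`integrated`,
#'   `full_viral_discard` or `none`).
#' @export
sequence_linkage <- function(hits, contig_lengths, virus_lengths,
                             cfg = mag_thresholds()) {
  miss_c <- setdiff(unique(hits$contig_id), names(contig_lengths))
  miss_v <- setdiff(unique(hits$virus_id), names(virus_lengths))
  if (length(miss_c)) stop("missing contig length(s): ",
                           paste(miss_c, collapse = ", "))
  if (length(miss_v)) stop("missing virus length(s): ",
                           paste(miss_v, collapse = ", "))
  clen <- contig_lengths[hits$contig_id]
  vlen <- virus_lengths[hits$virus_id]
  strong <- hits$identity > cfg$linkage_min_ident &
    hits$length > cfg$linkage_min_len
  hits$verdict <- ifelse(!strong, "none",
                         ifelse(clen > cfg$prophage_len_ratio * vlen,
                                "integrated", "full_viral_discard"))
  hits
}

#' Accept or reject de novo prophage predictions
#'
#' A prediction is accepted when its detector category is 4 or 5, fewer
#' than `decayed_pfam_frac` (default 30%) of its genes have a Pfam best
#' hit (a high fraction indicates a decayed, inactive prophage), and it
#' does not overlap a known virus. All arguments are vectorized.
#'
#' @param category detector confidence category (integer; 4 and 5 accepted
#'   by default, 6 is the lower-confidence extension and is rejected).
#' @param n_genes number of predicted genes (must be >= 1).
#' @param n_pfam_best_hits number of genes with a Pfam best hit.
#' @param known_virus_overlap logical: does the contig match a known viral
#'   genome (>90% identity over >500 bp)?
#' @param cfg a [mag_thresholds()] configuration.
#' @return logical vector of acceptances.
#' @export
accept_de_novo_prophage <- function(category, n_genes, n_pfam_best_hits,
                                    known_virus_overlap,
                                    cfg = mag_thresholds()) {
  if (any(n_genes < 1)) stop("n_genes must be >= 1")
  if (any(n_pfam_best_hits > n_genes))
    stop("n_pfam_best_hits cannot exceed n_genes")
  category %in% c(4, 5) &
    (n_pfam_best_hits / n_genes) < cfg$decayed_pfam_frac &
    !known_virus_overlap
}

#' Aggregate virus-host linkages
#'
#' Summarizes a linkage table: per-virus agreement with the modal host
#' family (fraction of that virus's linkages pointing at its most common
#' family), the overall fraction of multiply-linked viruses whose
#' agreement is 1, the per-phylum fraction of MAGs linked by each method,
#' and the fraction of linkages whose virus and MAG share a top-level
#' environment label.
#'
#' @param linkages data frame with columns `virus_id`, `mag_id`, `method`
#'   (one of `crispr`, `sequence`, `de_novo_prophage`).
#' @param host_taxonomy data frame keyed by `mag_id` with columns `family`
#'   and optionally `phylum`; must cover all linked MAGs.
#' @param virus_env,mag_env optional named character vectors of top-level
#'   environment labels.
#' @param n_mags_per_phylum optional named vector giving the MAG universe
#'   per phylum (defaults to the MAGs seen in `host_taxonomy`).
#' @return list with `per_virus`, `family_consistency`,
#'   `frac_perfect_agreement`, `per_phylum` and `env_concordance`.
#' @export
aggregate_linkages <- function(linkages, host_taxonomy, virus_env = NULL,
                               mag_env = NULL, n_mags_per_phylum = NULL) {
  miss <- setdiff(unique(linkages$mag_id), host_taxonomy$mag_id)
  if (length(miss)) stop("host taxonomy missing for MAG(s): ",
                         paste(miss, collapse = ", "))
  fam <- host_taxonomy$family[match(linkages$mag_id, host_taxonomy$mag_id)]

  per_virus <- do.call(rbind, lapply(split(fam, linkages$virus_id),
    function(f) {
      tt <- table(f)
      data.frame(n_linkages = length(f),
                 modal_family = names(tt)[which.max(tt)],
                 agreement = max(tt) / length(f),
                 stringsAsFactors = FALSE)
    }))
  per_virus$virus_id <- rownames(per_virus)
  rownames(per_virus) <- NULL
  per_virus <- per_virus[, c("virus_id", "n_linkages", "modal_family",
                             "agreement")]

  # family consistency: mean per-linkage agreement and the fraction of
  # viruses all of whose linkages hit one family
  family_consistency <- sum(per_virus$agreement * per_virus$n_linkages) /
    sum(per_virus$n_linkages)
  frac_perfect <- mean(per_virus$agreement == 1)

  per_phylum <- NULL
  if ("phylum" %in% names(host_taxonomy)) {
    phy <- host_taxonomy$phylum[match(linkages$mag_id, host_taxonomy$mag_id)]
    universe <- if (is.null(n_mags_per_phylum))
      table(host_taxonomy$phylum) else n_mags_per_phylum
    per_phylum <- do.call(rbind, lapply(names(universe), function(p) {
      in_p <- which(phy == p)
      rows <- lapply(unique(linkages$method), function(m) {
        mags <- unique(linkages$mag_id[in_p][linkages$method[in_p] == m])
        data.frame(phylum = p, method = m,
                   frac_mags_linked = length(mags) / as.numeric(universe[[p]]),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }))
  }

  env_concordance <- NA_real_
  if (!is.null(virus_env) && !is.null(mag_env)) {
    ve <- virus_env[linkages$virus_id]
    me <- mag_env[linkages$mag_id]
    env_concordance <- mean(ve == me, na.rm = TRUE)
  }

  list(per_virus = per_virus,
       family_consistency = family_consistency,
       frac_perfect_agreement = frac_perfect,
       per_phylum = per_phylum,
       env_concordance = env_concordance)
}
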