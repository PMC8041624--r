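make_array <- function(array_id, mag, repeats, spacers) {
  rbind(
    data.frame(array_id = array_id, mag_id = mag, contig_id = "c1",
               type = "repeat", seq = repeats, stringsAsFactors = FALSE),
    data.frame(array_id = array_id, mag_id = mag, contig_id = "c1",
               type = "spacer", seq = spacers, stringsAsFactors = FALSE))
}

test_that("array filters enforce spacer count, repeat identity and cas count", {
  rep30 <- strrep("ACGT", 8)  # 32 bp repeat
  sp <- function(n) vapply(seq_len(n), function(i)
    gen_genome(30, seed = 500 + i), character(1))
  cas <- c(magA = 4, magB = 3)

  ok <- filter_crispr_arrays(make_array("a1", "magA", rep(rep30, 4), sp(3)),
                             cas)
  expect_equal(unique(ok$kept$array_id), "a1")
  expect_equal(sum(ok$kept$type == "spacer"), 3)

  few <- filter_crispr_arrays(make_array("a2", "magA", rep(rep30, 3), sp(2)),
                              cas)
  expect_equal(nrow(few$kept), 0)
  expect_match(few$rejected$reason, "spacer count")

  lowcas <- filter_crispr_arrays(make_array("a3", "magB", rep(rep30, 4),
                                            sp(3)), cas)
  expect_match(lowcas$rejected$reason, "cas count")

  expect_error(filter_crispr_arrays(make_array("a4", "magZ", rep30, sp(3)),
                                    cas), "magZ")
})

test_that("repeat conservation boundary sits exactly at 97% mean identity", {
  base <- gen_genome(100, seed = 77)
  corrupt <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    ch[seq_len(k)] <- vapply(ch[seq_len(k)], function(b)
      setdiff(c("A", "C", "G", "T"), b)[1], character(1))
    paste(ch, collapse = "")
  }
  sp <- vapply(1:3, function(i) gen_genome(30, seed = 600 + i), character(1))
  cas <- c(m = 5)
  # 9 perfect + identity 0.70 -> mean 0.970: kept
  kept <- filter_crispr_arrays(
    make_array("b1", "m", c(rep(base, 9), corrupt(base, 30)), sp), cas)
  expect_equal(nrow(kept$rejected), 0)
  # 9 perfect + identity 0.69 -> mean 0.969: dropped
  drop <- filter_crispr_arrays(
    make_array("b2", "m", c(rep(base, 9), corrupt(base, 31)), sp), cas)
  expect_match(drop$rejected$reason, "nonconserved")
})

test_that("short spacers are removed from kept arrays at the 25 bp bound", {
  rep30 <- gen_genome(30, seed = 88)
  spacers <- c(gen_genome(25, seed = 89), gen_genome(26, seed = 90),
               gen_genome(40, seed = 91))
  out <- filter_crispr_arrays(make_array("c1", "m", rep(rep30, 4), spacers),
                              c(m = 4))
  kept_sp <- out$kept$seq[out$kept$type == "spacer"]
  expect_equal(sort(nchar(kept_sp)), c(26, 40))
})

test_that("array filters are order-independent", {
  set.seed(13)
  rep30 <- gen_genome(30, seed = 92)
  arr <- rbind(
    make_array("d1", "m1", rep(rep30, 4),
               vapply(1:3, function(i) gen_genome(30, seed = 700 + i),
                      character(1))),
    make_array("d2", "m2", rep(rep30, 3),
               vapply(1:2, function(i) gen_genome(30, seed = 800 + i),
                      character(1))))
  cas <- c(m1 = 6, m2 = 6)
  out1 <- filter_crispr_arrays(arr, cas)
  out2 <- filter_crispr_arrays(arr[sample(nrow(arr)), ], cas)
  expect_setequal(unique(out1$kept$array_id), unique(out2$kept$array_id))
  expect_setequal(out1$kept$seq, out2$kept$seq)
})

test_that("consensus repeat is the per-column majority", {
  reps <- c("AAAA", "AAAA", "AATA", "CAAA")
  expect_equal(consensus_repeat(reps), "AAAA")
  # alphabetical tie-break per column
  expect_equal(consensus_repeat(c("AC", "CA")), "AA")
})

test_that("spacer matches respect the mismatch and coverage budget", {
  set.seed(14)
  virus <- gen_genome(400, seed = 15)
  spacer <- substr(virus, 101, 130)  # 30 bp exact protospacer
  hits <- match_spacers(c(s1 = spacer), c(v1 = virus))
  exact <- hits[hits$mismatches == 0 & hits$coverage == 1, ]
  expect_true(any(exact$position == 101 & exact$strand == "+"))

  # two substitutions: no acceptance
  ch <- strsplit(spacer, "")[[1]]
  ch[5] <- setdiff(c("A", "C", "G", "T"), ch[5])[1]
  ch[20] <- setdiff(c("A", "C", "G", "T"), ch[20])[1]
  two <- match_spacers(c(s1 = paste(ch, collapse = "")), c(v1 = virus))
  expect_false(any(two$position == 101 & two$strand == "+"))

  # reverse-complement placement is found on the minus strand
  rc_hits <- match_spacers(c(s1 = revcomp_chr(spacer)), c(v1 = virus))
  expect_true(any(rc_hits$position == 101 & rc_hits$strand == "-"))

  # strict mode forbids combining truncation with a mismatch: a spacer
  # whose only placement needs one leading truncation plus one internal
  # substitution is accepted by default but not in strict mode
  ch1 <- strsplit(spacer, "")[[1]]
  ch1[15] <- setdiff(c("A", "C", "G", "T"), ch1[15])[1]
  bad_head <- setdiff(c("A", "C", "G", "T"),
                      substr(virus, 101, 101))[1]  # 2 mm if not truncated
  probe <- paste0(bad_head, paste(ch1[2:30], collapse = ""))
  lax <- match_spacers(c(s1 = probe), c(v1 = virus))
  expect_true(any(lax$position == 102 & lax$strand == "+" &
                  lax$coverage < 1))
  strict <- match_spacers(c(s1 = probe), c(v1 = virus), strict = TRUE)
  expect_false(any(strict$position == 102 & strict$strand == "+"))
})

test_that("spacer matcher agrees with the brute-force scanner", {
  set.seed(16)
  for (trial in 1:60) {
    vlen <- sample(150:350, 1)
    virus <- gen_genome(vlen, seed = 1000 + trial)
    L <- sample(26:40, 1)
    if (trial %% 2 == 0) {
      st <- sample(vlen - L + 1, 1)
      sp <- substr(virus, st, st + L - 1)
      nmm <- sample(0:2, 1)
      if (nmm > 0) {
        ch <- strsplit(sp, "")[[1]]
        for (i in sample(L, nmm))
          ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
        sp <- paste(ch, collapse = "")
      }
      if (trial %% 4 == 0) sp <- revcomp_chr(sp)
    } else {
      sp <- gen_genome(L, seed = 2000 + trial)
    }
    got <- match_spacers(data.frame(spacer_id = "s", seq = sp),
                         c(v = virus))
    got <- got[order(got$position, got$strand),
               c("strand", "position", "mismatches", "coverage")]
    rownames(got) <- NULL
    want <- naive_spacer_scan(sp, virus)
    expect_equal(got, want, info = paste("trial", trial))
  }
})

test_that("sequence linkage applies the identity, length and 1.5x rules", {
  hits <- data.frame(
    contig_id = c("c70", "c50", "c70"),
    virus_id = c("v40", "v40", "v40"),
    identity = c(0.92, 0.92, 0.89),
    length = c(600, 600, 10000), stringsAsFactors = FALSE)
  clen <- c(c70 = 70000, c50 = 50000)
  vlen <- c(v40 = 40000)
  out <- sequence_linkage(hits, clen, vlen)
  expect_equal(out$verdict, c("integrated", "full_viral_discard", "none"))
  # boundaries are strict
  b <- sequence_linkage(data.frame(contig_id = "c70", virus_id = "v40",
                                   identity = 0.90, length = 501,
                                   stringsAsFactors = FALSE), clen, vlen)
  expect_equal(b$verdict, "none")
  b2 <- sequence_linkage(data.frame(contig_id = "c70", virus_id = "v40",
                                    identity = 0.91, length = 500,
                                    stringsAsFactors = FALSE), clen, vlen)
  expect_equal(b2$verdict, "none")
  expect_error(sequence_linkage(hits, clen[-1], vlen), "c70")
})

test_that("de novo prophage acceptance applies category, Pfam and overlap rules", {
  expect_false(accept_de_novo_prophage(5, 10, 3, FALSE))  # 30% is decayed
  expect_true(accept_de_novo_prophage(5, 10, 2, FALSE))
  expect_false(accept_de_novo_prophage(6, 10, 0, FALSE))
  expect_false(accept_de_novo_prophage(4, 10, 1, TRUE))
  expect_true(accept_de_novo_prophage(4, 10, 2, FALSE))
  expect_error(accept_de_novo_prophage(5, 0, 0, FALSE), "n_genes")
  # tightening the Pfam threshold never adds an acceptance
  set.seed(17)
  cat_ <- sample(3:6, 50, replace = TRUE)
  ng <- sample(5:20, 50, replace = TRUE)
  nh <- vapply(ng, function(k) sample(0:k, 1), integer(1))
  ov <- sample(c(TRUE, FALSE), 50, TRUE)
  loose <- accept_de_novo_prophage(cat_, ng, nh, ov,
                                   mag_thresholds(decayed_pfam_frac = 0.5))
  tight <- accept_de_novo_prophage(cat_, ng, nh, ov,
                                   mag_thresholds(decayed_pfam_frac = 0.2))
  expect_true(all(loose | !tight))
})

test_that("linkage aggregation computes family agreement and environment concordance", {
  linkages <- data.frame(
    virus_id = c("v1", "v1", "v1", "v2", "v2"),
    mag_id = c("m1", "m2", "m3", "m4", "m5"),
    method = c("crispr", "crispr", "sequence", "crispr", "crispr"),
    stringsAsFactors = FALSE)
  tax <- data.frame(mag_id = paste0("m", 1:5),
                    family = c("F1", "F1", "F2", "F3", "F3"),
                    phylum = c("P1", "P1", "P1", "P2", "P2"),
                    stringsAsFactors = FALSE)
  res <- aggregate_linkages(linkages, tax)
  v1 <- res$per_virus[res$per_virus$virus_id == "v1", ]
  expect_equal(v1$agreement, 2 / 3)
  v2 <- res$per_virus[res$per_virus$virus_id == "v2", ]
  expect_equal(v2$agreement, 1)
  expect_equal(res$frac_perfect_agreement, 0.5)
  p1 <- res$per_phylum[res$per_phylum$phylum == "P1" &
                       res$per_phylum$method == "crispr", ]
  expect_equal(p1$frac_mags_linked, 2 / 3)
  expect_error(aggregate_linkages(linkages, tax[-1, ]), "m1")
})

test_that("planted environment concordance is recovered on a seeded cohort", {
  set.seed(18)
  n <- 500
  mags <- sprintf("m%03d", 1:n)
  envs <- c("Aquatic", "Terrestrial", "Host-associated")
  mag_env <- setNames(sample(envs, n, replace = TRUE), mags)
  viruses <- sprintf("v%03d", 1:n)
  agree <- runif(n) < 0.95
  virus_env <- setNames(ifelse(agree, mag_env,
    vapply(mag_env, function(e) sample(setdiff(envs, e), 1), character(1))),
    viruses)
  linkages <- data.frame(virus_id = viruses, mag_id = mags,
                         method = "crispr", stringsAsFactors = FALSE)
  tax <- data.frame(mag_id = mags, family = "F1", stringsAsFactors = FALSE)
  res <- aggregate_linkages(linkages, tax, virus_env, mag_env)
  expect_equal(res$env_concordance, mean(agree), tolerance = 1e-12)
  expect_lt(abs(res$env_concordance - 0.95), 0.02)
})
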