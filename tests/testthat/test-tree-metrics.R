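test_that("rooting between two leaf sets places the root on the separating edge", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  rooted <- root_between(tr, c("A", "B"), c("C", "D"))
  expect_true(ape::is.rooted(rooted))
  expect_true(ape::is.monophyletic(rooted, c("A", "B")))
  expect_true(ape::is.monophyletic(rooted, c("C", "D")))
  expect_error(root_between(tr, c("A", "C"), c("B", "D")),
               "no single edge")
  expect_error(root_between(tr, c("A", "B"), c("C")), "bipartition")
  expect_error(root_between(tr, c("A", "B", "C"), c("C", "D")), "disjoint")
})

test_that("a two-domain tree is monophyletic per domain after rooting", {
  tr <- two_domain_tree(25, seed = 3)
  a <- grep("^A", tr$tip.label, value = TRUE)
  b <- grep("^B", tr$tip.label, value = TRUE)
  rooted <- root_between(tr, a, b)
  expect_true(ape::is.monophyletic(rooted, a))
  expect_true(ape::is.monophyletic(rooted, b))
  kids <- rooted$edge[rooted$edge[, 1] == length(rooted$tip.label) + 1, 2]
  expect_equal(length(kids), 2)
})

test_that("phylogenetic diversity matches hand sums and picante", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(phylogenetic_diversity(tr, c("A", "B", "C")), 5)
  expect_equal(phylogenetic_diversity(tr, "C"), 2)
  expect_equal(phylogenetic_diversity(tr, c("A", "B")), 3)
  expect_equal(phylogenetic_diversity(tr, tr$tip.label),
               sum(tr$edge.length))
  expect_error(phylogenetic_diversity(tr, "Z"), "unknown leaf")

  skip_if_not_installed("picante")
  for (seed in 1:5) {
    rt <- random_tree(30, seed)
    set.seed(seed + 100)
    leaves <- sample(rt$tip.label, 10)
    comm <- matrix(as.integer(rt$tip.label %in% leaves), nrow = 1,
                   dimnames = list("s", rt$tip.label))
    ref <- picante::pd(comm, rt, include.root = TRUE)$PD
    expect_equal(phylogenetic_diversity(rt, leaves), ref, tolerance = 1e-9)
  }
})

test_that("PD gain matches hand computation and conserves branch lengths", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  g <- pd_gain(tr, "C", c("A", "B"))
  expect_equal(g$gain_fraction, 2 / 3)
  expect_equal(pd_gain(tr, "A", c("A", "B"))$gain_fraction, 0)  # a within b
  expect_error(pd_gain(ape::read.tree(text = "((A:0,B:0):0,C:1);"),
                       "C", c("A", "B")), "zero")

  for (seed in 1:5) {
    rt <- random_tree(40, seed)
    set.seed(seed)
    a <- sample(rt$tip.label, 12)
    b <- sample(rt$tip.label, 15)
    g <- pd_gain(rt, a, b)
    # decomposition: uniquely-a + b-side = union
    expect_equal(g$share_fraction * g$pd_union + g$pd_b, g$pd_union,
                 tolerance = 1e-9)
    # brute-force union via edge marking on the combined set
    expect_equal(g$pd_union, phylogenetic_diversity(rt, union(a, b)),
                 tolerance = 1e-12)
    # monotone under superset, subadditive
    expect_gte(g$pd_union + 1e-12, max(g$pd_a, g$pd_b))
    expect_lte(g$pd_union, g$pd_a + g$pd_b + 1e-12)
  }
})

test_that("RED matches the recurrence on hand fixtures", {
  tr <- ape::read.tree(text = "(A:2,(B:1,C:1):1);")
  red <- compute_red(tr)
  expect_equal(unname(red[4]), 0)        # root
  expect_equal(unname(red[1:3]), c(1, 1, 1))
  expect_equal(unname(red[5]), 0.5, tolerance = 1e-12)

  # ultrametric balanced depth-3: equal REDs per depth, increasing
  nwk <- "(((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1);"
  bt <- ape::read.tree(text = nwk)
  redb <- compute_red(bt)
  d1 <- redb[c(10, 13)]  # depth-1 internal nodes
  d2 <- redb[c(11, 12, 14, 15)]
  expect_equal(unname(d1), rep(1 / 3, 2), tolerance = 1e-12)
  expect_equal(unname(d2), rep(2 / 3, 4), tolerance = 1e-12)
})

test_that("RED is monotone root-to-leaf and scale-invariant on random trees", {
  for (seed in 1:25) {
    rt <- random_tree(4 + seed %% 30, seed)
    red <- compute_red(rt)
    n <- length(rt$tip.label)
    expect_equal(unname(red[n + 1]), 0)
    expect_true(all(red[seq_len(n)] == 1))
    parent <- rt$edge[, 1]
    child <- rt$edge[, 2]
    expect_true(all(red[child] >= red[parent] - 1e-12))
    expect_true(all(red >= 0 & red <= 1))
    scaled <- rt
    scaled$edge.length <- rt$edge.length * 7.3
    expect_equal(compute_red(scaled), red, tolerance = 1e-12)
  }
  # degenerate zero-length subtree inherits the parent RED
  z <- ape::read.tree(text = "(A:1,(B:0,C:0):0);")
  redz <- compute_red(z)
  expect_equal(unname(redz[5]), unname(redz[4]))
})

test_that("RED clustering emits shallowest qualifying clades", {
  tr <- ape::read.tree(text = "(A:2,(B:1,C:1):1);")
  red <- compute_red(tr)
  cl <- cluster_by_red(tr, red, 0.4, support_min = 0)
  grp <- split(cl$leaf, cl$group)
  expect_equal(length(grp), 2)
  expect_true(any(vapply(grp, function(g) setequal(g, c("B", "C")),
                         logical(1))))
  # near-1 cutoff: only leaves qualify, all singletons
  cl1 <- cluster_by_red(tr, red, 0.9999, support_min = 0)
  expect_equal(nrow(cl1), 3)
  expect_equal(length(unique(cl1$group)), 3)
  # failing support splits the clade into its children
  tr2 <- tr
  tr2$node.label <- c("", "0.5")  # (B,C) node support 0.5
  cl2 <- cluster_by_red(tr2, compute_red(tr2), 0.4, support_min = 0.7)
  expect_equal(length(unique(cl2$group)), 3)
  expect_error(cluster_by_red(tr, red, 1.0), "cutoff")
})

test_that("RED cluster output partitions leaves; raising cutoffs only splits", {
  for (seed in 1:10) {
    rt <- random_tree(30, seed)
    red <- compute_red(rt)
    lo <- cluster_by_red(rt, red, 0.35, support_min = 0)
    hi <- cluster_by_red(rt, red, 0.7, support_min = 0)
    expect_setequal(lo$leaf, rt$tip.label)
    expect_equal(anyDuplicated(lo$leaf), 0L)
    # each high-cutoff group is inside a single low-cutoff group
    lo_of <- setNames(lo$group, lo$leaf)
    for (g in split(hi$leaf, hi$group))
      expect_equal(length(unique(lo_of[g])), 1)
  }
})

test_that("cutoff calibration recovers a planted cutoff and rejects noise", {
  tt <- gen_labelled_tree(80, c(order = 0.5), seed = 9)
  labels <- setNames(tt$taxonomy$order, tt$taxonomy$leaf)
  cal <- calibrate_red_cutoff(tt$tree, labels, grid_step = 0.1)
  expect_equal(cal$cutoff, 0.5, tolerance = 1e-9)
  expect_equal(cal$ami_at_cutoff, 1.0, tolerance = 1e-9)

  # grid_step 0.5 evaluates exactly cutoff 0.5
  cal5 <- calibrate_red_cutoff(tt$tree, labels, grid_step = 0.5)
  expect_equal(cal5$grid$cutoff, 0.5)

  set.seed(10)
  noise <- setNames(sample(letters[1:4], 80, replace = TRUE),
                    tt$taxonomy$leaf)
  caln <- calibrate_red_cutoff(tt$tree, noise, grid_step = 0.1)
  expect_lt(abs(caln$ami_at_cutoff), 0.1)

  expect_error(calibrate_red_cutoff(tt$tree,
    setNames(rep("x", 80), tt$taxonomy$leaf)), "degenerate")
})

test_that("AMI satisfies its defining properties", {
  expect_equal(adjusted_mutual_information(c(1, 1, 2, 2, 3),
                                           c("x", "x", "y", "y", "z")), 1)
  expect_equal(adjusted_mutual_information(rep(1, 6), c(1, 2, 1, 2, 1, 2)), 0)
  expect_error(adjusted_mutual_information(1, 2), "at least 2")
  expect_error(adjusted_mutual_information(1:3, 1:4), "equal length")
  set.seed(12)
  a <- sample(3, 40, replace = TRUE)
  b <- sample(4, 40, replace = TRUE)
  expect_equal(adjusted_mutual_information(a, b),
               adjusted_mutual_information(b, a), tolerance = 1e-12)
  # invariant to label renaming
  expect_equal(adjusted_mutual_information(a, b),
               adjusted_mutual_information(4 - a, b), tolerance = 1e-12)
})

test_that("medoid selection maximizes mean off-diagonal identity", {
  expect_equal(medoid_select(matrix(1)), 1L)
  m <- matrix(c(1, .9, .9, .9, 1, .99, .9, .99, 1), 3, 3)
  expect_equal(medoid_select(m), 2L)
  expect_error(medoid_select(matrix(c(1, 2, 3, 4), 2)), "symmetric")
  for (seed in 1:10) {
    set.seed(seed)
    x <- matrix(runif(100), 10)
    m <- (x + t(x)) / 2
    diag(m) <- 1
    expect_equal(medoid_select(m), naive_medoid(m))
  }
})
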