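#' Root a tree on the edge separating two leaf sets
#'
#' Places the root at the midpoint of the single edge whose removal
#' bipartitions the leaves into exactly `set_a` and `set_b` (for example,
#' between two domains). Errors when the two sets do not partition the
#' leaves or when no single edge separates them.
#'
#' @param tree an `ape::phylo` tree (rooted trees are unrooted first).
#' @param set_a,set_b character vectors of leaf labels forming a
#'   bipartition of the tips.
#' @return a rooted `phylo` whose two root children subtend `set_a` and
#'   `set_b`.
#' @export
root_between <- function(tree, set_a, set_b) {
  tips <- tree$tip.label
  if (length(intersect(set_a, set_b)))
    stop("set_a and set_b must be disjoint")
  if (!setequal(c(set_a, set_b), tips) || !length(set_a) || !length(set_b))
    stop("set_a and set_b must bipartition the leaves")
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  desc <- tip_descendants(tr)
  n <- length(tips)
  root <- n + 1L
  target <- NA_integer_
  for (node in seq_along(desc)) {
    if (node == root) next
    below <- tr$tip.label[desc[[node]]]
    if (setequal(below, set_a) || setequal(below, set_b)) {
      target <- node
      break
    }
  }
  if (is.na(target))
    stop("no single edge separates the two leaf sets")
  edge_i <- which(tr$edge[, 2] == target)
  pos <- tr$edge.length[edge_i] / 2
  rooted <- phytools::reroot(tr, node.number = target, position = pos)
  rooted
}

# list of tip index vectors below each node (tips: themselves)
tip_descendants <- function(tree) {
  n <- length(tree$tip.label)
  m <- n + tree$Nnode
  desc <- vector("list", m)
  for (i in seq_len(n)) desc[[i]] <- i
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1]; ch <- edge[i, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

# indices (into tree$edge rows) of edges in the minimal subtree connecting
# `leaves` to the root
spanning_edges <- function(tree, leaves) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!length(leaves)) stop("leaf set must be non-empty")
  idx <- match(leaves, tree$tip.label)
  if (anyNA(idx))
    stop("unknown leaf label(s): ",
         paste(leaves[is.na(idx)], collapse = ", "))
  n <- length(tree$tip.label)
  root <- n + 1L
  parent <- integer(n + tree$Nnode)
  edge_of <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  marked <- logical(n + tree$Nnode)
  for (tip in idx) {
    node <- tip
    while (node != root && !marked[node]) {
      marked[node] <- TRUE
      node <- parent[node]
    }
  }
  edge_of[which(marked)]
}

#' Phylogenetic diversity of a leaf subset
#'
#' Sum of branch lengths in the minimal spanning subtree connecting the
#' given leaves to the root. With all leaves this equals the total branch
#' length of the tree.
#'
#' @param tree a rooted `ape::phylo` with branch lengths.
#' @param leaves character vector of leaf labels (non-empty; unknown labels
#'   are an error).
#' @return numeric branch-length sum.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' phylogenetic_diversity(tr, c("A", "B", "C"))  # 5
#' phylogenetic_diversity(tr, "C")               # 2
#' @export
phylogenetic_diversity <- function(tree, leaves) {
  sum(tree$edge.length[spanning_edges(tree, leaves)])
}

#' Phylogenetic diversity gain of one leaf set over another
#'
#' `gain_fraction` is the relative increase in PD when adding set `a` to a
#' baseline set `b`: `(PD(a + b) - PD(b)) / PD(b)`. `share_fraction` is the
#' proportion of the combined spanning subtree covered only by `a`.
#' Branch lengths decompose exactly: uniquely-a + uniquely-b + shared =
#' PD(a + b).
#'
#' @param tree a rooted `ape::phylo` with branch lengths.
#' @param set_a,set_b character vectors of leaf labels; their union must be
#'   non-empty and `PD(set_b)` must be positive.
#' @return list with `gain_fraction`, `share_fraction`, `pd_a`, `pd_b`,
#'   `pd_union`.
#' @export
pd_gain <- function(tree, set_a, set_b) {
  ea <- spanning_edges(tree, set_a)
  eb <- spanning_edges(tree, set_b)
  len <- tree$edge.length
  pd_b <- sum(len[eb])
  pd_union <- sum(len[union(ea, eb)])
  if (pd_b <= 0) stop("PD of the baseline set is zero; gain undefined")
  list(gain_fraction = (pd_union - pd_b) / pd_b,
       share_fraction = sum(len[setdiff(ea, eb)]) / pd_union,
       pd_a = sum(len[ea]), pd_b = pd_b, pd_union = pd_union)
}

#' Relative evolutionary divergence of every node
#'
#' Computes RED by the standard recurrence: the root has RED 0, leaves have
#' RED 1, and an internal node with parent RED `p`, branch length `d` to
#' its parent and mean parent-to-descendant-leaf distance `u` gets
#' `red = p + (d / u) * (1 - p)`, clamped to at most 1. Degenerate
#' zero-length subtrees (`u = 0`) inherit the parent's RED, the limit of
#' the recurrence. RED is non-decreasing along every root-to-leaf path and
#' invariant under uniform branch-length scaling.
#'
#' @param tree a rooted `ape::phylo` with non-negative branch lengths.
#' @return numeric vector of RED values indexed by node number (tips
#'   `1..n`, then internal nodes), with names for tips.
#' @examples
#' tr <- ape::read.tree(text = "(A:2,(B:1,C:1):1);")
#' compute_red(tr)[5]  # the (B,C) node: 0.5
#' @export
compute_red <- function(tree) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  n <- length(tree$tip.label)
  m <- n + tree$Nnode
  root <- n + 1L

  # postorder: per node, number of descendant leaves and summed distances
  post <- ape::reorder.phylo(tree, "postorder")
  nleaf <- c(rep(1, n), rep(0, tree$Nnode))
  sumdist <- numeric(m)
  for (i in seq_len(nrow(post$edge))) {
    p <- post$edge[i, 1]; ch <- post$edge[i, 2]; d <- post$edge.length[i]
    nleaf[p] <- nleaf[p] + nleaf[ch]
    sumdist[p] <- sumdist[p] + sumdist[ch] + nleaf[ch] * d
  }

  red <- numeric(m)
  red[seq_len(n)] <- 1
  red[root] <- 0
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(pre$edge))) {
    p <- pre$edge[i, 1]; ch <- pre$edge[i, 2]; d <- pre$edge.length[i]
    if (ch <= n) next  # leaves stay at 1
    u <- d + sumdist[ch] / nleaf[ch]
    red[ch] <- if (u <= 0) red[p] else min(1, red[p] + (d / u) * (1 - red[p]))
  }
  names(red) <- c(tree$tip.label, rep("", tree$Nnode))
  red
}

# numeric support per internal node from node labels; NA -> default
node_supports <- function(tree, default_support = 1) {
  supp <- rep(default_support, tree$Nnode)
  if (!is.null(tree$node.label)) {
    parsed <- suppressWarnings(as.numeric(tree$node.label))
    supp[!is.na(parsed)] <- parsed[!is.na(parsed)]
  }
  supp
}

#' Cluster leaves into monophyletic groups at a RED cutoff
#'
#' Walking from the root, a clade is emitted at the shallowest node whose
#' RED reaches the cutoff and whose support exceeds `support_min`; nodes
#' failing the support bound are split into their children. Leaves not
#' covered by any qualifying clade become singleton groups. The output
#' groups are disjoint, cover all leaves, and raising the cutoff never
#' merges two previously separate groups.
#'
#' @param tree a rooted `ape::phylo`.
#' @param red RED values from [compute_red()] (recomputed when `NULL`).
#' @param cutoff RED cutoff in (0, 1).
#' @param support_min minimum (exclusive) support for a clade to be emitted
#'   (default 0.7).
#' @param default_support support assumed for nodes without a parseable
#'   support label (default 1).
#' @return data frame with columns `leaf` and `group`.
#' @export
cluster_by_red <- function(tree, red = NULL, cutoff, support_min = 0.7,
                           default_support = 1) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)")
  if (is.null(red)) red <- compute_red(tree)
  n <- length(tree$tip.label)
  root <- n + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  supp <- node_supports(tree, default_support)

  leaf <- character(0)
  group <- character(0)
  gid <- 0L
  desc <- tip_descendants(tree)
  stack <- root
  while (length(stack)) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (node <= n) {
      gid <- gid + 1L
      leaf <- c(leaf, tree$tip.label[node])
      group <- c(group, sprintf("G%04d", gid))
    } else if (red[node] >= cutoff && supp[node - n] > support_min) {
      gid <- gid + 1L
      tips <- tree$tip.label[desc[[node]]]
      leaf <- c(leaf, tips)
      group <- c(group, rep(sprintf("G%04d", gid), length(tips)))
    } else {
      # push children in reverse so traversal stays left-to-right
      stack <- c(stack, rev(kids[[as.character(node)]]))
    }
  }
  data.frame(leaf = leaf, group = group, stringsAsFactors = FALSE)
}

#' Calibrate a rank's RED cutoff against a taxonomy
#'
#' Grid-searches cutoffs in (0, 1) at `grid_step`, clusters the full tree
#' with [cluster_by_red()] at each cutoff, and scores agreement with the
#' supplied taxonomy labels by adjusted mutual information, evaluated on
#' the labelled leaves only. Returns the cutoff maximizing AMI (ties go to
#' the smallest cutoff).
#'
#' @param tree a rooted `ape::phylo`.
#' @param taxonomy named character vector: taxon label per leaf (a subset
#'   of leaves may be labelled; at least two leaves and two distinct taxa
#'   are required).
#' @param red RED values (recomputed when `NULL`).
#' @param grid_step grid spacing (default 0.001).
#' @param support_min,default_support passed to [cluster_by_red()].
#' @return list with `cutoff`, `ami_at_cutoff` and the full `grid` data
#'   frame.
#' @export
calibrate_red_cutoff <- function(tree, taxonomy, red = NULL,
                                 grid_step = 0.001, support_min = 0.7,
                                 default_support = 1) {
  labelled <- names(taxonomy)
  if (length(labelled) < 2) stop("need taxonomy labels on at least 2 leaves")
  if (length(unique(taxonomy)) < 2)
    stop("taxonomy is degenerate: all labelled leaves share one taxon")
  if (anyNA(match(labelled, tree$tip.label)))
    stop("taxonomy names leaves absent from the tree")
  if (is.null(red)) red <- compute_red(tree)

  cutoffs <- seq(grid_step, 1, by = grid_step)
  cutoffs <- cutoffs[cutoffs > 0 & cutoffs < 1]
  ami <- vapply(cutoffs, function(ct) {
    cl <- cluster_by_red(tree, red, ct, support_min, default_support)
    pred <- cl$group[match(labelled, cl$leaf)]
    adjusted_mutual_information(pred, unname(taxonomy))
  }, numeric(1))
  best <- which.max(ami)  # first maximum = smallest cutoff on ties
  list(cutoff = cutoffs[best], ami_at_cutoff = ami[best],
       grid = data.frame(cutoff = cutoffs, ami = ami))
}

#' Adjusted mutual information between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items:
#' `AMI = (MI - E[MI]) / (mean(H(a), H(b)) - E[MI])`, with the expected
#' mutual information taken under the hypergeometric permutation model and
#' all entropies in nats. Identical labelings with at least two classes
#' score 1; a constant labeling scores 0 by convention.
#'
#' @param labels_a,labels_b vectors of equal length (n >= 2); any atomic
#'   type, compared as factors.
#' @return numeric AMI.
#' @export
adjusted_mutual_information <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labelings must have equal length")
  n <- length(labels_a)
  if (n < 2) stop("need at least 2 items")
  a <- as.integer(factor(labels_a))
  b <- as.integer(factor(labels_b))
  tab <- table(a, b)
  ai <- rowSums(tab)
  bj <- colSums(tab)
  N <- n

  ha <- entropy_nats(ai, N)
  hb <- entropy_nats(bj, N)
  if (ha == 0 || hb == 0) return(0)

  # observed MI
  nz <- which(tab > 0, arr.ind = TRUE)
  nij <- tab[nz]
  mi <- sum(nij / N * log(N * nij / (ai[nz[, 1]] * bj[nz[, 2]])))

  # expected MI under the permutation (hypergeometric) model
  emi <- 0
  lgN <- lgamma(N + 1)
  for (i in seq_along(ai)) {
    for (j in seq_along(bj)) {
      lo <- max(1, ai[i] + bj[j] - N)
      hi <- min(ai[i], bj[j])
      if (hi < lo) next
      k <- lo:hi
      lterm <- lgamma(ai[i] + 1) + lgamma(bj[j] + 1) +
        lgamma(N - ai[i] + 1) + lgamma(N - bj[j] + 1) - lgN -
        lgamma(k + 1) - lgamma(ai[i] - k + 1) - lgamma(bj[j] - k + 1) -
        lgamma(N - ai[i] - bj[j] + k + 1)
      emi <- emi + sum(k / N * log(N * k / (ai[i] * bj[j])) * exp(lterm))
    }
  }

  denom <- (ha + hb) / 2 - emi
  eps <- .Machine$double.eps
  denom <- if (denom < 0) min(denom, -eps) else max(denom, eps)
  (mi - emi) / denom
}

entropy_nats <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

#' Medoid of a pairwise identity matrix
#'
#' Returns the index of the element with the highest mean identity to the
#' others (mean of off-diagonal entries of its row); the representative
#' "centroid gene" rule for pooled marker genes. Ties resolve to the lowest
#' index; a 1x1 matrix returns 1.
#'
#' @param identities square symmetric numeric matrix (n >= 1).
#' @return integer index (1-based).
#' @export
medoid_select <- function(identities) {
  if (!is.matrix(identities) || nrow(identities) == 0)
    stop("identities must be a non-empty square matrix")
  n <- nrow(identities)
  if (ncol(identities) != n) stop("identities must be square")
  if (!isSymmetric(unname(identities), tol = 1e-8))
    stop("identities must be symmetric")
  if (n == 1) return(1L)
  means <- (rowSums(identities) - diag(identities)) / (n - 1)
  which.max(means)
}
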