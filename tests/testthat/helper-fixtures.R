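# Shared fixtures, all built in code.

# the 3-leaf hand-oracle tree: branches A, B, I(=AB ancestor), C, length 1
three_leaf_tree <- function() ape::read.tree(text = "((A:1,B:1)I:1,C:1);")

# two samples j/k on the 3-leaf tree used by the hand-derived values
three_leaf_table <- function() {
  otu_table(matrix(c(5, 5, 0,
                     5, 0, 5), 2, 3, byrow = TRUE,
                   dimnames = list(c("j", "k"), c("A", "B", "C"))))
}

# random count table with matching random tree
random_fixture <- function(n = 5, m = 8, depth = 100, seed = 1) {
  set.seed(seed)
  tree <- ape::rtree(m)
  tree$tip.label <- paste0("OTU", seq_len(m))
  counts <- t(stats::rmultinom(n, depth, stats::runif(m)))
  dimnames(counts) <- list(paste0("S", seq_len(n)), tree$tip.label)
  # guarantee no all-zero sample
  counts[rowSums(counts) == 0, 1] <- 1
  list(table = otu_table(counts), tree = tree)
}

# brute-force leaf-set enumeration oracle for branch profiles: for each edge,
# find the tip set below it by walking the edge list (independent of the
# incidence-matrix implementation)
brute_force_branch_profiles <- function(tree, props, presence) {
  ntip <- length(tree$tip.label)
  tips_below <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  L <- nrow(tree$edge)
  abund <- matrix(0, nrow(props), L)
  rich <- matrix(0, nrow(props), L)
  for (l in seq_len(L)) {
    tips <- tips_below(tree$edge[l, 2])
    labs <- tree$tip.label[tips]
    labs <- intersect(labs, colnames(props))
    if (length(labs)) {
      abund[, l] <- rowSums(unclass(props)[, labs, drop = FALSE])
      rich[, l] <- rowSums(unclass(presence)[, labs, drop = FALSE])
    }
  }
  list(abundance = abund, richness = rich, branch_lengths = tree$edge.length)
}

# exact permutation p-value by full enumeration of orderings (n <= 7)
enumeration_p_value <- function(D, x) {
  G <- gower_center(D)
  n <- length(x)
  perms <- all_permutations(n)
  F_obs <- pseudo_f(G, x, gower = TRUE)
  F_all <- apply(perms, 1, function(p) pseudo_f(G, x[p], gower = TRUE))
  mean(F_all >= F_obs)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
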