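#' Read a rooted phylogenetic tree from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' UniFrac distances need: unique leaf labels and finite, non-negative branch
#' lengths on every edge.
#'
#' @param path path to a Newick file.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick tree in ", path)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicated leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; lengths are required for UniFrac distances")
  if (anyNA(tree$edge.length)) {
    if (all(is.na(tree$edge.length)))
      stop("tree has no branch lengths; lengths are required for UniFrac distances")
    # Newick with lengths on some edges only (typically unannotated internal
    # edges): treat the missing ones as zero-length
    message(sum(is.na(tree$edge.length)),
            " edge(s) without a length treated as zero-length")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  tree
}

#' Leaf-by-branch descent incidence of a rooted tree
#'
#' Returns a sparse 0/1 matrix `A` (leaves x edges) with `A[i, l] = 1` when
#' leaf `i` descends from edge `l`.  Multiplying a samples-by-leaves matrix
#' by `A` accumulates per-leaf quantities up the tree in one step, which is
#' how branch-level abundance and richness profiles are formed.  The root has
#' no incoming edge in the `phylo` encoding, so no root edge appears.
#'
#' @param tree an [ape::phylo] tree.
#' @return A [Matrix::sparseMatrix()] with rows named by `tip.label`.
#' @keywords internal
branch_incidence <- function(tree) {
  ntip <- length(tree$tip.label)
  edges <- tree$edge                       # (parent, child) per edge
  nedge <- nrow(edges)
  # postorder over edges: accumulate the leaf set of each node bottom-up
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  leafsets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) leafsets[[i]] <- i
  for (e in seq_len(nrow(ord))) {
    parent <- ord[e, 1]; child <- ord[e, 2]
    leafsets[[parent]] <- c(leafsets[[parent]], leafsets[[child]])
  }
  ii <- integer(0); jj <- integer(0)
  for (l in seq_len(nedge)) {
    leaves <- leafsets[[edges[l, 2]]]
    ii <- c(ii, leaves)
    jj <- c(jj, rep.int(l, length(leaves)))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(ntip, nedge),
                       dimnames = list(tree$tip.label, NULL))
}

#' Branch-level abundance and richness profiles
#'
#' For each sample j and tree edge l, computes `p_jl`, the total relative
#' abundance of the OTUs descending from l, and `n_jl`, the number of present
#' OTUs descending from l.  These are the primitives of every UniFrac-family
#' distance.
#'
#' @param tree an [ape::phylo] rooted tree whose tips cover all OTU ids.
#' @param props a `proportion_table` from [to_proportions()].
#' @param presence a `presence_table` from [to_presence()]; defaults to the
#'   presence pattern of `props`.
#' @param incidence optional precomputed [branch_incidence()] matrix; pass it
#'   when profiling many tables against one fixed tree (the simulation
#'   harnesses do) to avoid recomputing the tree traversal.
#' @return A list of class `branch_profile` with elements `branch_lengths`
#'   (length L), `abundance` (n x L matrix of p_jl), `richness` (n x L matrix
#'   of n_jl), and `n_leaves` (leaves under each edge).
#' @export
branch_profiles <- function(tree, props, presence = to_presence(props),
                            incidence = NULL) {
  validate_tree(tree)
  if (length(tree$tip.label) < 2L)
    stop("tree must have at least two leaves")
  otus <- colnames(props)
  missing <- setdiff(otus, tree$tip.label)
  if (length(missing))
    stop("OTUs absent from the tree: ", paste(missing, collapse = ", "))
  extra <- setdiff(tree$tip.label, otus)
  if (length(extra))
    message(length(extra), " tree leaf/leaves without matching OTUs retained: ",
            paste(utils::head(extra, 5), collapse = ", "),
            if (length(extra) > 5) ", ..." else "")
  A <- if (is.null(incidence)) branch_incidence(tree) else incidence
  # align table columns to tip order; unmatched tips get zero columns
  pmat <- matrix(0, nrow(props), length(tree$tip.label),
                 dimnames = list(rownames(props), tree$tip.label))
  nmat <- pmat
  pmat[, otus] <- unclass(props)[, otus]
  nmat[, otus] <- unclass(presence)[, otus]
  structure(list(
    branch_lengths = tree$edge.length,
    abundance = as.matrix(pmat %*% A),
    richness = as.matrix(nmat %*% A),
    n_leaves = Matrix::colSums(A),
    sample_ids = rownames(props)
  ), class = "branch_profile")
}

#' Patristic distance matrix between tree leaves
#'
#' Sum of branch lengths along the path connecting each pair of leaves.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return A symmetric matrix with zero diagonal, leaves as dimnames.
#' @export
patristic_matrix <- function(tree) {
  validate_tree(tree)
  ape::cophenetic.phylo(tree)
}
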