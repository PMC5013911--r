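#' Specify a beta-diversity distance
#'
#' The six supported distances fall into abundance distances (`bray_curtis`,
#' `w_unifrac`, `gw_unifrac`) and presence-absence distances (`jaccard`,
#' `uw_unifrac`, `pw_unifrac`).  `gw_unifrac` (generalized UniFrac) and
#' `pw_unifrac` (presence-weighted UniFrac) take an attenuation parameter
#' `alpha` in \[0, 1\]: lower alpha weakens the contribution of highly
#' abundant (respectively, highly rich) branches.
#'
#' @param name one of `"bray_curtis"`, `"jaccard"`, `"w_unifrac"`,
#'   `"gw_unifrac"`, `"uw_unifrac"`, `"pw_unifrac"`; alternatively a compact
#'   string `"pw_unifrac:0.5"` carrying alpha.
#' @param alpha attenuation parameter, required (and only allowed) for
#'   `gw_unifrac` and `pw_unifrac`.
#' @return An object of class `distance_spec`.
#' @export
distance_spec <- function(name, alpha = NULL) {
  if (grepl(":", name, fixed = TRUE)) {
    parts <- strsplit(name, ":", fixed = TRUE)[[1]]
    name <- parts[1]
    alpha <- as.numeric(parts[2])
  } else if (grepl("^[a-z_]+\\([0-9.eE+-]+\\)$", name)) {
    alpha <- as.numeric(sub("^[a-z_]+\\(([^)]+)\\)$", "\\1", name))
    name <- sub("\\(.*$", "", name)
  }
  name <- match.arg(name, c("bray_curtis", "jaccard", "w_unifrac",
                            "gw_unifrac", "uw_unifrac", "pw_unifrac"))
  needs_alpha <- name %in% c("gw_unifrac", "pw_unifrac")
  if (needs_alpha) {
    if (is.null(alpha) || is.na(alpha))
      stop(name, " requires an alpha parameter in [0, 1]")
    if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  } else if (!is.null(alpha)) {
    stop(name, " does not take an alpha parameter")
  }
  label <- if (needs_alpha) sprintf("%s(%g)", name, alpha) else name
  structure(list(name = name, alpha = alpha, label = label,
                 tree_based = name %in% c("w_unifrac", "gw_unifrac",
                                          "uw_unifrac", "pw_unifrac"),
                 presence_based = name %in% c("jaccard", "uw_unifrac",
                                              "pw_unifrac")),
            class = "distance_spec")
}

#' The simulation-study distance set
#'
#' Weighted UniFrac, Bray-Curtis, presence-weighted UniFrac with alpha 1 and
#' 0, unweighted UniFrac and Jaccard: two abundance distances and four
#' presence-absence distances that together probe richness- and
#' evenness-driven community differences.
#'
#' @return A named list of six [distance_spec()] objects.
#' @export
default_distances <- function() {
  specs <- list(distance_spec("w_unifrac"), distance_spec("bray_curtis"),
                distance_spec("pw_unifrac", 1), distance_spec("pw_unifrac", 0),
                distance_spec("uw_unifrac"), distance_spec("jaccard"))
  names(specs) <- vapply(specs, `[[`, "", "label")
  specs
}

## ---- scalar pairwise forms (reference implementations / small inputs) ----

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum|p_j - p_k| / sum(p_j + p_k)`.
#'
#' @param p_j,p_k non-negative abundance vectors of equal length.
#' @return A dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(p_j, p_k) {
  stopifnot(length(p_j) == length(p_k))
  if (any(p_j < 0) || any(p_k < 0)) stop("abundances must be non-negative")
  den <- sum(p_j + p_k)
  if (den == 0) stop("Bray-Curtis undefined: both samples are empty")
  sum(abs(p_j - p_k)) / den
}

#' Jaccard dissimilarity between two presence vectors
#'
#' `n01 / (n01 + n11)` where `n01` counts species present in exactly one
#' sample and `n11` species present in both.
#'
#' @param a_j,a_k binary (0/1) vectors of equal length.
#' @return A dissimilarity in \[0, 1\].
#' @export
jaccard <- function(a_j, a_k) {
  stopifnot(length(a_j) == length(a_k))
  if (!all(a_j %in% c(0, 1)) || !all(a_k %in% c(0, 1)))
    stop("presence vectors must be binary")
  n11 <- sum(a_j == 1 & a_k == 1)
  n01 <- sum(a_j != a_k)
  if (n01 + n11 == 0) stop("Jaccard undefined: no species present in either sample")
  n01 / (n01 + n11)
}

profile_cols <- function(profile, j, k) {
  ids <- profile$sample_ids
  idx <- function(s) if (is.character(s)) match(s, ids) else s
  list(j = idx(j), k = idx(k))
}

#' Weighted UniFrac between two samples of a branch profile
#'
#' `sum_l b_l |p_jl - p_kl| / sum_l b_l (p_jl + p_kl)`.
#'
#' @param profile a [branch_profiles()] object.
#' @param j,k sample ids or indices.
#' @return A dissimilarity in \[0, 1\].
#' @export
weighted_unifrac <- function(profile, j, k) {
  s <- profile_cols(profile, j, k)
  b <- profile$branch_lengths
  pj <- profile$abundance[s$j, ]; pk <- profile$abundance[s$k, ]
  den <- sum(b * (pj + pk))
  if (den == 0) stop("weighted UniFrac undefined: no abundance on any branch")
  sum(b * abs(pj - pk)) / den
}

#' Generalized UniFrac between two samples of a branch profile
#'
#' `sum_l b_l (p_jl+p_kl)^alpha |(p_jl-p_kl)/(p_jl+p_kl)| /
#'  sum_l b_l (p_jl+p_kl)^alpha` over branches with positive combined
#' abundance; reduces to weighted UniFrac at `alpha = 1`.
#'
#' @inheritParams weighted_unifrac
#' @param alpha attenuation parameter in \[0, 1\].
#' @return A dissimilarity in \[0, 1\].
#' @export
generalized_unifrac <- function(profile, j, k, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  s <- profile_cols(profile, j, k)
  alpha_unifrac_pair(profile$abundance[s$j, ], profile$abundance[s$k, ],
                     profile$branch_lengths, alpha,
                     "generalized UniFrac undefined: no occupied branch")
}

#' Unweighted UniFrac between two samples of a branch profile
#'
#' `sum_l b_l |I(n_jl>0) - I(n_kl>0)| / sum_l b_l`; the denominator is the
#' total branch length of the tree, with no occupancy restriction.
#'
#' @inheritParams weighted_unifrac
#' @return A dissimilarity in \[0, 1\].
#' @export
unweighted_unifrac <- function(profile, j, k) {
  s <- profile_cols(profile, j, k)
  b <- profile$branch_lengths
  if (sum(b) == 0) stop("unweighted UniFrac undefined: zero total branch length")
  nj <- profile$richness[s$j, ] > 0
  nk <- profile$richness[s$k, ] > 0
  sum(b[nj != nk]) / sum(b)
}

#' Presence-weighted UniFrac between two samples of a branch profile
#'
#' Weights each branch by the relative richness difference
#' `|n_jl - n_kl| / (n_jl + n_kl)` instead of the presence indicator:
#' `sum_l b_l (n_jl+n_kl)^alpha |(n_jl-n_kl)/(n_jl+n_kl)| /
#'  sum_l b_l (n_jl+n_kl)^alpha` over branches holding at least one present
#' OTU.  Decreasing `alpha` attenuates high-richness branches and sharpens
#' sensitivity to richness change on moderately rich lineages.
#'
#' @inheritParams generalized_unifrac
#' @return A dissimilarity in \[0, 1\].
#' @export
presence_weighted_unifrac <- function(profile, j, k, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  s <- profile_cols(profile, j, k)
  alpha_unifrac_pair(profile$richness[s$j, ], profile$richness[s$k, ],
                     profile$branch_lengths, alpha,
                     "presence-weighted UniFrac undefined: no occupied branch")
}

# shared alpha-weighted form; zero-mass branches drop from both sums so that
# D(x, x) = 0 and the alpha = 1 reduction holds exactly
alpha_unifrac_pair <- function(vj, vk, b, alpha, err) {
  s <- vj + vk
  keep <- s > 0
  if (!any(keep)) stop(err)
  w <- b[keep] * s[keep]^alpha
  den <- sum(w)
  if (den == 0) stop(err)
  sum(w * abs(vj[keep] - vk[keep]) / s[keep]) / den
}

## ---- full matrices ----

#' Compute a pairwise distance matrix for one distance
#'
#' Applies the distance named by `spec` to every pair of samples.  Samples
#' with zero total counts are excluded with a warning (their distances are
#' undefined).  Tree-based distances require `tree`.
#'
#' @param table an [otu_table()] (or non-negative abundance matrix).
#' @param spec a [distance_spec()] or a name/`"name:alpha"` string.
#' @param tree an [ape::phylo] tree; required for UniFrac variants.
#' @param rarefy_depth optional depth; when given, presence-absence distances
#'   are computed from counts rarefied to this depth (abundance distances
#'   always use the unrarefied counts).
#' @param seed seed used only for rarefaction.
#' @param profile optional precomputed [branch_profiles()] (internal reuse).
#' @return A symmetric `dist_matrix` (matrix with zero diagonal, sample ids
#'   as dimnames, and the spec label in attribute `distance`).
#' @export
distance_matrix <- function(table, spec, tree = NULL, rarefy_depth = NULL,
                            seed = NULL, profile = NULL) {
  if (is.character(spec)) spec <- distance_spec(spec)
  mats <- distance_matrix_set(table, list(spec), tree = tree,
                              rarefy_depth = rarefy_depth, seed = seed,
                              profiles = if (is.null(profile)) NULL else
                                list(abund = profile, pres = profile))
  mats[[1]]
}

#' Compute several distance matrices from one table in a single pass
#'
#' Shares the branch-profile computation across all UniFrac variants, which
#' dominates cost in simulation loops.
#'
#' @inheritParams distance_matrix
#' @param specs list of [distance_spec()] objects (or strings).
#' @param profiles internal: precomputed list(abund=, pres=) branch profiles.
#' @return A named list of `dist_matrix` objects, one per spec.
#' @export
distance_matrix_set <- function(table, specs, tree = NULL, rarefy_depth = NULL,
                                seed = NULL, profiles = NULL) {
  specs <- lapply(specs, function(s) if (is.character(s)) distance_spec(s) else s)
  mat <- unclass(as.matrix(table))
  totals <- rowSums(mat)
  if (any(totals == 0)) {
    warning("excluding ", sum(totals == 0), " zero-total sample(s): ",
            paste(rownames(mat)[totals == 0], collapse = ", "))
    mat <- mat[totals > 0, , drop = FALSE]
  }
  if (nrow(mat) < 2L) stop("need at least two samples with positive totals")
  if (any(vapply(specs, `[[`, TRUE, "tree_based")) && is.null(tree) &&
      is.null(profiles))
    stop("a phylogenetic tree is required for UniFrac distances")

  pres_mat <- mat
  if (!is.null(rarefy_depth) &&
      any(vapply(specs, `[[`, TRUE, "presence_based"))) {
    pres_mat <- unclass(rarefy(otu_table(mat), rarefy_depth, seed = seed))
  }
  props <- to_proportions(mat)
  pres <- to_presence(pres_mat)

  need_abund_prof <- any(vapply(specs, function(s)
    s$name %in% c("w_unifrac", "gw_unifrac"), TRUE))
  need_pres_prof <- any(vapply(specs, function(s)
    s$name %in% c("uw_unifrac", "pw_unifrac"), TRUE))
  prof_a <- prof_p <- NULL
  if (is.null(profiles)) {
    if (need_abund_prof || need_pres_prof) {
      inc <- branch_incidence(tree)
      same_source <- identical(pres_mat, mat)
      if (need_abund_prof || same_source)
        prof_a <- branch_profiles(tree, props, to_presence(mat), incidence = inc)
      prof_p <- if (same_source) prof_a else
        branch_profiles(tree, to_proportions(pres_mat), pres, incidence = inc)
    }
  } else {
    prof_a <- profiles$abund
    prof_p <- profiles$pres
  }

  ids <- rownames(mat)
  out <- lapply(specs, function(s) {
    D <- switch(s$name,
      bray_curtis = cpp_pair_bray(t(unclass(props))),
      jaccard     = cpp_pair_jaccard(t(unclass(pres))),
      w_unifrac   = cpp_pair_wunifrac(t(prof_a$abundance), prof_a$branch_lengths),
      gw_unifrac  = cpp_pair_alpha_unifrac(t(prof_a$abundance),
                                           prof_a$branch_lengths, s$alpha),
      uw_unifrac  = cpp_pair_uwunifrac(t(prof_p$richness), prof_p$branch_lengths),
      pw_unifrac  = cpp_pair_alpha_unifrac(t(prof_p$richness),
                                           prof_p$branch_lengths, s$alpha))
    dimnames(D) <- list(ids, ids)
    structure(D, distance = s$label, class = c("dist_matrix", "matrix", "array"))
  })
  names(out) <- vapply(specs, `[[`, "", "label")
  out
}

#' Write a distance matrix as square TSV
#'
#' @param D a `dist_matrix`.
#' @param path output path.
#' @export
write_distance_matrix <- function(D, path) {
  df <- data.frame(sample_id = rownames(D),
                   as.data.frame(unclass(D), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square TSV distance matrix
#'
#' @param path path written by [write_distance_matrix()].
#' @return A `dist_matrix`.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  D <- as.matrix(df)
  validate_distance_matrix(D)
}

validate_distance_matrix <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix must have zero diagonal")
  structure(D, class = c("dist_matrix", "matrix", "array"))
}
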