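#' Dirichlet-multinomial community parameters
#'
#' @param proportions mean proportion vector `pi` (non-negative, sums to 1).
#' @param theta overdispersion in (0, 1); the Dirichlet concentration is
#'   `pi * (1 - theta) / theta`, so small `theta` approaches a plain
#'   multinomial and larger `theta` produces sparser, more variable
#'   communities.
#' @return An object of class `dm_params`.
#' @export
dm_params <- function(proportions, theta) {
  nm <- names(proportions)
  proportions <- as.numeric(proportions)
  names(proportions) <- nm
  if (any(proportions < 0)) stop("proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  if (length(theta) != 1L || theta <= 0 || theta >= 1)
    stop("theta must lie strictly between 0 and 1")
  structure(list(proportions = proportions, theta = theta),
            class = "dm_params")
}

#' Sample an OTU table from the Dirichlet-multinomial model
#'
#' Each sample draws community proportions `q ~ Dirichlet(pi (1-theta)/theta)`
#' and counts `~ Multinomial(depth, q)`.
#'
#' @param params a [dm_params()].
#' @param n number of samples.
#' @param depth reads per sample.
#' @param seed optional integer seed.
#' @return An [otu_table()] with samples `S1..Sn` and OTUs `OTU1..OTUm`.
#' @export
sample_dm <- function(params, n, depth, seed = NULL) {
  stopifnot(inherits(params, "dm_params"))
  if (depth < 1) stop("depth must be >= 1")
  m <- length(params$proportions)
  if (m < 2L) stop("need at least two OTUs")
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  counts <- rmultinom_dm(n, depth, params$proportions, params$theta)
  dimnames(counts) <- list(paste0("S", seq_len(n)), paste0("OTU", seq_len(m)))
  otu_table(counts)
}

# n x m DM counts; rows may use different proportion vectors via pi_matrix
rmultinom_dm <- function(n, depth, pi, theta, pi_matrix = NULL) {
  conc_scale <- (1 - theta) / theta
  m <- if (is.null(pi_matrix)) length(pi) else ncol(pi_matrix)
  out <- matrix(0, n, m)
  for (j in seq_len(n)) {
    a <- (if (is.null(pi_matrix)) pi else pi_matrix[j, ]) * conc_scale
    g <- stats::rgamma(m, shape = a)         # shape 0 -> exact 0 mass
    tot <- sum(g)
    if (tot == 0) { g <- a; tot <- sum(g) }  # pathological fallback
    out[j, ] <- stats::rmultinom(1, depth, g / tot)
  }
  out
}

#' Method-of-moments Dirichlet-multinomial estimator
#'
#' Fits `pi` and `theta` from a count table so simulations can mirror a real
#' community: `pi` from pooled proportions and `theta` from the average
#' moment-based overdispersion of per-OTU proportions.
#'
#' @param table an [otu_table()].
#' @return A [dm_params()].
#' @export
estimate_dm <- function(table) {
  mat <- unclass(as.matrix(table))
  depth <- rowSums(mat)
  keep <- depth > 0
  mat <- mat[keep, , drop = FALSE]; depth <- depth[keep]
  props <- mat / depth
  pi_hat <- colMeans(props)
  pi_hat <- pi_hat / sum(pi_hat)
  # Mosimann moment estimator pooled over OTUs with non-degenerate means
  v <- apply(props, 2, stats::var)
  p <- pi_hat
  use <- p > 1e-8 & p < 1 - 1e-8
  nbar <- mean(depth)
  # Var(prop) = p(1-p) (theta + (1-theta)/depth) under DM
  theta_i <- (v[use] / (p[use] * (1 - p[use])) - 1 / nbar) / (1 - 1 / nbar)
  theta <- min(max(mean(theta_i, na.rm = TRUE), 1e-6), 0.99)
  dm_params(pi_hat, theta)
}

#' Synthetic default community: proportions, dispersion and tree
#'
#' Builds a deterministic stand-in for the respiratory-tract community the
#' study design assumes: a random coalescent tree over `m` OTUs whose leaves
#' are partitioned into `k_lineages` lineages by PAM on the patristic
#' distances, lineage abundance shares fixed so the most common lineage
#' carries 19.7% of total abundance and the rarest 0.9%, and dispersion
#' theta = 0.01.  Lineage shares are assigned by decreasing lineage size and
#' spread over the member OTUs with a lognormal rank-abundance profile
#' (sdlog 1.2), giving the long right tail and the sporadic presences of
#' real 16S surveys at moderate sequencing depth.
#'
#' @param m total number of OTUs.
#' @param k_lineages number of lineages.
#' @param seed integer seed controlling the (reproducible) tree and profile.
#' @return A list with `params` ([dm_params()]), `tree` ([ape::phylo]),
#'   `partition` (the [pam_partition()]), `lineage_shares` (named by lineage
#'   id) and `lineage_of_otu` (PAM assignment per OTU).
#' @export
default_params <- function(m = 856, k_lineages = 20, seed = 42L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  tree <- ape::rcoal(m)
  tree$tip.label <- paste0("OTU", seq_len(m))
  pat <- patristic_matrix(tree)
  ord <- paste0("OTU", seq_len(m))
  part <- pam_partition(pat[ord, ord], k_lineages)
  lineage <- part$assignment
  sizes <- table(lineage)
  shares <- lineage_shares(k_lineages)
  # largest lineage gets the largest share
  share_of <- stats::setNames(shares[rank(-as.numeric(sizes),
                                          ties.method = "first")],
                              names(sizes))
  pi <- numeric(m)
  names(pi) <- ord
  for (g in names(sizes)) {
    members <- which(lineage == as.integer(g))
    w <- stats::rlnorm(length(members), meanlog = 0, sdlog = 1.2)
    pi[members] <- share_of[[g]] * w / sum(w)
  }
  pi <- pi / sum(pi)
  list(params = dm_params(pi, 0.01), tree = tree, partition = part,
       lineage_shares = stats::setNames(
         vapply(names(sizes), function(g)
           sum(pi[lineage == as.integer(g)]), 0), names(sizes)),
       lineage_of_otu = lineage)
}

# fixed decreasing abundance shares: max pinned at 0.197, min at 0.009,
# geometric interpolation in between; the interior is rescaled affinely
# above a floor slightly over the rare share so the pinned extremes stay
# the extremes after normalization
lineage_shares <- function(k) {
  if (k < 2L) return(1)
  hi <- 0.197; lo <- 0.009
  raw <- exp(seq(log(hi), log(lo), length.out = k))
  if (k > 2L) {
    u <- raw[-c(1, k)]
    floor_s <- 1.05 * lo
    s <- (1 - hi - lo - length(u) * floor_s) / sum(u - floor_s)
    interior <- floor_s + (u - floor_s) * s
    shares <- c(hi, interior, lo)
    # the exact pins are only attainable when enough lineages share the
    # interior mass (the k = 20 study design); otherwise keep the profile
    if (all(diff(shares) < 0)) return(shares)
  }
  raw / sum(raw)
}

#' Partition points into k lineages by Partitioning Around Medoids
#'
#' Classic PAM: greedy BUILD initialization followed by SWAP steps to a
#' local optimum of total within-cluster distance to medoids.
#'
#' @param dist symmetric dissimilarity matrix (e.g. [patristic_matrix()]).
#' @param k number of clusters (1 <= k <= n).
#' @param seed unused (PAM is deterministic); kept for interface symmetry.
#' @return A list of class `lineage_partition` with `medoids` (indices),
#'   `assignment` (cluster id per point, named), and `cost`.
#' @export
pam_partition <- function(dist, k, seed = NULL) {
  D <- as.matrix(dist)
  n <- nrow(D)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k cannot exceed the number of points")
  # BUILD
  medoids <- which.min(rowSums(D))[1]
  dnear <- D[, medoids]
  while (length(medoids) < k) {
    gain <- vapply(seq_len(n), function(h) {
      if (h %in% medoids) return(-Inf)
      sum(pmax(dnear - D[, h], 0))
    }, 0)
    medoids <- c(medoids, which.max(gain))
    dnear <- pmin(dnear, D[, medoids[length(medoids)]])
  }
  # SWAP
  repeat {
    Dm <- D[, medoids, drop = FALSE]
    near_idx <- max.col(-Dm, ties.method = "first")
    dnear <- Dm[cbind(seq_len(n), near_idx)]
    dsecond <- apply(Dm, 1, function(r) sort(r, partial = 2)[2])
    if (k == 1L) dsecond <- rep(Inf, n)
    best <- list(delta = -1e-12, r = NA, h = NA)
    for (h in seq_len(n)) {
      if (h %in% medoids) next
      dh <- D[, h]
      a <- pmin(dh - dnear, 0)                 # improvement for any removal
      b <- pmin(dh, dsecond) - dnear - a       # extra cost if own medoid leaves
      s_all <- sum(a)
      extra <- vapply(seq_len(k), function(r) sum(b[near_idx == r]), 0)
      T_rh <- s_all + extra                    # per removed medoid r
      r <- which.min(T_rh)
      if (T_rh[r] < best$delta) best <- list(delta = T_rh[r], r = r, h = h)
    }
    if (is.na(best$r)) break
    medoids[best$r] <- best$h
  }
  Dm <- D[, medoids, drop = FALSE]
  assignment <- max.col(-Dm, ties.method = "first")
  cost <- sum(Dm[cbind(seq_len(n), assignment)])
  nm <- rownames(D)
  if (!is.null(nm)) names(assignment) <- nm
  structure(list(medoids = medoids, assignment = assignment, cost = cost,
                 k = k), class = "lineage_partition")
}

#' Aggregate abundance share of each lineage
#'
#' @param params a [dm_params()].
#' @param assignment integer cluster id per OTU (as from [pam_partition()]).
#' @return Named numeric vector of lineage abundance shares (sums to 1).
#' @export
lineage_abundance_shares <- function(params, assignment) {
  shares <- tapply(params$proportions, assignment, sum)
  shares[order(-shares)]
}

#' Configuration of a between-group differentiation pattern
#'
#' Pattern `A` flips random absences to presences (count 1) in group 1 so
#' each target OTU's presence fraction grows by the factor `c` (richness
#' change); pattern `B` multiplies group-1 abundance at presences by
#' `(1/p_hat_i)^c` with `p_hat_i` the mean observed abundance in group 2
#' (evenness change); pattern `C` scales the group-1 DM proportion
#' parameters by `(1/p_i)^c` before sampling (balanced change).  The
#' identity values are `c = 1` (A) and `c = 0` (B, C).
#'
#' @param pattern `"A"`, `"B"` or `"C"`.
#' @param target `"common_lineage"`, `"rare_lineage"`, `"random_lineage"`, or
#'   `"random_otus"`.
#' @param effect the differentiation degree `c`.
#' @param n_random_otus number of OTUs drawn for `target = "random_otus"`.
#' @return An object of class `differentiation_config`.
#' @export
differentiation_config <- function(pattern = c("A", "B", "C"),
                                   target = c("common_lineage", "rare_lineage",
                                              "random_lineage", "random_otus"),
                                   effect, n_random_otus = 40L) {
  pattern <- match.arg(pattern)
  target <- match.arg(target)
  if (pattern == "A" && effect < 1)
    stop("pattern A only adds presences; effect c must be >= 1")
  if (pattern %in% c("B", "C") && effect < 0)
    stop("effect c must be >= 0")
  structure(list(pattern = pattern, target = target, effect = effect,
                 n_random_otus = as.integer(n_random_otus)),
            class = "differentiation_config")
}

# resolve the target OTU index set for a replicate
resolve_target <- function(config, world) {
  lineage <- world$lineage_of_otu
  shares <- tapply(world$params$proportions, lineage, sum)
  switch(config$target,
    common_lineage = which(lineage == as.integer(names(which.max(shares)))),
    rare_lineage   = which(lineage == as.integer(names(which.min(shares)))),
    random_lineage = which(lineage == sample(unique(lineage), 1)),
    random_otus    = sample(length(lineage), min(config$n_random_otus,
                                                 length(lineage))))
}

#' Apply a differentiation pattern to simulated data
#'
#' For patterns A and B the input is a sampled [otu_table()] plus a group
#' mask; the return value is the modified abundance table (pattern B yields
#' real-valued abundances whose rows are renormalized downstream by
#' [to_proportions()]).  For pattern C the input is a [dm_params()] and the
#' return value is the group-1 parameter set to sample from.
#'
#' @param data an [otu_table()] (patterns A, B) or [dm_params()] (pattern C).
#' @param config a [differentiation_config()].
#' @param target_otus integer indices of the OTUs carrying the signal.
#' @param group_mask logical vector (length n) marking group-1 samples
#'   (ignored for pattern C).
#' @return Modified table (A, B) or modified [dm_params()] (C).
#' @export
apply_pattern <- function(data, config, target_otus, group_mask = NULL) {
  c_eff <- config$effect
  if (config$pattern == "C") {
    stopifnot(inherits(data, "dm_params"))
    if (c_eff == 0) return(data)           # bit-exact identity
    pi <- data$proportions
    pi[target_otus] <- pi[target_otus] * (1 / pi[target_otus])^c_eff
    pi <- pi / sum(pi)
    return(dm_params(pi, data$theta))
  }
  mat <- unclass(as.matrix(data))
  if (is.null(group_mask) || length(group_mask) != nrow(mat))
    stop("patterns A and B need a logical group mask over samples")
  g1 <- which(group_mask)
  g2 <- which(!group_mask)
  if (config$pattern == "A") {
    for (i in target_otus) {
      present <- mat[g1, i] > 0
      n_present <- sum(present)
      want <- min(length(g1), round(c_eff * n_present))
      add <- want - n_present
      if (add > 0) {
        zeros <- g1[!present]
        flip <- zeros[sample.int(length(zeros), min(add, length(zeros)))]
        mat[flip, i] <- 1
      }
    }
    return(otu_table(mat))
  }
  # pattern B: boost presences in group 1 by (1/p_hat_i)^c
  props2 <- unclass(to_proportions(mat[g2, , drop = FALSE]))
  p_hat <- colMeans(props2)
  for (i in target_otus) {
    if (p_hat[i] <= 0) next                # no reference abundance: no boost
    boost <- (1 / p_hat[i])^c_eff
    mat[g1, i] <- mat[g1, i] * boost
  }
  structure(mat, class = c("otu_table", "matrix", "array"))
}

#' Simulate a confounder tied to the most common lineage
#'
#' Computes the per-sample abundance (total relative abundance) or richness
#' (number of present OTUs) of the most common lineage, standardizes it to
#' mean 0 / SD 1 across samples, draws `Z ~ Normal(statistic, 1)`, and
#' assigns each sample to group 1 with probability `expit(0.5 Z)`.
#'
#' @param table an [otu_table()].
#' @param lineage_of_otu integer lineage id per OTU.
#' @param kind `"abundance"` or `"richness"`.
#' @param seed optional integer seed.
#' @return A list with `z` (confounder vector) and `group` (0/1 labels).
#' @export
make_confounder <- function(table, lineage_of_otu,
                            kind = c("abundance", "richness"), seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  mat <- unclass(as.matrix(table))
  shares <- tapply(colSums(mat), lineage_of_otu, sum)
  common <- as.integer(names(which.max(shares)))
  cols <- which(lineage_of_otu == common)
  stat <- if (kind == "abundance") {
    rowSums(mat[, cols, drop = FALSE]) / rowSums(mat)
  } else {
    rowSums(mat[, cols, drop = FALSE] > 0)
  }
  if (stats::sd(stat) == 0) stop("zero-variance lineage statistic")
  stat <- (stat - mean(stat)) / stats::sd(stat)
  z <- stats::rnorm(length(stat), mean = stat, sd = 1)
  group <- stats::rbinom(length(z), 1, stats::plogis(0.5 * z))
  list(z = z, group = group)
}

#' Between-group change in richness and evenness
#'
#' Summarizes what a differentiation pattern did to the community: per-group
#' mean richness (number of present OTUs per sample) and mean Shannon
#' diversity, and the relative change of each between groups.
#'
#' @param table an [otu_table()] or abundance matrix.
#' @param group_mask logical vector marking group-1 samples.
#' @return A list with `richness` and `evenness` per group plus
#'   `richness_change` and `evenness_change` (relative, group 1 vs group 2).
#' @export
richness_evenness_summary <- function(table, group_mask) {
  mat <- unclass(as.matrix(table))
  if (!any(group_mask) || all(group_mask)) stop("both groups must be non-empty")
  props <- unclass(to_proportions(mat))
  shannon <- apply(props, 1, function(p) { p <- p[p > 0]; -sum(p * log(p)) })
  rich <- rowSums(mat > 0)
  r1 <- mean(rich[group_mask]); r2 <- mean(rich[!group_mask])
  e1 <- mean(shannon[group_mask]); e2 <- mean(shannon[!group_mask])
  list(richness = c(group1 = r1, group2 = r2),
       evenness = c(group1 = e1, group2 = e2),
       richness_change = (r1 - r2) / r2,
       evenness_change = (e1 - e2) / e2)
}
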