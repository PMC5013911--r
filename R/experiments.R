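#' Simulation world shared by the experiment harnesses
#'
#' Builds the synthetic community ([default_params()]), partitions its OTUs
#' into lineages by PAM on the patristic distances, and caches the tree
#' incidence used by every UniFrac computation.
#'
#' @param m,k_lineages,seed passed to [default_params()].
#' @return A list with `params`, `tree`, `incidence`, `partition` (from
#'   [pam_partition()]), `lineage_of_otu` (PAM assignment in OTU order) and
#'   `lineage_shares` (abundance share per PAM lineage).
#' @export
simulation_world <- function(m = 856, k_lineages = 20, seed = 42L) {
  base <- default_params(m = m, k_lineages = k_lineages, seed = seed)
  list(params = base$params, tree = base$tree,
       incidence = branch_incidence(base$tree),
       partition = base$partition,
       lineage_of_otu = base$lineage_of_otu,
       lineage_shares = base$lineage_shares)
}

# distance matrices for one simulated table against the cached world
world_distances <- function(counts_mat, world, specs) {
  props <- to_proportions(counts_mat)
  pres <- to_presence(counts_mat)
  prof <- branch_profiles(world$tree, props, pres, incidence = world$incidence)
  distance_matrix_set(counts_mat, specs,
                      profiles = list(abund = prof, pres = prof))
}

method_names <- function(specs) {
  c(vapply(specs, `[[`, "", "label"), "p_min_bonferroni", "unified")
}

# run the six single-distance tests + Bonferroni + unified on one dataset
# with a fixed permutation budget (no escalation: rejection at 0.05 only
# needs resolution well above 1/B)
run_all_methods <- function(D_list, x, z, B, seed) {
  spec <- test_spec(x, z = z, B = B, seed = seed)
  cfg <- unified_config(distances = lapply(names(D_list), distance_spec),
                        B_initial = B, B_max = B, tol = 0.5)
  res <- unified_test(D_list, spec, cfg)
  c(res$p_values, p_min_bonferroni = res$bonferroni_p, unified = res$p_value)
}

#' Type-I-error experiment
#'
#' Generates null communities (no differentiation pattern), assigns group
#' labels either by an even split (`scenario = "none"`) or through a
#' lineage-linked confounder, runs the six single-distance tests, the
#' Bonferroni comparator and the unified test on every replicate, and
#' reports the rejection fraction at the given level.
#'
#' @param scenario `"none"`, `"abundance"` or `"richness"` (confounder kind).
#' @param adjust adjust for the confounder Z (parametric bootstrap, since the
#'   group label is binary)?  Ignored when `scenario = "none"`.
#' @param n total sample size.
#' @param reps number of simulation replicates.
#' @param B permutations per test.
#' @param depth reads per sample.
#' @param level significance level.
#' @param seed master seed.
#' @param world optional precomputed [simulation_world()].
#' @return A list with `rejection` (named rate per method), `p_matrix`
#'   (reps x methods), and the settings.
#' @export
type1_experiment <- function(scenario = c("none", "abundance", "richness"),
                             adjust = TRUE, n = 20, reps = 2000, B = 1000,
                             depth = 1000, level = 0.05, seed = 1L,
                             world = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(world)) world <- simulation_world()
  specs <- default_distances()
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  pmat <- matrix(NA_real_, reps, length(specs) + 2,
                 dimnames = list(NULL, method_names(specs)))
  for (r in seq_len(reps)) {
    counts <- rmultinom_dm(n, depth, world$params$proportions,
                           world$params$theta)
    rownames(counts) <- paste0("S", seq_len(n))
    colnames(counts) <- paste0("OTU", seq_len(ncol(counts)))
    if (scenario == "none") {
      x <- rep(c(0, 1), length.out = n)
      z <- NULL
    } else {
      # redraw labels that are degenerate (one group empty) or, when
      # adjusting, perfectly separated by Z -- no adjustment is defined on
      # such a draw and a real analysis would have to exclude it too
      repeat {
        conf <- make_confounder(counts, world$lineage_of_otu, scenario)
        if (length(unique(conf$group)) < 2L) next
        if (adjust) {
          ok <- tryCatch({
            logistic_fit_columns(matrix(conf$group, n, 1),
                                 matrix(conf$z, ncol = 1), strict = TRUE)
            TRUE
          }, error = function(e) FALSE)
          if (!ok) next
        }
        break
      }
      x <- conf$group
      z <- if (adjust) matrix(conf$z, ncol = 1) else NULL
    }
    D_list <- world_distances(counts, world, specs)
    pmat[r, ] <- run_all_methods(D_list, x, z, B, rep_seeds[r])
  }
  list(rejection = colMeans(pmat < level), p_matrix = pmat,
       scenario = scenario, adjust = adjust, n = n, reps = reps, B = B,
       level = level, seed = seed)
}

#' Power experiment for one differentiation setting
#'
#' Applies a differentiation pattern between two even groups at each effect
#' size in `c_grid` and reports the rejection fraction per method.
#'
#' @param config a [differentiation_config()] (its `effect` is overridden by
#'   each grid value).
#' @param n total sample size (split evenly).
#' @param c_grid effect sizes to evaluate.
#' @param reps replicates per grid point.
#' @param B permutations per test.
#' @param depth reads per sample.
#' @param level significance level.
#' @param seed master seed.
#' @param world optional precomputed [simulation_world()].
#' @return A list with `power` (length(c_grid) x methods matrix) and
#'   settings.
#' @export
power_experiment <- function(config, n = 20, c_grid, reps = 500, B = 1000,
                             depth = 1000, level = 0.05, seed = 1L,
                             world = NULL) {
  stopifnot(inherits(config, "differentiation_config"))
  if (is.null(world)) world <- simulation_world()
  specs <- default_distances()
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  power <- matrix(NA_real_, length(c_grid), length(specs) + 2,
                  dimnames = list(as.character(c_grid), method_names(specs)))
  m <- length(world$params$proportions)
  otu_ids <- names(world$params$proportions)
  if (is.null(otu_ids)) otu_ids <- paste0("OTU", seq_len(m))
  group_mask <- rep(c(TRUE, FALSE), length.out = n)   # group 1 = TRUE
  x <- as.numeric(group_mask)
  for (ci in seq_along(c_grid)) {
    cfg <- config
    cfg$effect <- c_grid[ci]
    set.seed(seed + ci - 1L)
    rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
    hits <- matrix(NA_real_, reps, ncol(power))
    for (r in seq_len(reps)) {
      target <- resolve_target(cfg, world)
      if (cfg$pattern == "C") {
        params1 <- apply_pattern(world$params, cfg, target)
        counts <- matrix(0, n, m)
        counts[group_mask, ] <- rmultinom_dm(sum(group_mask), depth,
                                             params1$proportions,
                                             params1$theta)
        counts[!group_mask, ] <- rmultinom_dm(sum(!group_mask), depth,
                                              world$params$proportions,
                                              world$params$theta)
        rownames(counts) <- paste0("S", seq_len(n))
        colnames(counts) <- otu_ids
        table_mod <- counts
      } else {
        counts <- rmultinom_dm(n, depth, world$params$proportions,
                               world$params$theta)
        rownames(counts) <- paste0("S", seq_len(n))
        colnames(counts) <- otu_ids
        table_mod <- unclass(as.matrix(
          apply_pattern(otu_table(counts), cfg, target, group_mask)))
      }
      D_list <- world_distances(table_mod, world, specs)
      hits[r, ] <- run_all_methods(D_list, x, NULL, B, rep_seeds[r]) < level
    }
    power[ci, ] <- colMeans(hits)
  }
  list(power = power, config = config, n = n, c_grid = c_grid, reps = reps,
       B = B, level = level, seed = seed)
}
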