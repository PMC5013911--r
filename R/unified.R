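#' Configuration for the unified multi-distance test
#'
#' @param distances list of [distance_spec()] objects (or strings) naming the
#'   K distances to ensemble; defaults to the six-distance study set.
#' @param B_initial starting permutation count (>= 100).
#' @param tol accuracy parameter in (0, 1): the permutation count B is
#'   escalated (doubled) while `p_min < 1 / (tol * B)`, so a smaller `tol`
#'   demands finer resolution around small p-values.
#' @param B_max cap on the escalation; when reached the result is flagged
#'   `at_cap` and reported at the achieved resolution.
#' @param seed integer seed; `NULL` (default) defers to the seed of the
#'   [test_spec()] passed to [unified_test()].
#' @return An object of class `unified_config`.
#' @export
unified_config <- function(distances = default_distances(), B_initial = 500L,
                           tol = 0.1, B_max = 1e6, seed = NULL) {
  distances <- lapply(distances, function(s)
    if (is.character(s)) distance_spec(s) else s)
  if (length(distances) < 1L) stop("need at least one distance (K >= 1)")
  if (B_initial < 100L) stop("B_initial must be >= 100")
  if (tol <= 0 || tol >= 1) stop("tol must lie strictly between 0 and 1")
  if (B_max < B_initial) stop("B_max must be >= B_initial")
  structure(list(distances = distances, B_initial = as.integer(B_initial),
                 tol = tol, B_max = B_max,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "unified_config")
}

#' Permutation-budget escalation rule
#'
#' Doubles B while `p_min < 1 / (tol * B)` and the cap allows; returns the
#' input B unchanged (stop) once the criterion is met.
#'
#' @param current_B current permutation count.
#' @param p_min smallest per-distance p-value at the current B.
#' @param tol accuracy parameter in (0, 1).
#' @param B_max escalation cap.
#' @return The next B to use, or `current_B` when no escalation is needed or
#'   the cap is reached.
#' @export
escalate_B <- function(current_B, p_min, tol, B_max = 1e6) {
  if (p_min >= 1 / (tol * current_B)) return(current_B)
  min(B_max, 2 * current_B)
}

#' Bonferroni combination of per-distance p-values
#'
#' `min(1, K * min(p))`: the usual conservative comparator to the unified
#' min-P test.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return A single adjusted p-value.
#' @export
bonferroni_min_p <- function(p_values) {
  if (length(p_values) == 0) stop("empty p-value list")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  min(1, length(p_values) * min(p_values))
}

# permuted 'p-values' p_k(b) = (B - rank(F_k(b))) / B with max-rank ties:
# equals the strict-exceedance proportion #{b': F(b') > F(b)} / B
permuted_p_values <- function(F_perm) {
  B <- length(F_perm)
  (B - rank(F_perm, ties.method = "max")) / B
}

#' Unified multi-distance association test (min-P ensemble)
#'
#' Ensembles K distances by using the minimal per-distance p-value as the
#' test statistic, calibrated against a shared permutation null.  The
#' multistage procedure: (1) observed pseudo-F per distance; (2) B shared
#' permutations (one covariate draw per permutation reused across all K
#' distances) giving `F_k(b)`; (3) per-distance p-values; if
#' `p_min < 1/(tol B)` double B and redo; (4) permuted p-values
#' `p_k(b) = (B - rank(F_k(b)))/B`; (5) `p_min(b) = min_k p_k(b)`;
#' (6) the unified p-value is the proportion of `p_min(b)` strictly below
#' `p_min`.  The confounder-adjustment scheme of [permanova_test()]
#' (Freedman-Lane or parametric bootstrap) is applied inside each
#' permutation when `spec` declares confounders.
#'
#' @param D_list named list of distance matrices, all with identical sample
#'   ordering (e.g. from [distance_matrix_set()]).
#' @param spec a [test_spec()]; its `B` is ignored in favor of the config's
#'   escalation schedule.
#' @param config a [unified_config()]; its `distances` are only used for
#'   labels when `D_list` is unnamed.
#' @param max_f also run the maxF comparator on the same permutations.
#' @return A `unified_result` with per-distance `F` and `p`, `p_min`, the
#'   unified `p_value` (and add-one variant `p_value_add_one`), Bonferroni
#'   comparator, optional maxF p-value, `B_final`, and `at_cap` flag.
#' @export
unified_test <- function(D_list, spec, config = unified_config(),
                         max_f = FALSE) {
  if (length(D_list) < 1L) stop("need at least one distance matrix (K >= 1)")
  ids <- rownames(D_list[[1]])
  for (D in D_list)
    if (!identical(rownames(as.matrix(D)), ids))
      stop("all distance matrices must share sample ids and ordering")
  G_list <- lapply(D_list, gower_center)
  labels <- names(D_list)
  if (is.null(labels))
    labels <- vapply(config$distances, `[[`, "", "label")[seq_along(D_list)]
  if (!is.null(config$seed)) spec$seed <- config$seed

  B <- config$B_initial
  repeat {
    eng <- test_engine(G_list, spec, B = B)
    p_k <- vapply(seq_along(G_list), function(k)
      (1 + sum(eng$F_perm[[k]] >= eng$F_obs[1, k])) / (B + 1), 0)
    p_min <- min(p_k)
    newB <- escalate_B(B, p_min, config$tol, config$B_max)
    if (newB == B) { at_cap <- FALSE; break }
    if (newB >= config$B_max) {
      B <- config$B_max
      eng <- test_engine(G_list, spec, B = B)
      p_k <- vapply(seq_along(G_list), function(k)
        (1 + sum(eng$F_perm[[k]] >= eng$F_obs[1, k])) / (B + 1), 0)
      p_min <- min(p_k)
      at_cap <- p_min < 1 / (config$tol * B)
      break
    }
    B <- newB
  }

  pmat <- vapply(eng$F_perm, permuted_p_values, numeric(B))  # B x K
  p_min_b <- do.call(pmin, as.data.frame(pmat))
  count <- sum(p_min_b < p_min)
  res <- list(
    distances = labels,
    F_observed = stats::setNames(drop(eng$F_obs), labels),
    p_values = stats::setNames(p_k, labels),
    p_min = p_min,
    p_value = count / B,
    p_value_add_one = (1 + count) / (B + 1),
    bonferroni_p = bonferroni_min_p(p_k),
    B_final = B,
    at_cap = at_cap,
    seed = spec$seed
  )
  if (max_f) {
    F_obs_max <- max(eng$F_obs)
    F_perm_max <- do.call(pmax, eng$F_perm)
    res$max_f_p <- (1 + sum(F_perm_max >= F_obs_max)) / (B + 1)
  }
  structure(res, class = "unified_result")
}

#' @export
print.unified_result <- function(x, ...) {
  cat("Unified multi-distance association test\n")
  tab <- data.frame(distance = x$distances, F = x$F_observed, p = x$p_values)
  print(tab, row.names = FALSE, digits = 4)
  cat(sprintf("p_min = %.4g | unified p = %.4g | Bonferroni p = %.4g | B = %d%s\n",
              x$p_min, x$p_value, x$bonferroni_p, x$B_final,
              if (x$at_cap) " (escalation cap reached)" else ""))
  if (!is.null(x$max_f_p)) cat(sprintf("maxF p = %.4g\n", x$max_f_p))
  invisible(x)
}

#' maxF comparator test
#'
#' Uses `max_k F_k` as the statistic against the shared permutation null.
#' Valid only when the pseudo-F scales agree across distances; provided as a
#' comparator to the scale-free min-P unified test.
#'
#' @inheritParams unified_test
#' @param B permutation count.
#' @return A p-value (add-one convention).
#' @export
max_f_test <- function(D_list, spec, B = spec$B) {
  if (length(D_list) < 1L) stop("need at least one distance matrix")
  G_list <- lapply(D_list, gower_center)
  eng <- test_engine(G_list, spec, B = B)
  F_obs <- max(eng$F_obs)
  F_perm <- do.call(pmax, eng$F_perm)
  (1 + sum(F_perm >= F_obs)) / (B + 1)
}
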