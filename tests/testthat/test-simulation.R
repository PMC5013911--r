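test_that("dm_params validates and preserves names", {
  expect_error(dm_params(c(0.5, 0.6), 0.1), "sum to 1")
  expect_error(dm_params(c(0.5, 0.5), 0), "between 0 and 1")
  expect_error(dm_params(c(0.5, 0.5), 1), "between 0 and 1")
  p <- dm_params(c(a = 0.3, b = 0.7), 0.05)
  expect_equal(names(p$proportions), c("a", "b"))
})

test_that("sample_dm produces depth-constrained reproducible tables", {
  params <- dm_params(rep(0.2, 5), 0.05)
  tab <- sample_dm(params, n = 10, depth = 300, seed = 3)
  expect_true(all(rowSums(tab) == 300))
  expect_equal(dim(tab), c(10L, 5L))
  expect_identical(unclass(sample_dm(params, 10, 300, seed = 3)), unclass(tab))
})

test_that("DM at small theta approaches the plain multinomial", {
  # chi-square goodness of fit on pooled counts, theta -> 0 limit
  pi <- c(0.4, 0.3, 0.2, 0.08, 0.02)
  params <- dm_params(pi, 1e-6)
  tab <- sample_dm(params, n = 400, depth = 500, seed = 8)
  pooled <- colSums(tab)
  gof <- suppressWarnings(stats::chisq.test(pooled, p = pi))
  expect_gt(gof$p.value, 0.01)
})

test_that("DM mean proportions converge to pi and theta inflates the variance", {
  pi <- c(0.5, 0.3, 0.15, 0.05)
  params <- dm_params(pi, 0.05)
  tab <- sample_dm(params, n = 3000, depth = 200, seed = 21)
  props <- unclass(to_proportions(tab))
  se <- apply(props, 2, stats::sd) / sqrt(3000)
  expect_true(all(abs(colMeans(props) - pi) < 3 * se + 1e-3))
  # observed variance matches the DM law var = p(1-p)(theta + (1-theta)/depth)
  v_theory <- pi * (1 - pi) * (0.05 + 0.95 / 200)
  expect_equal(unname(apply(props, 2, stats::var)), v_theory, tolerance = 0.15)
  # and the moment estimator recovers the parameters roughly
  est <- estimate_dm(tab)
  expect_equal(est$proportions, colMeans(props), ignore_attr = TRUE,
               tolerance = 1e-6)
  expect_equal(est$theta, 0.05, tolerance = 0.3)
})

test_that("patristic distances match the hand-computed path sums", {
  tree <- three_leaf_tree()
  pat <- patristic_matrix(tree)
  expect_equal(pat["A", "B"], 2)
  expect_equal(pat["A", "C"], 3)
  expect_equal(pat["B", "C"], 3)
  expect_equal(unname(diag(pat)), rep(0, 3))
  # tree metric: triangle inequality on a random tree
  rt <- ape::rtree(12)
  p <- patristic_matrix(rt)
  for (i in 1:12) for (j in 1:12) for (k in 1:12)
    expect_lte(p[i, j], p[i, k] + p[k, j] + 1e-12)
})

test_that("pam_partition attains the exhaustive optimum on small inputs", {
  set.seed(14)
  # two well-separated planar clusters
  pts <- rbind(matrix(rnorm(12, 0, 0.3), 6, 2),
               matrix(rnorm(12, 5, 0.3), 6, 2))
  D <- as.matrix(dist(pts))
  part <- pam_partition(D, 2)
  expect_length(unique(part$assignment[1:6]), 1L)
  expect_true(all(part$assignment[1:6] == part$assignment[[1]]))
  expect_true(all(part$assignment[7:12] == part$assignment[7]))
  # brute-force optimum over all medoid pairs
  combos <- utils::combn(12, 2)
  costs <- apply(combos, 2, function(md)
    sum(pmin(D[, md[1]], D[, md[2]])))
  expect_equal(part$cost, min(costs), tolerance = 1e-12)
})

test_that("pam_partition handles degenerate k and relabeling equivariance", {
  set.seed(3)
  D <- as.matrix(dist(matrix(rnorm(14), 7, 2)))
  expect_error(pam_partition(D, 0), ">= 1")
  expect_error(pam_partition(D, 8), "exceed")
  all_self <- pam_partition(D, 7)
  expect_equal(all_self$cost, 0)
  # relabeling equivariance on unambiguous, well-separated clusters
  centers <- rbind(c(0, 0), c(6, 6), c(12, 0))
  pts <- centers[rep(1:3, each = 4), ] + matrix(rnorm(24, 0, 0.2), 12, 2)
  Dw <- as.matrix(dist(pts))
  part <- pam_partition(Dw, 3)
  perm <- sample(12)
  part_p <- pam_partition(Dw[perm, perm], 3)
  a <- part$assignment[perm]
  b <- part_p$assignment
  expect_equal(length(unique(paste(a, b))), 3L)
  expect_equal(part_p$cost, part$cost, tolerance = 1e-12)
})

test_that("default_params is deterministic and hits the lineage share targets", {
  w1 <- default_params(m = 200, k_lineages = 20, seed = 5)
  w2 <- default_params(m = 200, k_lineages = 20, seed = 5)
  expect_identical(w1$params$proportions, w2$params$proportions)
  expect_identical(ape::write.tree(w1$tree), ape::write.tree(w2$tree))
  expect_equal(sum(w1$params$proportions), 1, tolerance = 1e-12)
  sh <- sort(w1$lineage_shares, decreasing = TRUE)
  expect_gt(sh[1], 0.15); expect_lt(sh[1], 0.25)
  expect_equal(unname(min(sh)), 0.009, tolerance = 1e-9)
})

test_that("differentiation patterns are identity at their null effect", {
  world <- default_params(m = 60, k_lineages = 4, seed = 7)
  tab <- sample_dm(world$params, 10, 500, seed = 2)
  mask <- rep(c(TRUE, FALSE), 5)
  target <- which(world$lineage_of_otu == 1)

  cfgA <- differentiation_config("A", "common_lineage", 1)
  outA <- apply_pattern(tab, cfgA, target, mask)
  expect_identical(unclass(outA), unclass(tab))

  cfgB <- differentiation_config("B", "common_lineage", 0)
  outB <- apply_pattern(tab, cfgB, target, mask)
  expect_identical(unclass(outB), unclass(tab))

  cfgC <- differentiation_config("C", "common_lineage", 0)
  outC <- apply_pattern(world$params, cfgC, target)
  expect_identical(outC$proportions, world$params$proportions)

  expect_error(differentiation_config("A", "common_lineage", 0.5), ">= 1")
  expect_error(differentiation_config("B", "common_lineage", -1), ">= 0")
})

test_that("pattern A doubles per-OTU presence counts at c = 2", {
  m <- matrix(0, 10, 3,
              dimnames = list(paste0("g1_", 1:10), c("t1", "t2", "other")))
  m[1:2, "t1"] <- 5                      # present in 2 of 10 group-1 samples
  m[1:4, "t2"] <- 3                      # present in 4 of 10
  m[, "other"] <- 1
  mask <- rep(TRUE, 10)                  # all samples in group 1
  set.seed(31)
  out <- apply_pattern(otu_table(m), differentiation_config("A", "random_otus", 2),
                       target_otus = 1:2, group_mask = mask)
  expect_equal(sum(unclass(out)[, "t1"] > 0), 4)
  expect_equal(sum(unclass(out)[, "t2"] > 0), 8)
  # new presences enter with count exactly 1; old counts untouched
  expect_equal(sum(unclass(out)[, "t1"] == 5), 2)
  expect_equal(sum(unclass(out)[, "t1"] == 1), 2)
  # saturation: c large flips every zero
  out_sat <- apply_pattern(otu_table(m),
                           differentiation_config("A", "random_otus", 100),
                           target_otus = 1:2, group_mask = mask)
  expect_true(all(unclass(out_sat)[, 1:2] > 0))
})

test_that("pattern B multiplies only group-1 presences and pattern C rescales pi", {
  world <- default_params(m = 40, k_lineages = 4, seed = 9)
  tab <- sample_dm(world$params, 8, 400, seed = 4)
  mask <- rep(c(TRUE, FALSE), 4)
  target <- order(-world$params$proportions)[1:5]
  out <- apply_pattern(tab, differentiation_config("B", "random_otus", 0.3),
                       target, mask)
  mat0 <- unclass(tab); mat1 <- unclass(out)
  # group 2 untouched; group-1 zeros stay zero; group-1 presences scaled up
  expect_identical(mat1[!mask, ], mat0[!mask, ])
  expect_identical(mat1[mask, -target], mat0[mask, -target])
  expect_true(all(mat1[mask, target][mat0[mask, target] == 0] == 0))
  expect_true(all(mat1[mask, target] >= mat0[mask, target]))

  newp <- apply_pattern(world$params,
                        differentiation_config("C", "random_otus", 0.2), target)
  expect_equal(sum(newp$proportions), 1, tolerance = 1e-12)
  # boost is (1/pi)^c before renormalization: ratios on non-target OTUs equal
  r <- newp$proportions[-target] / world$params$proportions[-target]
  expect_lt(diff(range(r)), 1e-12)
  expect_true(all(newp$proportions[target] / world$params$proportions[target] >
                  r[1]))
})

test_that("make_confounder standardizes the lineage statistic and is seeded", {
  world <- default_params(m = 80, k_lineages = 5, seed = 11)
  tab <- sample_dm(world$params, 40, 800, seed = 6)
  for (kind in c("abundance", "richness")) {
    conf <- make_confounder(tab, world$lineage_of_otu, kind, seed = 13)
    conf2 <- make_confounder(tab, world$lineage_of_otu, kind, seed = 13)
    expect_identical(conf$group, conf2$group)
    expect_true(all(conf$group %in% c(0, 1)))
    expect_equal(length(conf$z), 40)
  }
  # group-1 fraction is near 1/2 by symmetry over many draws
  set.seed(17)
  fr <- replicate(300, mean(make_confounder(tab, world$lineage_of_otu,
                                            "abundance")$group))
  expect_lt(abs(mean(fr) - 0.5), 0.03)
})

test_that("richness/evenness summary separates the patterns as designed", {
  world <- default_params(m = 120, k_lineages = 6, seed = 13)
  tab <- sample_dm(world$params, 20, 1000, seed = 8)
  mask <- rep(c(TRUE, FALSE), 10)
  base <- richness_evenness_summary(tab, mask)

  # identical groups built by duplication: zero change
  dup <- unclass(tab)[c(1:5, 1:5), ]
  rownames(dup) <- paste0("r", 1:10)
  same <- richness_evenness_summary(dup, rep(c(TRUE, FALSE), each = 5))
  expect_equal(same$richness_change, 0)
  expect_equal(same$evenness_change, 0)

  set.seed(3)
  target <- seq_len(120)
  tabA <- apply_pattern(tab, differentiation_config("A", "random_otus", 3),
                        target, mask)
  sA <- richness_evenness_summary(tabA, mask)
  tabB <- apply_pattern(tab, differentiation_config("B", "random_otus", 0.4),
                        target, mask)
  sB <- richness_evenness_summary(tabB, mask)
  # A moves richness much more than B does; B leaves richness untouched
  expect_gt(sA$richness_change, 0.1)
  expect_equal(sB$richness_change, base$richness_change, tolerance = 1e-12)
  expect_gt(abs(sB$evenness_change - base$evenness_change), 1e-3)
})

test_that("experiment harnesses run end to end at toy scale", {
  world <- simulation_world(m = 60, k_lineages = 4, seed = 3)
  r <- type1_experiment(scenario = "none", n = 10, reps = 4, B = 120,
                        depth = 200, seed = 5, world = world)
  expect_true(all(r$p_matrix >= 0 & r$p_matrix <= 1))
  expect_equal(dim(r$p_matrix), c(4L, 8L))
  r2 <- type1_experiment(scenario = "abundance", adjust = TRUE, n = 10,
                         reps = 3, B = 120, depth = 200, seed = 6,
                         world = world)
  expect_true(all(is.finite(r2$p_matrix)))
  pw <- power_experiment(differentiation_config("C", "rare_lineage", 0.3),
                         n = 10, c_grid = 0.3, reps = 3, B = 120, depth = 200,
                         seed = 7, world = world)
  expect_true(all(pw$power >= 0 & pw$power <= 1))
  # reproducibility of the whole harness under a fixed seed
  r_rep <- type1_experiment(scenario = "none", n = 10, reps = 4, B = 120,
                            depth = 200, seed = 5, world = world)
  expect_identical(r$p_matrix, r_rep$p_matrix)
})
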