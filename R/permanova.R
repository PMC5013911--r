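#' Describe the association test to run
#'
#' Bundles the covariate of interest, optional confounders, optional strata
#' for restricted permutation, and the permutation budget.
#'
#' @param x covariate of interest, numeric vector of length n with no missing
#'   values.  Binary covariates must be coded 0/1.
#' @param type `"continuous"` or `"binary"`; `"auto"` treats a two-valued 0/1
#'   vector as binary.  The type selects the confounder-adjustment scheme:
#'   Freedman-Lane residual permutation (continuous) or logistic parametric
#'   bootstrap (binary).
#' @param z optional confounder matrix (n x q) or vector; an intercept is
#'   always appended internally.
#' @param strata optional factor of length n; permutations are restricted to
#'   shuffle labels within each stratum (paired/repeated designs).
#' @param B number of permutations.
#' @param seed integer seed governing all randomness in the test.
#' @return An object of class `test_spec`.
#' @export
test_spec <- function(x, type = c("auto", "continuous", "binary"), z = NULL,
                      strata = NULL, B = 999L, seed = 1L) {
  type <- match.arg(type)
  x <- as.numeric(x)
  if (anyNA(x)) stop("covariate x must have no missing values")
  vals <- sort(unique(x))
  if (type == "auto")
    type <- if (length(vals) == 2L && all(vals %in% c(0, 1))) "binary"
            else "continuous"
  if (type == "binary") {
    if (!all(x %in% c(0, 1)) || length(vals) != 2L)
      stop("binary covariate must take exactly the two values 0 and 1")
  } else if (length(vals) < 2L) stop("covariate x is constant")
  if (!is.null(z)) {
    z <- as.matrix(z)
    if (nrow(z) != length(x)) stop("z must have one row per sample")
    if (anyNA(z)) stop("confounders z must have no missing values")
  }
  if (!is.null(strata)) {
    strata <- as.factor(strata)
    if (length(strata) != length(x)) stop("strata must have length n")
    if (any(table(strata) < 2L)) stop("every stratum must contain >= 2 samples")
  }
  if (B < 1L) stop("B must be >= 1")
  structure(list(x = x, type = type, z = z, strata = strata,
                 B = as.integer(B), seed = as.integer(seed)),
            class = "test_spec")
}

#' Gower-center a squared distance matrix
#'
#' Computes `G = -1/2 (I - 11'/n) D^2 (I - 11'/n)` where `D^2` is the
#' element-wise square of `D`.  `G` is symmetric with zero row and column
#' sums; it plays the role of an inner-product (Gram) matrix in the pseudo-F
#' statistic.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @return The centered matrix `G`.
#' @export
gower_center <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop("D must be a symmetric square matrix")
  A <- -0.5 * D^2
  rm <- rowMeans(A)
  A - outer(rm, rep(1, ncol(A))) - outer(rep(1, nrow(A)), colMeans(A)) + mean(A)
}

# center x, within strata when given (the hat matrix of the permutation
# design); constants are annihilated by G's double centering anyway, but
# explicit centering conditions X'X and makes that identity concrete
center_x <- function(x, strata = NULL) {
  if (is.null(strata)) return(x - mean(x))
  stats::ave(x, strata, FUN = function(v) v - mean(v))
}

#' Pseudo-F statistic for a univariate covariate
#'
#' `F = tr(HGH) / tr((I-H)G(I-H))` with `H = x(x'x)^{-1}x'` built from the
#' centered covariate (or adjusted residual) and `G` the Gower-centered
#' squared distance matrix.  For univariate centered `x` this reduces to
#' `q / (tr(G) - q)` with `q = x'Gx / x'x`.
#'
#' @param D symmetric distance matrix (or a precomputed `G` via `gower = TRUE`).
#' @param x covariate or residual vector; must not be constant.
#' @param gower set `TRUE` when `D` is already Gower-centered.
#' @return The pseudo-F value; `+Inf` when the residual trace is zero and the
#'   hypothesis trace positive (perfect separation).
#' @export
pseudo_f <- function(D, x, gower = FALSE) {
  G <- if (gower) as.matrix(D) else gower_center(D)
  x <- center_x(as.numeric(x))
  xx <- sum(x^2)
  if (xx == 0) stop("covariate x is constant")
  q <- drop(crossprod(x, G %*% x)) / xx
  trG <- sum(diag(G))
  den <- trG - q
  if (abs(den) < 1e-12) {
    if (abs(q) < 1e-12) stop("degenerate distance matrix: both traces are zero")
    return(Inf)
  }
  if (den < 0)
    warning("negative residual trace (strongly non-Euclidean distances); ",
            "pseudo-F reported as the literal trace ratio")
  q / den
}

## ---- permutation machinery ----

# n x B matrix of permuted indices, restricted within strata when given
perm_index_matrix <- function(n, B, strata = NULL) {
  if (is.null(strata)) {
    return(vapply(seq_len(B), function(b) sample.int(n), integer(n)))
  }
  strata <- as.factor(strata)
  idx <- seq_len(n)
  out <- matrix(0L, n, B)
  groups <- split(idx, strata)
  for (b in seq_len(B)) {
    p <- idx
    for (g in groups) p[g] <- g[sample.int(length(g))]
    out[, b] <- p
  }
  out
}

# F statistics for many covariate columns against one G: columns of xmat are
# already centered/residualized; returns q/(trG - q) per column
f_stat_columns <- function(G, xmat, trG = sum(diag(G))) {
  q <- colSums(xmat * (G %*% xmat)) / colSums(xmat^2)
  den <- trG - q
  f <- q / den
  f[abs(den) < 1e-12 & abs(q) >= 1e-12] <- Inf
  f
}

# least-squares residual projector for [1, Z]
residual_projector <- function(z, n) {
  Zi <- cbind(`(intercept)` = 1, z)
  qrz <- qr(Zi)
  if (qrz$rank < ncol(Zi)) {
    dropped <- colnames(Zi)[qrz$pivot[(qrz$rank + 1):ncol(Zi)]]
    stop("confounder matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  Q <- qr.Q(qrz)
  diag(n) - tcrossprod(Q)
}

# vectorized logistic regression of each column of ymat on (1, z) by Newton's
# method; returns fitted probability matrix (n x B).  With strict = TRUE a
# (quasi-)separated fit is an error; otherwise the damped finite-iteration
# fit is accepted, mirroring what IRLS with a fixed iteration cap does for
# the occasional separated bootstrap redraw.
logistic_fit_columns <- function(ymat, z, maxit = 25L, tol = 1e-8,
                                 strict = FALSE) {
  n <- nrow(ymat); B <- ncol(ymat)
  Zi <- cbind(1, z)
  p <- ncol(Zi)
  if (p == 2L) {
    # closed-form 2x2 Newton solve, fully vectorized across columns
    zv <- Zi[, 2]
    beta0 <- rep(0, B); beta1 <- rep(0, B)
    for (it in seq_len(maxit)) {
      eta <- outer(rep(1, n), beta0) + outer(zv, beta1)
      mu <- stats::plogis(eta)
      w <- mu * (1 - mu)
      g0 <- colSums(ymat - mu); g1 <- colSums(zv * (ymat - mu))
      a <- colSums(w); bq <- colSums(zv * w); c2 <- colSums(zv^2 * w)
      det <- a * c2 - bq^2
      det[det < 1e-10] <- 1e-10
      d0 <- (c2 * g0 - bq * g1) / det
      d1 <- (a * g1 - bq * g0) / det
      # dampen huge steps (incipient separation)
      step <- pmax(abs(d0), abs(d1))
      damp <- ifelse(step > 10, 10 / step, 1)
      beta0 <- pmin(pmax(beta0 + damp * d0, -30), 30)
      beta1 <- pmin(pmax(beta1 + damp * d1, -30), 30)
      if (max(step) < tol) break
    }
    if (strict && (max(abs(beta0)) >= 30 || max(abs(beta1)) >= 30))
      stop("logistic regression did not converge (perfect separation?); ",
           "consider removing or coarsening confounders")
    return(stats::plogis(outer(rep(1, n), beta0) + outer(zv, beta1)))
  }
  # general case: per-column IRLS via glm.fit
  apply(ymat, 2, function(y) {
    fit <- suppressWarnings(stats::glm.fit(Zi, y, family = stats::binomial()))
    if (strict && (!fit$converged ||
                   any(abs(fit$coefficients) > 30, na.rm = TRUE)))
      stop("logistic regression did not converge (perfect separation?); ",
           "consider removing or coarsening confounders")
    fit$fitted.values
  })
}

# assemble a test result with both p-value conventions
finish_single_test <- function(F_obs, F_perm, method, B, seed) {
  exceed <- sum(F_perm >= F_obs)
  structure(list(
    F_observed = F_obs,
    permuted_F = F_perm,
    p_value = (1 + exceed) / (B + 1),
    p_value_literal = mean(F_perm > F_obs),
    B = B, method = method, seed = seed
  ), class = "permanova_test")
}

#' @export
print.permanova_test <- function(x, ...) {
  cat(sprintf("permanova_test (%s): F = %.4f, p = %.4g (B = %d)\n",
              x$method, x$F_observed, x$p_value, x$B))
  invisible(x)
}

#' Single-distance PERMANOVA permutation test
#'
#' Runs the appropriate test for the spec: plain label permutation when no
#' confounders are declared, Freedman-Lane residual permutation for a
#' continuous covariate with confounders, or logistic parametric bootstrap
#' for a binary covariate with confounders.  The reported `p_value` uses the
#' add-one convention `(1 + #\{F_b >= F_obs\}) / (B + 1)`; the literal strict
#' exceedance proportion is reported alongside as `p_value_literal`.
#'
#' @param D a distance matrix (samples matching `spec$x` order).
#' @param spec a [test_spec()].
#' @return A `permanova_test` with `F_observed`, `permuted_F`, `p_value`,
#'   `p_value_literal`, `B`.
#' @export
permanova_test <- function(D, spec) {
  stopifnot(inherits(spec, "test_spec"))
  if (is.null(spec$z)) unadjusted_test(D, spec)
  else if (spec$type == "continuous") freedman_lane_test(D, spec)
  else parametric_bootstrap_test(D, spec)
}

#' Unadjusted permutation test
#'
#' Permutes the covariate (within strata when given) and recomputes the
#' pseudo-F for each permutation.
#'
#' @inheritParams permanova_test
#' @return A `permanova_test`.
#' @export
unadjusted_test <- function(D, spec) {
  if (!is.null(spec$z)) stop("spec declares confounders; use permanova_test()")
  eng <- test_engine(list(gower_center(D)), spec)
  finish_single_test(eng$F_obs[1, ], eng$F_perm[[1]], "unadjusted permutation",
                     spec$B, spec$seed)
}

#' Freedman-Lane adjusted test for a continuous covariate
#'
#' Regresses X on the confounders (with intercept), permutes the residuals R
#' to R*, rebuilds `X* = Z ghat + R*`, re-residualizes X* on Z, and computes
#' the pseudo-F from the twice-residualized `R**`.  Because the fitted part
#' lies in the column span of Z, `R** = Q_Z R*` where `Q_Z` is the residual
#' projector -- the implementation uses this identity.
#'
#' @inheritParams permanova_test
#' @return A `permanova_test`.
#' @export
freedman_lane_test <- function(D, spec) {
  if (is.null(spec$z)) stop("Freedman-Lane requires confounders z")
  if (spec$type != "continuous") stop("Freedman-Lane applies to continuous x")
  eng <- test_engine(list(gower_center(D)), spec)
  finish_single_test(eng$F_obs[1, ], eng$F_perm[[1]], "Freedman-Lane",
                     spec$B, spec$seed)
}

#' Parametric-bootstrap adjusted test for a binary covariate
#'
#' Fits logistic regression of X on the confounders, takes residuals
#' `R = X - expit(Z ghat)`, and for each replicate redraws
#' `X* ~ Bernoulli(expit(Z ghat))`, refits the logistic model, and computes
#' the pseudo-F from `R** = X* - expit(Z ghat*)`.
#'
#' @inheritParams permanova_test
#' @return A `permanova_test`.
#' @export
parametric_bootstrap_test <- function(D, spec) {
  if (is.null(spec$z)) stop("parametric bootstrap requires confounders z")
  if (spec$type != "binary") stop("parametric bootstrap applies to binary x")
  eng <- test_engine(list(gower_center(D)), spec)
  finish_single_test(eng$F_obs[1, ], eng$F_perm[[1]], "parametric bootstrap",
                     spec$B, spec$seed)
}

# Shared engine: observed and permuted F for K Gower matrices under ONE set
# of permutation/bootstrap draws (the structural requirement of the unified
# min-P test).  Returns F_obs (K-vector as 1 x K? -> matrix[1,K]) and
# F_perm (list of K B-vectors).
test_engine <- function(G_list, spec, B = spec$B) {
  n <- length(spec$x)
  for (G in G_list) if (nrow(G) != n)
    stop("distance matrix dimension does not match covariate length")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  trG <- vapply(G_list, function(G) sum(diag(G)), 0)

  if (is.null(spec$z)) {
    x0 <- center_x(spec$x, spec$strata)
    if (sum(x0^2) == 0) stop("covariate x is constant (within strata)")
    perm <- perm_index_matrix(n, B, spec$strata)
    Xp <- matrix(x0[perm], n, B)
    Xobs <- x0
  } else if (spec$type == "continuous") {
    Qz <- residual_projector(spec$z, n)
    R <- drop(Qz %*% spec$x)
    if (sum(R^2) < 1e-12) stop("covariate x is collinear with confounders")
    perm <- perm_index_matrix(n, B, spec$strata)
    Xp <- Qz %*% matrix(R[perm], n, B)
    Xobs <- R
  } else {
    if (!is.null(spec$strata))
      warning("strata are ignored by the parametric bootstrap scheme")
    phat <- drop(logistic_fit_columns(matrix(spec$x, n, 1), spec$z,
                                      strict = TRUE))
    R <- spec$x - phat
    if (sum(R^2) < 1e-12) stop("degenerate logistic fit: zero residuals")
    Xstar <- matrix(stats::rbinom(n * B, 1, rep(phat, B)), n, B)
    # guard against degenerate redraws (all 0 / all 1)
    bad <- which(colSums(Xstar) %in% c(0L, n))
    tries <- 0L
    while (length(bad) && tries < 100L) {
      Xstar[, bad] <- stats::rbinom(n * length(bad), 1, rep(phat, length(bad)))
      bad <- which(colSums(Xstar) %in% c(0L, n))
      tries <- tries + 1L
    }
    if (length(bad)) stop("bootstrap keeps producing degenerate covariates; ",
                          "fitted probabilities are too extreme")
    phat_star <- logistic_fit_columns(Xstar, spec$z)
    Xp <- Xstar - phat_star
    Xobs <- R
  }
  Xobs <- Xobs - mean(Xobs)
  Xp <- sweep(Xp, 2, colMeans(Xp))
  F_obs <- vapply(seq_along(G_list), function(k)
    f_stat_columns(G_list[[k]], matrix(Xobs, n, 1), trG[k]), 0)
  F_perm <- lapply(seq_along(G_list), function(k)
    f_stat_columns(G_list[[k]], Xp, trG[k]))
  list(F_obs = matrix(F_obs, 1), F_perm = F_perm)
}
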