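---
title: "Distance-based microbiome association testing with permanovaS: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based microbiome association testing with permanovaS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Microbiome association studies ask whether community composition — an OTU
count table of n samples by m taxa, usually with n in the tens and m in the
hundreds or thousands — varies with a covariate of interest X (disease
status, treatment, a continuous exposure).  The workhorse is PERMANOVA: pick
a beta-diversity distance, form the n x n matrix D of pairwise
dissimilarities, and compare between-group to within-group dissimilarity
through a pseudo-F statistic whose null distribution is simulated by
permutation.  Two practical problems motivate this package:

1. **Confounding.**  Permuting raw labels is invalid when a variable Z is
   correlated with both X and the community; the classic test then rejects
   far too often.
2. **Distance choice.**  No single distance is powerful against every kind
   of compositional difference; picking the best-looking p-value after
   trying several distances is anti-conservative.

`permanovaS` addresses both: residual-based permutation schemes that
preserve the X–Z relationship under the null, and a min-P ensemble (the
"unified test") that combines any number of distances in one calibrated
test.

## The pseudo-F statistic

For a univariate covariate x (centered), let
`G = -1/2 (I - 11'/n) D^2 (I - 11'/n)` (Gower centering of the element-wise
squared distances) and `H = x(x'x)^{-1}x'`.  The statistic is

    F = tr(HGH) / tr((I-H)G(I-H)).

For univariate x this reduces to `q/(tr G - q)` with `q = x'Gx/x'x`, which
is what the implementation computes — it makes a permutation replicate a
single quadratic form instead of two matrix products.  Centering x is
mathematically redundant (double centering of G annihilates constants) but
conditions `x'x`; with strata, x is centered within each stratum.  For
strongly non-Euclidean distance matrices `tr((I-H)G(I-H))` can be negative;
the trace ratio is still reported, with a warning, rather than silently
truncated.

## Distances

Six distances are implemented, in two families.

*Abundance distances* (computed from relative abundances `p`):
Bray–Curtis `sum|p_j - p_k| / sum(p_j + p_k)`; weighted UniFrac
`sum_l b_l |p_jl - p_kl| / sum_l b_l (p_jl + p_kl)` over tree branches l
with length `b_l` and descendant abundance `p_jl`; generalized UniFrac with
attenuation `alpha` in [0, 1].

*Presence–absence distances* (computed from 0/1 indicators): Jaccard
`n01/(n01 + n11)`; unweighted UniFrac
`sum_l b_l |I(n_jl>0) - I(n_kl>0)| / sum_l b_l`; and presence-weighted
UniFrac

    D_PW(alpha) = sum_l b_l (n_jl + n_kl)^alpha |n_jl - n_kl|/(n_jl + n_kl)
                  / sum_l b_l (n_jl + n_kl)^alpha,

where `n_jl` is the number of present OTUs below branch l.  Presence-
weighted UniFrac replaces the all-or-nothing branch indicator of unweighted
UniFrac with the *relative richness difference*, so it responds to partial
richness shifts inside a lineage; `alpha` attenuates the contribution of
very rich branches (alpha = 0 weights all occupied branches equally).

Numerical conventions, chosen once and tested:

* Branches with zero combined mass (`p_jl + p_kl = 0`, or `n_jl + n_kl = 0`)
  are excluded from both numerator and denominator of the alpha-weighted
  forms.  With `alpha = 0`, `0^0 = 1` would otherwise inject weight from
  branches neither sample occupies, breaking both `D(x, x) = 0` and the
  identity `D_GW(1) = D_W`.
* The unweighted UniFrac denominator is the *total* branch length, with no
  occupancy restriction — the literal definition.  (Some implementations
  restrict to occupied branches; note the choice is immaterial to the test
  itself, since the pseudo-F is invariant to a constant rescaling of D.)
* The root has no incoming edge in the `phylo` encoding, so no root edge
  enters any sum; at the root all samples have identical mass, so it could
  only contribute to denominators, and excluding it keeps the UniFrac
  variants mutually consistent.
* Multifurcating trees are supported; nothing assumes a binary topology.
* Samples with zero total counts have undefined distances and are dropped
  with a warning rather than propagated as NaN.
* Following the guidance that abundance distances stabilize quickly with
  depth while presence–absence distances are depth-sensitive, the optional
  `rarefy_depth` argument rarefies counts (without replacement) *only* for
  the presence–absence distances; abundance distances always use the
  unrarefied table.

## Confounder adjustment

With confounders Z (an intercept is always appended), label permutation is
replaced by residual schemes:

* **Continuous X — Freedman–Lane.**  Regress X on Z, keep residuals R;
  build the observed F from R.  Each replicate permutes R to R*, forms
  `X* = Z ghat + R*`, re-residualizes X* on Z and builds F from the result.
  Because the fitted part lies in span(Z), the twice-residualized vector is
  just `Q_Z R*` with `Q_Z` the residual projector — the implementation uses
  this identity, making a replicate one projection.
* **Binary X — parametric bootstrap.**  Fit logistic regression of X on Z,
  keep `R = X - expit(Z ghat)`; each replicate redraws
  `X* ~ Bernoulli(expit(Z ghat))`, refits, and uses `R** = X* - expit(Z ghat*)`.
  The per-replicate refits use a damped Newton iteration vectorized across
  all replicates.  A (quasi-)separated *observed* fit is an error (the
  adjustment is meaningless there); a separated *bootstrap redraw* — which
  occurs with non-trivial probability at n = 20 — is accepted at the damped
  finite-iteration fit, exactly as a capped IRLS would behave, and
  contributes one replicate to the null sample.  Degenerate redraws (all 0
  or all 1) are redrawn.

Permutations are restricted within strata when a stratum factor is given
(paired designs); when both strata and Freedman–Lane adjustment are
requested, residuals are permuted within strata — the natural composition
of the two schemes, flagged here because it is an extension rather than a
published recipe.  Strata are ignored by the parametric bootstrap (the
model-based redraw already conditions on Z); a warning says so.

**P-value convention.**  The add-one estimate
`(1 + #{F_b >= F_obs})/(B + 1)` is reported as `p_value` (never exactly
zero, valid at any B, ties counted as exceedances); the literal strict
proportion `#{F_b > F_obs}/B` is reported alongside as `p_value_literal`.

## The unified (min-P) test

K distances are ensembled by using the *smallest* per-distance p-value as
the statistic, calibrated against the same permutations:

1. observed `F_k` per distance;
2. B shared permutation (or bootstrap) draws — one covariate draw per
   replicate reused across all K distances, which is what makes the min-P
   null correlation structure right; this is enforced structurally, the
   engine generates the permuted covariate once per replicate;
3. per-distance p-values; while `p_min < 1/(tol x B)`, B is doubled
   (defaults: `B_initial = 500`, `tol = 0.1`, cap `B_max = 1e6`; the cap is
   reported via an `at_cap` flag rather than an error);
4. permuted "p-values" `p_k(b) = (B - rank(F_k(b)))/B` with ties assigned
   the maximum rank, making `p_k(b)` exactly the strict-exceedance
   proportion `#{b': F_k(b') > F_k(b)}/B` (tie handling is not part of the
   published recipe; this choice matches the brute-force count and is
   verified against it in the tests);
5. `p_min(b) = min_k p_k(b)`;
6. unified p = proportion of `p_min(b)` strictly below `p_min` (an add-one
   variant is reported alongside).

The unified p-value can never undercut `p_min`, which is asserted
per run in the test suite.  Two comparators are provided: Bonferroni
`min(1, K p_min)` (conservative, ignores the correlation between
distances) and maxF (`max_k F_k` as statistic), which is only calibrated
when the F scales agree across distances — the min-P construction is
scale-free, and the tests demonstrate invariance of the unified p to
rescaling any D.

## The synthetic community and what the simulations establish

The published benchmark community was fit to a real respiratory-tract
dataset whose Dirichlet-multinomial parameter estimates are not printed
anywhere reproducible, so this package ships a deterministic synthetic
stand-in (`default_params()` / `simulation_world()`), plus a
method-of-moments estimator (`estimate_dm()`) for users who want to mirror
their own data instead.  The stand-in states this world:

* m = 856 OTUs on a random coalescent tree (fixed seed), partitioned into
  k = 20 lineages by PAM (classic BUILD + SWAP, implemented in-package) on
  patristic distances;
* lineage abundance shares fixed so the most common lineage carries 19.7%
  and the rarest 0.9% of total abundance (the two printed anchors), with a
  geometric profile between, assigned to lineages by decreasing size;
* within a lineage, OTU proportions follow a lognormal rank-abundance
  profile (sdlog 1.2), giving ~170 observed OTUs per sample at depth 1000 —
  the long tail and sporadic presences of real 16S surveys;
* Dirichlet-multinomial dispersion theta = 0.01 and sequencing depth 1000
  reads/sample, n = 20 or 50 split evenly unless a confounder assigns
  groups.

Confounder scenarios standardize the most common lineage's per-sample
abundance (or richness) to mean 0/SD 1, draw `Z ~ Normal(statistic, 1)`
(the variance around the mean is unstated in the source recipe; unit noise
is this package's choice) and assign group 1 with probability
`expit(0.5 Z)`.

Differentiation patterns, applied to a target OTU set (common lineage, rare
lineage, a lineage re-drawn per replicate, or 40 random OTUs re-drawn per
replicate):

* **A (richness)** — flips randomly chosen zero cells of group 1 to count 1
  until each target OTU's presence fraction grows by the factor c (rounded
  to the nearest achievable count; saturates at 100% presence).  Identity
  at c = 1.
* **B (evenness)** — multiplies group-1 abundance at presences by
  `(1/p_hat_i)^c`, `p_hat_i` the mean observed proportion in group 2
  including zeros.  Identity at c = 0; presences are untouched, so richness
  is exactly preserved.
* **C (balanced)** — scales the group-1 DM proportion parameters by
  `(1/p_i)^c` before sampling.  Identity at c = 0.

Proportions are renormalized after each pattern.  Effect grids were chosen
so the power curves traverse the informative range (from the 0.05 floor
toward 1) in this world: c in {1..5} for A and {0..0.4} for B and C, with
mid-grid points 3 and 0.2 used in the acceptance checks.

**What a green test establishes, and what it does not.**  Type-I error is a
property of the permutation machinery, not of the community parameters, so
the level checks (unified rejection ~0.05 with and without adjustment,
Bonferroni conservativeness) transfer directly to real data.  Power
*orderings* (presence–absence distances dominate under richness change,
abundance distances under evenness change, unweighted/presence-weighted
UniFrac lead when a rare lineage differentiates) reproduce the published
qualitative structure, but absolute power values depend on the unprinted
parameters of the original community and on the effect grids; they are
qualitative benchmarks, not reproductions.  The generator also does not
emulate real-data features such as taxonomic structure in the tree,
depth variation across samples, or zero-inflation beyond what the DM model
produces.

## Scale and runtime choices

The published study used 10,000 type-I replicates and 2,000 power
replicates per grid point.  The acceptance tests run 2,000 and 500 with
B = 1000 (tolerances widened to 3 Monte-Carlo standard errors
accordingly), and `scripts/acceptance.R` reports 1,000-replicate versions;
both finish in minutes on one CPU.  Experiment harnesses fix B rather than
using the escalation schedule: rejection at level 0.05 only requires
p-value resolution well above 1/B, and escalation on strong-signal
replicates would spend permutations where the decision is already made.

## Known limitations

* X must be univariate; sequential (multi-term) decompositions as in
  `vegan::adonis2` are out of scope by design.
* The parametric bootstrap assumes the logistic model of X on Z is
  adequate; with n = 20 and several confounders, separation becomes likely
  and the test will refuse to run.
* HDF5 BIOM tables are not read (dense JSON only); convert externally.
* `estimate_dm()` is a moment estimator — adequate for simulation
  mirroring, not a substitute for maximum likelihood DM fitting.
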