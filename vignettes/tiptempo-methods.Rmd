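---
title: "Tip-based tempo metrics on stochastic character maps: models, conventions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tip-based tempo metrics on stochastic character maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package answers

Rates of discrete-trait evolution are usually summarized per clade or per
tree. `tiptempo` instead attaches the tempo of trait evolution to each
*living species*, so that evolutionary speed can be mapped in geographic
space through the assemblages species belong to. Three per-species metrics
are computed on complete character histories (stochastic maps) of a
k-state trait on dated phylogenies:

* **Transition rate, TR = t / N.** `N` is the number of nodes on the
  species' root-to-tip path (root included, tip excluded) and `t` the number
  of state changes over the `N` parent-child comparisons along that path,
  the final comparison being last-internal-node versus tip. TR is 0 when
  tip and all ancestors share one state and exactly 1 when every comparison
  changed state. Within-branch excursions that revert before the next node
  are *not* counted in `t`.
* **Stasis time, ST (Ma).** The longest contiguous stretch of time the
  lineage spent in the state its tip currently shows, anywhere along its
  root-to-tip history. Runs are built from within-branch dwell segments and
  merged across node boundaries when the state does not change; a brief
  within-branch excursion truncates a run, so ST is sensitive to events that
  TR ignores.
* **Last transition time, LT (Ma).** The length of the terminal run in the
  tip state: how long ago the lineage last entered its current state. A
  never-changing lineage has LT = ST = its full depth.

ST and LT are *not* ordered in general: a lineage may have had a long
ancient stay in its current state, left it, and returned recently, giving
ST > LT. The package therefore never asserts LT ≥ ST. Likewise ST is
restricted to the species' own root-to-tip history, not the whole tree; the
maximal-run reading (rather than a maximum over raw parent-child branch
lengths) is the default because only it responds to within-branch events.
Both conventions are switchable: `stasis_time(mode = "branchwise")` and
`extract_lineage(count_tip_node = TRUE)`.

## Producing the histories

Histories are drawn by stochastic character mapping under an Mk model:

1. **Model fit.** `fit_mk()` maximizes the pruning likelihood over ER, SYM
   or ARD generators, on the log-rate scale with dispersed deterministic
   restarts (ARD surfaces can be multimodal). The search is confined to
   rates in `[1e-6, 100]` times the characteristic rate `1/tree depth`:
   beyond roughly a hundred expected changes per lineage the likelihood is
   flat in the rate (saturation), so the cap costs nothing statistically
   while keeping the fitted generator usable downstream. SYM vs ARD is
   decided by AIC (`compare_models()`), ties going to the smaller model.
2. **Root prior.** Default is the stationary distribution of the fitted
   generator (uniform for ER/SYM); a flat prior is available. The choice is
   recorded in the fit object.
3. **Node states.** `sample_node_states()` draws all internal states
   jointly: pruning partials upward, then a root draw and conditional
   preorder draws.
4. **Branch paths.** `sample_branch_history()` draws the endpoint-
   conditioned CTMC path on each branch: forward rejection sampling first
   (exact and cheap at low rates), capped at 10,000 attempts, with an exact
   uniformization sampler as fallback. When the expected event count on a
   branch exceeds 15 the sampler goes straight to uniformization; rejection
   would be slower with no benefit. Zero-length branches carry a single
   zero-duration segment and cannot change state.

`simulate_maps()` refits the generator on every phylogeny of the set
(topologies and branch lengths differ across trees) and spawns one RNG
substream per (tree, simulation) cell from the master seed, so any subset of
the ensemble reproduces in isolation.

The estimate cube (`compute_cube()`) evaluates the three metrics for every
species on every map, in long form `species x tree x simulation`; in the
study design this is 100 trees x 100 simulations = 10,000 estimates per
species.

## Diet states

Percentage diet compositions map to four states: insectivore, plant-eater,
fruit/seed-eater (each requiring >= 50% of its category with the other two
below 50%) and generalist (everything else). Two categories tied at exactly
50% fall to generalist - the residual class; the data source does not
guarantee percentages sum to 100, so no renormalization is applied. Missing
compositions are imputed by an iterative random-forest scheme over the
percentage columns only (deliberately no phylogenetic predictors, so the
imputation cannot manufacture phylogenetic signal), stopping when the change
in imputed values rises or after 10 iterations; imputed cells are clipped to
[0, 100] and observed cells are never modified.

## The spatial design

All geometry runs in a Lambert cylindrical equal-area projection centered on
(15 S, 56 W). The design parameters default to the study's values: grid
cells of 26.4 km width (the "~0.25-degree" raster; the stated ~26 km² cell
area is internally inconsistent with a 0.25-degree cell, so the package
standardizes on the width consistent with the 13.2 km half-cell buffer and
exposes it as a parameter), 10 ecotone points (closest to the ecoregion
boundary) and 10 core points (farthest) per ecoregion, a 13.2 km composition
buffer, and a 4.16 square-degree small-range threshold (strict `<`).
Boundary distances are exact planar distances to the polygon boundary.
Distance ties at the k-th rank break by ascending point id; the two classes
are disjoint by construction. Species present at both a core and an ecotone
point of the same ecoregion are removed from that ecoregion (exclusivity
filter, idempotent). Moran's I uses inverse-distance, row-standardized
weights with a permutation p-value; the weighting is configurable because
the original analysis does not state one.

Assemblage metrics (aTR/aST/aLT) are unweighted means over the species
present at a point, per estimate; per-point means and sample SDs across
estimates (n-1 denominator) quantify phylogenetic/mapping uncertainty. The
within/between-phylogeny randomization draws, per iteration, 10 simulations
of one tree and one shared simulation index across 10 distinct trees, takes
the SD of each pooled set per point, averages over points, and reports the
proportion of iterations with the within-tree SD lower. The original text
does not state at which level the pooled SD is taken; per-point-then-average
is the reading implemented, and the alternative "independent simulation per
tree" draw is available behind `between_mode`. Faith's PD is root-inclusive
(a single-species assemblage on an ultrametric tree of height H has PD = H),
because the spanning-subtree definition is ambiguous for singletons.

## The synthetic-data generator

The generator exists so the whole pipeline is testable without external
downloads. It emulates:

* dated ultrametric trees from a sequential-waits birth-death simulator
  conditioned on the tip count (for pure birth the expected root age is
  `sum_{k=2..n} 1/(bk)`, which the tests check analytically). With
  extinction the same forward scheme retries on total extinction; the
  final-waiting-time stopping rule slightly overshoots strict conditioning
  on n tips at the present, a bias accepted and irrelevant to the pure-birth
  defaults;
* tree sets sharing a tip set, with a log-normal per-tree depth scaling
  (`jitter`) controlling between-phylogeny variance. Scenario tree sets
  share one topology by default: a posterior tree sample has correlated
  topologies, and fully independent topologies make per-species histories
  unidentifiable (each tree re-assigns every species new neighbours), which
  no real analysis would tolerate;
* a 4-state trait evolved forward under a symmetric generator (ground-truth
  histories are kept, so mapping and metrics can be checked against truth);
* rectangular ecoregion landscapes with checkerboard/random/block habitat
  labels, westernmost column flagged as the Andes stand-in and easternmost
  as the Atlantic-Rainforest stand-in, rook adjacency derived from shared
  boundaries;
* disc-shaped species ranges with log-normal (right-skewed) areas and a
  per-species core/ecotone placement affinity in [-1, 1].

A planted effect couples placement to the species' *terminal* transition
activity (a state change fixed at the final node-to-tip comparison of the
true history): with positive `planted_bias`, recently-transitioning species
receive ecotone-ward ranges. Terminal changes are used deliberately - deep
transitions are shared by whole clades (few effectively independent units)
and are poorly identified from tip data, while terminal changes are both
species-specific and the best-identified part of a lineage's history. The
null scenario (`planted_bias = 0`) places ranges independently of the trait.

What the generator does *not* emulate: real ecoregion geometry, realistic
range shapes, phylogenetic niche conservatism in range placement, spatial
autocorrelation of habitat, or the actual sigmodontine tree shape. Passing
tests therefore demonstrate correctness of the machinery and recoverability
of planted signals under controlled conditions - not that any empirical
dataset will show such signals.

## Problem sizes used by the test-suite and acceptance script

The suite exercises the study's full design counts where counting is the
point (93 ecoregions x 20 points = 1,860; 100 trees x 100 simulations =
10,000 estimates on a 6-tip tree; 2,000-estimate subsample) and reduced
dimensions elsewhere, chosen as the smallest sizes at which the checked
statistical properties are stable: metric-oracle equivalence on 1,000
simulated maps of 10-30 tips; node-state posteriors on 100 random 3-tip
cases at 20,000 draws each; conditioned-path event counts at 50,000 draws;
ER rate recovery on a 200-tip tree (50 replicates) and SYM/ARD selection on
a 150-tip tree (20 replicates); end-to-end null and planted scenarios at 80
species, 10 trees x 10 simulations, a 4 x 5 landscape of 200-km ecoregions
and k = 10 (50 replicates each). The acceptance script runs a 60-species,
10 x 10 scenario plus the full-scale design counts.

## Numerical choices

* Transition probabilities via eigendecomposition of the generator, with a
  scaled-and-squared Taylor fallback for defective matrices; pruning rescales
  partials to avoid underflow.
* Optimizer: Brent on the bounded log-rate interval for one-parameter
  models (a single pass - Brent is deterministic), Nelder-Mead with >= 5
  dispersed starts otherwise; convergence tolerance 1e-8 on the
  log-likelihood, configurable.
* Degenerate inputs are errors, not warnings: a single observed state
  (rates unidentifiable), impossible endpoint pairs on zero-length branches,
  empty assemblages in summaries that need an SD.
* All Monte-Carlo behavior is seed-deterministic; ensemble seeds are spawned
  once from the master seed.

## Known limitations

* The Mk machinery targets small state counts (k <= ~6); no hidden-rate or
  covarion models.
* Mapping uses empirical-Bayes fixed Q per tree (the standard simmap
  convention), not MCMC over Q, so mapping uncertainty is conditional on
  the fitted rates.
* The geometry layer is planar and exact only for simple polygons; it is
  not a substitute for a full GIS stack on real shapefiles, though GeoJSON-
  derived polygons in the projected plane work through the same interfaces.
* Mixed-model fitting on the exported assemblage tables (the regression
  stage of the original analysis) is intentionally out of scope; the
  package produces the model-ready tables instead.
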