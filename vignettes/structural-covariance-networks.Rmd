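---
title: "Structural covariance network analysis with covnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance network analysis with covnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covnet)
```

## The model

A structural covariance network (SCN) is a *group-level* graph over brain
regions: the nodes are the parcels of an atlas, and an edge weight is the
Pearson correlation, across the subjects of one group, of a regional
morphometric measure (cortical thickness in mm or structure volume in
mm³). Regions whose sizes co-vary across people are assumed to be
anatomically or developmentally coupled, so the topology of this
correlation graph is read as a summary of coordinated brain organisation.
There is one network per group — individual subjects do not have networks
in this framework, which is what makes inference non-standard (see
*Permutation inference* below).

The pipeline implemented here is:

1. **Residualization.** For every region, ordinary least squares removes
   the linear effects of age (years) and intracranial volume (mm³) —
   head size and ageing otherwise induce strong positive correlations
   everywhere. Residuals keep the units of the input measure.
2. **Covariance matrix.** Pearson correlations between all region pairs of
   one group's residuals; *negative correlations are set to zero* (only
   positive covariance defines edges) and the diagonal is zero.
3. **Sparsity thresholding.** For each sparsity value *s* in a grid
   (default 0.05–0.40 in steps of 0.01, 36 values), the
   `round(s · N(N−1)/2)` strongest edges are kept as an unweighted,
   undirected graph. Thresholding by sparsity rather than by a fixed
   correlation equalizes edge counts between the groups being compared.
4. **Graph properties.** At every threshold: clustering coefficient Cp,
   characteristic path length Lp, global efficiency, and per-node degree,
   betweenness, nodal and local efficiency. Cp and Lp are also normalized
   by their means over degree-preserving rewired null networks, giving
   γ = Cp/Cp_rand, λ = Lp/Lp_rand and the small-world index σ = γ/λ.
5. **AUC summary.** Each property's curve over the grid is reduced to its
   trapezoidal area under the curve (AUC), the threshold-free statistic
   that is actually tested.
6. **Permutation inference.** Group labels are shuffled (unpaired design)
   or scan labels are swapped within subject pairs (paired design), the
   whole pipeline is recomputed per relabeling, and two-tailed p-values
   come from the permutation distribution of AUC differences.
   Benjamini–Hochberg FDR is applied per nodal property across nodes.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| sparsity grid | 0.05–0.40, step 0.01 | fraction of possible edges kept; range chosen so that >90% of thresholds yield σ > 1.1 on well-conditioned data |
| `n_null` | 1000 | rewired null networks per threshold for reported γ/λ/σ curves |
| `n_null_inner` | 100 | null networks inside each permutation replicate (see *Numerical choices*) |
| `n_perm` | 5000 | permutation replicates; the attainable p-value floor is 1/(n_perm+1) ≈ 0.0002 |
| `n_swap_per_edge` | 10 | attempted Maslov–Sneppen swaps per edge, a standard mixing heuristic |
| `alpha`, `q` | 0.05, 0.05 | significance level and FDR level |
| backbone `alpha` | 0.001 | per-edge correlation t-test level for the group-average connection backbone |

## Conventions and numerical choices

* **Binary graphs.** Thresholded networks are unweighted; weighted
  variants are out of scope. This is the standard formulation for
  sparsity-grid/AUC small-world analyses.
* **Edge-count rounding** is round-half-up of `s·N(N−1)/2`, so edge counts
  are reproducible across implementations.
* **Ties.** Edges of equal correlation are ranked by ascending node-index
  pair after sorting by descending correlation; correlations are compared
  after rounding to 12 decimals so floating-point noise cannot reorder
  exact ties (two-subject pseudo-groups produce correlations of exactly
  ±1 and rely on this). The rule makes edge sets nested across the grid.
* **Disconnected graphs** are routine at low sparsity: Lp averages
  finite-distance pairs only; efficiencies use 1/∞ = 0; an edgeless graph
  has undefined (NaN) Lp.
* **Betweenness** is unnormalized (raw Brandes pair counts, endpoints
  excluded). Group differences are scale-invariant under permutation, and
  raw counts are the easiest to verify against exhaustive geodesic
  enumeration.
* **γ/λ/σ** propagate NaN when the null mean is zero (e.g. triangle-free
  null ensembles at very low sparsity). AUCs are then computed on the
  largest NaN-free suffix of the grid, with a warning.
* **Null networks are regenerated per threshold** and per permutation
  replicate; nothing is shared or cached across graphs.
* **Pooled residualization is computed once per comparison.** Because the
  covariate design matrix does not involve group labels, re-fitting after
  a label shuffle returns bitwise-identical residuals; the implementation
  exploits this identity. A `per-group` fit scope exists for exploratory
  use but is not available inside the permutation engine, where it would
  genuinely have to be re-fit per replicate.
* **Exhaustive enumeration** replaces Monte Carlo sampling whenever the
  relabeling space is small enough (`choose(nA+nB, nA) ≤ n_perm` unpaired,
  `2^n_pairs ≤ n_perm` paired), making small-design p-values exact. Monte
  Carlo p-values use the add-one estimator `(b+1)/(n_perm+1)`, which is
  valid (never anti-conservative) but bounded below by `1/(n_perm+1)`.
* **Determinism.** Every stochastic step (cohort simulation, rewiring,
  permutation sampling) consumes R's RNG from a caller-supplied seed;
  per-replicate seeds are pre-drawn so results are independent of the
  number of parallel workers.

## Design choices made where the method is underdetermined

* *Nodal efficiency* is the mean inverse distance from the node (the
  Brain Connectivity Toolbox convention), not the node's contribution to
  global efficiency.
* *Small-world nulls* are degree-preserving rewired graphs, not lattice
  references.
* *FDR family*: nodal tests are corrected per property across nodes
  (degree, betweenness, nodal efficiency families separately); global
  properties are reported uncorrected, with a joint correction available
  to users via `fdr_bh()`.
* *Edge backbone*: the "group average connections" display threshold is
  interpreted as the one-sample correlation t-test
  `t = r·sqrt((n−2)/(1−r²))` at uncorrected p < 0.001, applied to the
  rectified (positive) correlations.
* *The 17-node subcortical atlas* merges the five cingulate subdivisions
  across hemispheres: 12 bilateral structures (thalamus, caudate, putamen,
  pallidum, hippocampus, amygdala × 2 hemispheres) plus 5 bilateral
  cingulate parts is the only arithmetic that yields 17 nodes from these
  structures. The packaged node list documents this ordering.
* *Inner null count*: permutation replicates use 100 (configurable; the
  acceptance simulations use 20) rewired nulls per threshold instead of
  the 1000 used for reported group curves. The Monte Carlo noise this adds
  is identical in distribution for the observed and permuted statistics,
  so exchangeability — and hence p-value validity — is unaffected; the
  type-I-error simulation below confirms it empirically.

## What the synthetic generator does and does not emulate

`synthetic_spec()`/`generate_cohort()` draw regional values from a
multivariate normal whose correlation matrix has anatomically grouped
blocks (within-block correlation `r`, background `r0`), plus linear age
and ICV effects and optional independent noise. Defaults emulate the shape
of a late-middle-aged clinical cohort: age ~ N(59.7, 9.38) years,
ICV ~ N(1.45×10⁶, 1.4×10⁵) mm³, subcortical volumes ~ N(4500, 450) mm³
with β_age = −15 mm³/yr (atrophy) and β_icv = 0.003 (head-size scaling).
With this block-plus-background construction the implied correlation
matrix is always positive semi-definite (it is a sum of PSD terms when
`0 ≤ r0 ≤ r < 1`), and the generator verifies this at build time.

Packaged scenarios: `null_17` (identical generators — type-I error),
`effect_17` (block r 0.7 vs 0.1 — power), `paired_8` (8 pairs, limbic
covariance loss at follow-up — exercises exact enumeration) and
`paired_23` (follow-up-sized 23 pairs with a broad covariance collapse —
the paired power scenario; pilot power ≈ 0.9). The paired generator
matches the scan-2 correlation structure exactly by drawing the
innovation from `(C₂ − ρ²C₁)/(1−ρ²)`, which also delimits the reachable
(effect, ρ) combinations: a large instantaneous covariance loss at high
within-subject correlation is mathematically inconsistent and is rejected.

The generator does **not** emulate heavy-tailed or skewed morphometry,
site/scanner effects, segmentation failure, spatially smooth noise, or
nonlinear age trajectories. Tests passing on this data therefore validate
the *pipeline arithmetic and its statistical calibration under the model's
own assumptions*, not robustness to real-data pathologies.

A note on paired designs at small n: simulations during development showed
that with 8 pairs a group-covariance statistic has essentially no power
(a 17×17 correlation structure cannot be estimated from 8 subjects per
condition), whatever the planted effect. Exact enumeration still yields
valid p-values there; detecting realistic longitudinal covariance change
requires samples nearer the 23-pair scenario.

## Problem sizes used in the packaged simulations

The calibration suites run at deliberately reduced scale, chosen as the
smallest sizes at which the checks are statistically meaningful: the
type-I-error study uses 200 replicate null datasets of 20+20 subjects,
a 0.10–0.30 (step 0.05) grid, 500 permutations and 20 inner nulls; the
power study uses 100 runs of the `effect_17` fixture with 200
permutations; metric-oracle equivalence uses 200 random graphs with up to
12 nodes, where exhaustive geodesic enumeration is feasible. The reported
group curves in the analysis scripts use the full 36-value grid and 1000
nulls.

## Known limitations

* Only positive-rectified, binary, sparsity-thresholded networks; no
  weighted or signed variants, no absolute-threshold mode.
* No network-based statistic (NBS), modularity, rich-club or
  assortativity measures.
* Monte Carlo p-values cannot fall below 1/(n_perm+1); with 5000
  permutations that floor is ≈ 0.0002.
* Group covariance networks yield a single observation per group;
  everything rests on the permutation machinery, and effect sizes are
  AUC differences without confidence intervals.

## A worked miniature

```{r example, eval = FALSE}
library(covnet)

fx <- fixture_cohort("effect_17", seed = 1)         # two 40-subject groups
res <- permutation_test_unpaired(
  fx$A, fx$B, grid = sparsity_grid(), n_perm = 1000,
  n_null_inner = 20, seed = 1)
subset(res$results, node == "global")
```

The analysis scripts under `analysis/` run the full narrative:
simulation (`01`), network construction and small-world range checking
(`02`), unpaired inference on the null and effect scenarios (`03`), and
the paired follow-up analysis (`04`), writing tables under `results/`.
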