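---
title: "Methods: group-level CBF covariance networks"
author: "cbfnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group-level CBF covariance networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbfnet)
```

## The model

A CBF covariance network is a *group-level* construct. For a group of $n$
subjects with mean CBF extracted in $R$ atlas regions (116 for the AAL
parcellation), the network has one node per region and edge weights

$$ r_{ij} = \mathrm{cor}\!\left(e_i, e_j\right), $$

where $e_i \in \mathbb{R}^n$ are the OLS residuals of region $i$'s values on
an intercept plus the subject covariates (age in years, sex coded 0/1).
There is no per-subject network: the correlation is computed across
subjects, so every group yields exactly one $R \times R$ symmetric matrix
with unit diagonal. Two assumptions follow directly from this construction:

* subjects are exchangeable within a group once age and sex are regressed
  out — this is also exactly the invariance the permutation test exploits;
* covariate effects are linear and additive at each region. Residuals then
  have zero mean and zero sample correlation with each covariate by
  construction, which `residualizeCBF()` verifies is testable to machine
  precision.

Upstream of this, per-voxel CBF maps are normalized by the whole-brain
(in-mask) mean, so regional values are unitless ratios; the brain mask
defaults to finite, strictly positive voxels (the weakest defensible
constraint for a perfusion map) and an explicit mask file overrides it.
`CBFVolume` carries a `normalized` flag so the division happens exactly
once. Spatial preprocessing (registration, smoothing, template building) is
out of scope: volumes must already be on a common grid.

## Thresholding

Networks are compared at equal *sparsity* $S$ — the fraction of the
$R(R-1)/2$ possible edges retained — so that differences in overall
correlation level cannot masquerade as topological differences.
`applySparsity()` keeps exactly $\mathrm{round}(S \cdot R(R-1)/2)$ edges,
ranked by connection strength.

Choices the correlation literature leaves open, and what this package does:

* **Sign handling.** Edges are ranked and weighted by $|r|$ (default).
  Absolute correlation is the common covariance-network convention, keeps
  weights in $(0, 1]$, and treats strong negative coupling as coupling. A
  `rank = "positive"` mode restricts eligibility to $r > 0$ for users who
  prefer it.
* **Tie-breaking.** Ties at the cut are resolved by ascending node-index
  pair, so thresholding is deterministic across platforms and the edge sets
  are nested along the schedule (the graph at $S_1 < S_2$ is a subgraph of
  the one at $S_2$).
* **Schedule.** The default grid is $S = 0.09, 0.10, \dots, 0.30$
  (22 levels). The lower bound keeps the mean degree $2E/N$ of a 116-node
  network above $2 \ln N \approx 9.51$ (`checkDegreeCriterion()`; the
  logarithm base is configurable, natural log being the standard choice in
  small-world estimation); the upper bound keeps the network sparse enough
  to remain distinguishable from a random graph.
* **Weights are not rescaled after thresholding** — the retained $|r|$
  values are used as they are.

## Global metrics

Seven measures are computed per threshold (`normalizedMetrics()`,
`metricCurve()`):

* **Clustering `Cp`.** Binary graphs use the Watts–Strogatz triangle
  fraction. Weighted graphs use the Onnela coefficient — the geometric mean
  of triangle weights, each normalized by the graph's maximum weight — which
  reduces to Watts–Strogatz on unit weights and is the dominant convention
  in weighted brain-network work. Nodes with degree < 2 contribute 0 rather
  than being dropped, keeping the denominator at $N$ for every group.
* **Path length `Lp`.** Edge length is $1/w$ (stronger coupling = shorter
  distance). `Lp` is the *harmonic mean* distance
  $N(N-1) / \sum_{i \ne j} d_{ij}^{-1}$: unreachable pairs contribute zero
  to the reciprocal sum, so `Lp` stays finite on the disconnected graphs
  that proportional thresholding routinely produces, and the identity
  `Lp = 1/Eglob` holds exactly (both facts are asserted in the tests).
* **Efficiencies.** `Eglob` is the mean inverse distance over ordered pairs;
  `Eloc` averages the global efficiency of each node's neighborhood subgraph
  (the node removed), with degree < 2 nodes contributing 0.
* **Normalization.** $\gamma = Cp/\langle Cp_{\mathrm{rand}}\rangle$,
  $\lambda = Lp/\langle Lp_{\mathrm{rand}}\rangle$,
  $\sigma = \gamma/\lambda$, against `nRandom` (default 100) references per
  threshold. References are Maslov–Sneppen double-edge swaps — $10\times E$
  attempted swaps per reference, configurable — which preserve each node's
  degree and the edge count exactly; in weighted mode the original weight
  multiset is randomly reassigned to the rewired edges, preserving the
  weight distribution. This null model holds fixed precisely the two
  properties ($\,$degree sequence, weights$\,$) that the $\gamma/\lambda$
  normalization assumes.

Each metric's trajectory is summarized by its trapezoidal AUC over the
schedule. A single-point schedule has zero width; there the "AUC" is
reported as the raw value and the `MetricCurve` records `aucWidth = 0`.

## Permutation inference

`permutationTest()` compares groups A and B on any metric, per threshold or
as AUC. Each of `nPerm` permutations pools all subjects, reassigns them to
groups of the *original sizes*, and reruns everything — residualization,
correlation, thresholding, the metric, and (for $\gamma, \lambda, \sigma$)
fresh random references with a per-permutation derived seed. The p-value is

$$ p = \frac{\#\{\,|\Delta_{\mathrm{perm}}| \ge |\Delta_{\mathrm{obs}}|\,\}}{n_{\mathrm{perm}}}, $$

two-sided by default, with ties counted as exceedances (the conservative
reading); one-sided alternatives and the $(\mathrm{count}+1)/(n+1)$
small-sample variant are available by flag. With this convention identical
groups give $p = 1$ and a real difference exceeding every permuted one gives
$p = 0$. `compareAll()` runs several metrics in both weighted and binary
modes; within a mode all metrics share one permutation stream, so
cross-metric comparisons see identical relabelings (whether to share the
stream is genuinely open; sharing removes one source of Monte-Carlo noise
and is documented behavior). No multiple-testing correction is applied
across metrics — each test stands alone at its stated level.

## The synthetic generator

`generateCohort()` draws each group from a multivariate normal with
block-constant correlation: `nModules` contiguous modules with
`rhoWithin` inside and `rhoBetween` across, the simplest structure whose
positive semi-definiteness can be checked exactly (specs failing the eigen
check are rejected) and which yields the modular covariance networks the
analysis assumes. Independent Gaussian noise of SD `noiseSd` (relative to
unit signal SD) shrinks off-diagonal correlations by $1/(1+\sigma^2_{\eta})$;
the shrunk matrix is stored as the cohort's `truth`. Linear,
region-homogeneous age and sex effects (configurable per region) are added
so residualization can remove them exactly — that is what makes the
residualization contract testable. Defaults mirror a two-group perfusion
study design: 44 vs 50 subjects, 116 regions, ages uniform on 35–75, sex
balanced; baseline `rhoWithin = 0.30`, `rhoBetween = 0.10`,
`noiseSd = 0.5`, a mean level of 50 (mL/100 g/min scale) — values picked
once as a realistic regime in which the thresholded networks are modular
and small-world ($\sigma > 1$) across the default schedule.

What the generator does *not* emulate: ASL acquisition physics, spatial
noise, lesions, non-Gaussian marginals, and heteroscedastic or nonlinear
covariate effects. Tests passing on these cohorts demonstrate that the
pipeline's algebra, determinism and error control are correct under the
stated model — not that real perfusion data satisfy that model.

`generateToyVolumes()` writes each subject's regional vector into disjoint
voxel patches (≥ 8 voxels each) of a NIfTI grid, plus the matching label
volume, so the ROI-extraction path can be tested as an exact inverse at
zero jitter and against a $4\cdot\mathrm{jitter}/\sqrt{\mathrm{voxels}}$
standard-error bound otherwise.

## Calibration of the planted effect

The power checks plant a within-module correlation raise in group A. The
margin was calibrated once, during development, to the design target of a
true weighted Cp-AUC difference of about three permutation-null standard
deviations under the baseline conditions above; that gave
`rhoWithinA = 0.53` (baseline 0.30), which the test suite then holds fixed
while asserting detection power and sign stability. The calibration is a
property of the baseline generator settings, not a tunable of the test.

## Problem sizes and numerical tolerances

The test suite checks the metric implementations against independent
brute-force oracles (triple-loop Onnela clustering, Floyd–Warshall
distances, per-node subgraph efficiency) to $10^{-10}$ on 50 random graphs
of up to 20 nodes, and cross-checks shortest paths against
`igraph::distances()` exactly. Statistical properties use scaled-down
Monte-Carlo settings chosen to keep the suite practical on one CPU while
leaving the checked quantities well-identified: 200 null datasets and 100
planted-effect datasets at the full design size (44 vs 50 × 116 regions)
with `nPerm = 200` and `nRandom = 10`, 20 graphs for the Erdős–Rényi
$\gamma, \lambda \approx 1$ band and the Watts–Strogatz $\sigma > 1$ check
with 100 references each. The hot path (clustering-coefficient curves along
the nested threshold schedule, rewiring, Dijkstra) is implemented in C++;
the R object pipeline computes the same quantities and the suite asserts
the two routes agree to $10^{-12}$.

Degenerate inputs are errors, not warnings: constant regions (undefined
correlations), regions with no in-mask voxels (silent NaNs would corrupt
the network), rank-deficient covariate designs (named covariate), sparsity
levels yielding empty graphs, and graphs with no connected pair (undefined
`Lp`).

## Known limitations

* Only global metrics — no nodal measures, hubs, or modularity inference.
* Group comparison only, two groups, no covariate adjustment beyond the
  nodewise residualization.
* Proportional thresholding guarantees equal edge counts, not equal
  connectedness; the harmonic-mean `Lp` is how disconnection is absorbed.
* The generator's block-normal model is a stand-in for unknown real CBF
  covariance structure; conclusions about real ASL cohorts require real
  data.

```{r session}
sessionInfo()
```
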