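# cbfnet — cerebral blood flow covariance network analysis

`cbfnet` implements group-level graph analysis of regional cerebral blood
flow (CBF), the perfusion measure mapped non-invasively by arterial spin
labeling MRI. Because a covariance network is defined *across subjects* —
nodes are atlas regions, an edge is the Pearson correlation of two regions'
CBF over all subjects of a group — there is one network per group, not per
subject, and group comparison needs relabeling-based inference rather than
per-subject statistics. The package is aimed at neuroimaging researchers who
have per-subject CBF maps in a common space (or an already-extracted
subjects × regions table) and want reproducible, seed-stable network
comparisons between two groups.

## What it computes

Starting from normalized regional CBF values:

1. **Residualization.** At every region, OLS residuals of CBF on intercept +
   age + sex (any covariates in the subject table).
2. **Covariance network.** The R × R matrix of Pearson correlations
   `r_ij = cor(resid_i, resid_j)` across the subjects of one group
   (R = 116 for the AAL atlas: 90 cerebral + 26 cerebellar regions).
3. **Proportional thresholding.** At sparsity `S`, the strongest
   `round(S · R(R−1)/2)` edges by |r| are kept, so compared networks always
   have the same edge count. The default schedule is S = 0.09…0.30 in steps
   of 0.01, the lower end chosen so the mean degree `2E/N` stays above
   `2 ln N`. Weighted graphs keep |r| as the weight; binary graphs set all
   weights to 1.
4. **Global metrics** at every threshold:
   - `Cp` — mean clustering coefficient (Onnela geometric-mean formula on
     weighted graphs, Watts–Strogatz on binary);
   - `Lp` — characteristic path length as the *harmonic mean* shortest-path
     distance (edge length 1/w), finite on disconnected graphs, with
     `Lp = 1/Eglob` identically;
   - `γ = Cp / ⟨Cp_rand⟩`, `λ = Lp / ⟨Lp_rand⟩` against 100 degree-preserving
     Maslov–Sneppen rewired references (weight multiset shuffled in weighted
     mode), and small-worldness `σ = γ/λ`;
   - `Eglob`, `Eloc` — global and local efficiency.
   Each metric is also summarized by its trapezoidal AUC over the schedule.
5. **Permutation inference.** The observed group difference (A − B) of any
   metric is referred to a null distribution obtained by re-pooling all
   subjects, reassigning them to groups of the original sizes, and rerunning
   the entire construction per permutation; `p = #{|diff_perm| ≥ |diff_obs|} / n_perm`.

A synthetic cohort generator (multivariate normal with block-modular
correlation, planted group effects, and linear age/sex effects) and NIfTI
region-of-interest extraction make the full pipeline runnable end to end
with no external data.

## Worked example

```r
library(cbfnet)

spec   <- cohortSpec(rhoWithinA = 0.53, seed = 7)   # planted effect in group A
cohort <- generateCohort(spec)
cohort
#> SyntheticCohort: 44 + 50 subjects, 116 regions (8 modules), seed 7
#>   rho within A/B = 0.53/0.30, between = 0.10, noise SD = 0.50

groupA <- cohortGroup(cohort, "A")
netA   <- correlationNetwork(residualizeCBF(groupA))
netA
#> CovarianceNetwork: 116 regions, 44 subjects (group all)
#>   off-diagonal r: median 0.130, range [-0.465, 0.736]

g <- applySparsity(netA, S = 0.10)
g
#> ThresholdedGraph: 116 nodes, 667 edges (S = 0.100, weighted)
unlist(checkDegreeCriterion(g))
#>       pass meanDegree  threshold
#>    1.00000   11.50000    9.50718

curve <- metricCurve(netA, sparsitySchedule(), mode = "weighted",
                     nRandom = 20, seed = 7)
curve
#> MetricCurve (weighted): 22 sparsity levels in [0.09, 0.30], 20 references
#>   AUC: Cp=0.06474, Lp=0.8996, gamma=0.5277, lambda=0.2423, sigma=0.4517,
#>        Eloc=0.06819, Eglob=0.04922

test <- permutationTest(groupA, cohortGroup(cohort, "B"),
                        metric = "Cp", nPerm = 1000, seed = 7)
test
#> PermutationResult: Cp (weighted, auc), groups 44 vs 50
#>   observed diff = 0.023773, p = 0.006 (1000 permutations)
```

Reading the output: at S = 0.10 the 116-node network keeps exactly
667 = 0.10 × 6670 edges and its mean degree (11.5) clears the 2 ln 116 ≈ 9.51
admissibility bound. The AUC row condenses each metric's trajectory over the
22 thresholds into one number (γ's mean over the schedule is its AUC divided
by the width 0.21, here ≈ 2.5 — strongly clustered relative to rewired
references). Group A was generated with higher within-module coupling, and
the permutation test detects the resulting clustering surplus (Cp-AUC
difference +0.024, p = 0.006 with 1000 relabelings).

The same analysis runs from the command line via a YAML config:

```sh
Rscript inst/cli/cbfnet.R simulate --config run.yaml
Rscript inst/cli/cbfnet.R compare  --config run.yaml
```

with `simulate`, `extract` (NIfTI volumes + atlas → regional TSV) and
`compare` subcommands; every output embeds the config hash and seed.

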