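# ccbayes — consensus clustering for Bayesian mixture models

Bayesian mixture models are a natural fit for clustering biomedical data:
they infer the number of clusters rather than conditioning on it, and they
quantify how certain each co-assignment is. But the Gibbs samplers behind
most implementations mix badly once the number of features grows — a single
chain gets trapped in one posterior mode and no affordable run length fixes
that. `ccbayes` is for analysts who want the flexibility of the Bayesian
model without pretending their chains converged: it runs an **ensemble of
deliberately short chains**, each started from an independent draw from the
prior over partitions, and combines only their final partitions.

For chain depth `D` and ensemble width `W`, the procedure is:

1. For each of `W` seeds, draw a partition from the prior of an overfitted
   mixture (`K_max` components, symmetric Dirichlet weight prior with small
   concentration `α = 1/K_max`) and run `D` Gibbs sweeps.
2. Collect the `W` final partitions into the **consensus matrix**
   `CM_ij = #{chains with c_i = c_j} / W`.
3. Extract a point clustering `ĉ = argmax_c PEAR(c, CM)`, the maximiser of
   the posterior expected adjusted Rand index over a hierarchical-cut +
   greedy-move candidate set.
4. Size the ensemble with a scree-style heuristic: the mean absolute
   difference between consensus matrices at consecutive depths (and widths)
   shrinks as the ensemble grows; stop at the elbow.

The package also contains everything needed to study the method at desk
scale: the finite-mixture generator with irrelevant features behind the
simulation scenarios, exact small-instance oracles (posterior enumeration;
exhaustive PEAR search), the long-chain comparator with convergence
screening (Geweke Z-scores + Shapiro–Wilk, classic and rank-normalised
split R-hat, pooled posterior similarity matrices), an EM + BIC Gaussian
mixture baseline, and the adjusted Rand index for scoring.

## Worked example

```r
library(ccbayes)

ds <- simulate_mixture("2d", seed = 101)   # 100 items, 2 features, 5 clusters
cc <- consensus_clustering(ds, width = 100, depth = 1000, seeds = 1)
cc
#> <consensus_clustering> W = 100 chains, D = 1000 sweeps, 100 items
#>   point estimate: 5 clusters (PEAR 0.936)

ari(cc$point_estimate, ds$labels)
#> [1] 1
```

The ensemble of 100 chains, each only 1000 sweeps deep, recovers the five
generating clusters exactly (ARI 1); the PEAR value 0.936 says the point
estimate agrees closely, but not perfectly, with the pairwise consensus —
the residual reflects items whose co-assignments still vary across chains.
`autoplot(cc)` draws the consensus heatmap; `tidy(cc)` returns the pairwise
co-clustering proportions as a tibble.

Sizing the ensemble:

```r
grid <- consensus_grid(ds, depth_grid = c(10, 100, 1000),
                       width_grid = c(25, 100), seeds = 1)
stability_curves(grid)
#> # A tibble: 7 × 7
#>   curve depth width from_depth from_width     mad stable
#> 1 depth   100    25         10         25 0.0811  FALSE
#> 2 depth  1000    25        100         25 0.0199  FALSE
#> 3 depth   100   100         10        100 0.0755  FALSE
#> 4 depth  1000   100        100        100 0.0125  FALSE
#> 5 width    10   100         10         25 0.0334  FALSE
#> 6 width   100   100        100         25 0.0106  FALSE
#> 7 width  1000   100       1000         25 0.00885 TRUE
```

Each row is the mean absolute change in the consensus matrix when the
ensemble last grew; going from depth 100 to 1000 at width 100 still moves
the average entry by only 0.0125, and the width-growth change at depth 1000
has fallen below the advisory 0.01 threshold — this ensemble is close to
stable. `plot_stability_curves()` draws the elbow plot.

The maximum-likelihood comparator on the same data:

```r
em_gmm_bic(ds)
#> <gmm_bic> selected k = 5 (spherical covariance), BIC = -351.05
```

On this low-dimensional, well-separated problem EM + BIC agrees with the
ensemble. Its interesting failure mode — collapsing to a single cluster
when many irrelevant features are added, while the consensus ensemble still
finds structure — is what the `"irrelevant_features"` scenario probes (see
the vignette).

A thin command-line interface wraps the same functions
(`inst/cli/ccbayes.R`): subcommands `simulate`, `consensus`, `pointest`,
`diagnose`, `score`, `baseline`.

## Documentation

The methods vignette (`vignettes/consensus-clustering.Rmd`) describes the
model and sampler, the prior defaults and why they are calibrated to the
within-cluster scale, the generator's design (including what it does *not*
emulate), the PEAR maximiser, the stability heuristic, and known
limitations.
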