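---
title: "Consensus clustering with short MCMC chains: models and method choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus clustering with short MCMC chains: models and method choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccbayes)
```

## The idea

Sampling-based Bayesian clustering is attractive — it explores different
numbers of clusters in a single run and quantifies allocation uncertainty —
but a single Gibbs chain on high-dimensional data routinely gets trapped in
one posterior mode, and running it long enough to escape is often
infeasible. `ccbayes` treats the sampler as a *base learner* in an ensemble
instead: many chains are started from independent random draws from the
prior over partitions, each is run for a deliberately small, fixed number of
sweeps `D`, and only the final partition of each chain is kept. The `W`
collected partitions are compiled into a **consensus matrix** whose (i, j)
entry is the fraction of chains in which items i and j ended up together.
A point clustering is then extracted from that matrix by maximising the
posterior expected adjusted Rand index (PEAR), and the matrix itself
describes the stability of every pairwise association.

The result is not Bayesian inference — chains are intentionally stopped long
before convergence — but it inherits the model's flexibility (the number of
clusters is inferred, not fixed) while replacing an unattainable convergence
requirement with an ensemble-stability criterion that can actually be
checked.

## The mixture model and its sampler

The base learner is an overfitted finite mixture. For item $i$ with feature
vector $x_i$,

$$p(x_i \mid \pi, \theta) = \sum_{k=1}^{K_{max}} \pi_k \, p(x_i \mid \theta_k),$$

with $K_{max}$ deliberately larger than any plausible number of clusters and
a small symmetric Dirichlet prior $\pi \sim \mathrm{Dir}(\alpha, \ldots,
\alpha)$ so that surplus components empty out during sampling. Component
densities are products over features: diagonal-covariance Gaussians for
continuous data, independent Bernoullis for binary data. The shipped sampler
is the plain parameters-and-allocations ("uncollapsed") Gibbs sampler: each
sweep reallocates every item from its full conditional given the current
weights and component parameters, then redraws the weights from their
Dirichlet full conditional, then redraws every component's parameters from
the conjugate posterior of its current members (empty components draw from
the prior). Given the parameters the allocations are conditionally
independent, which is what makes each sweep cheap and the whole scheme
embarrassingly parallel across chains.

For validation the package also ships a *collapsed* oracle,
`enumerate_posterior_coclustering()`, which integrates the component
parameters out analytically and enumerates every labelled allocation of a
small instance. The uncollapsed sampler and the collapsed enumeration target
the same partition posterior, so long sampler runs on tiny instances must
reproduce the enumerated co-clustering probabilities — the strongest
correctness check a sampler can be given, and one the test suite applies at
$N \le 5$ for both the Gaussian and the Bernoulli model.

### Priors and their defaults

The defaults, all exposed in `mixture_hyperparameters()`:

| parameter | default | role |
|---|---|---|
| `k_max` | 50 | components in the overfitted mixture |
| `dirichlet_alpha` | `1 / k_max` | symmetric Dirichlet concentration |
| `prior_mean` | feature means | NIG location $m_0$ |
| `prior_shrinkage` | 0.01 | NIG $\kappa$: prior mean variance is $\sigma^2/\kappa$ |
| `prior_shape` | 2 | Inverse-Gamma shape $a_0$ |
| `prior_rate` | 0.1 × feature variance | Inverse-Gamma rate $b_0$ |
| `beta_a`, `beta_b` | 1, 1 | Beta prior on Bernoulli rates |

Two of these deserve comment.

**`dirichlet_alpha = 1/k_max`** is the standard overfitted-mixture regime:
it makes the prior on partitions concentrate on few clusters (the prior
probability that two items co-cluster is $(\alpha + 1)/(K_{max}\alpha + 1)
\approx 0.51$ at the defaults), and in long runs the number of *occupied*
components concentrates near the true number rather than $K_{max}$ — a
property the test suite checks on well-separated three-cluster data.

**`prior_rate = 0.1 ×` feature variance** calibrates the component-variance
prior to the *within-cluster* scale rather than the marginal scale. This is
a prior-predictive argument: if clustering structure exists, most marginal
variance is between clusters, and genuine components are much tighter than
the marginal spread. The Inverse-Gamma density vanishes like
$\exp(-b_0/\sigma^2)$ below its rate, so a rate on the marginal scale
(e.g. half the feature variance) effectively *excludes* the small
within-cluster variances real components need, and the sampler compensates
by merging clusters. Centring the prior mean of $\sigma^2$ at a tenth of the
marginal variance (with $a_0 = 2$, so the prior retains infinite variance
and stays weakly informative) removes that bias while remaining scale-free
for standardised data. Users analysing data they believe to be structureless
should raise it.

### Randomness and reproducibility

Every chain is a pure function of its own integer seed: the seed is set
immediately before the prior draw and the compiled sweep kernel consumes
only R's RNG stream. `run_ensemble()` therefore produces identical results
for any execution order of its chains — the serial implementation shipped
here and any parallel scheduling of the same seeds are exchangeable by
construction.

## The synthetic-data generator

`simulate_mixture()` draws labels i.i.d. from the mixture weights and
generates each *relevant* feature from a unit-variance-$\sigma^2$ Gaussian
whose cluster means form the equally spaced grid $0, \Delta\mu, \ldots,
(K-1)\Delta\mu$; *irrelevant* features are drawn from a single global
Gaussian regardless of the label. Three presets encode the study scenarios:
a two-feature well-separated problem (`"2d"`, N = 100, $\Delta\mu$ = 3), a
high-dimension/low-sample problem (`"small_n_large_p"`, N = 50, P = 500,
$\Delta\mu$ = 1) built to make single chains stick, and a noise-dominated
problem (`"irrelevant_features"`, N = 200, 20 signal + 100 noise features).

**Mean arrangement.** How the grid of means is assigned to clusters across
features is a genuinely open design choice. Assigning the grid *identically*
in every feature (`arrangement = "collinear"`) places all clusters on a
single line, and with K = 5 and $\Delta\mu = 3$ that geometry is so
confusable that the Bayes-optimal classifier itself misclassifies enough
items to depress ARI well below what a "well-separated" scenario should
deliver; no method can look good there, which defeats the scenario's
purpose. The default (`arrangement = "permuted"`) instead assigns the grid
to clusters by an independent random permutation per feature, so clusters
that are neighbours in one feature are typically distant in another.
$\Delta\mu$ keeps its literal meaning — the distance between neighbouring
cluster means within a single feature — while the scenario becomes
recoverable by a good method, which is what a positive control must be.

**Standardisation** (`standardise = TRUE`, the default) rescales every
feature to zero mean and unit variance after generation, so the
hyperparameter defaults above are appropriate without per-dataset tuning.

What the generator deliberately does *not* emulate: correlated features,
non-Gaussian (heavy-tailed, skewed, zero-inflated) noise, cluster-specific
variances, batch structure, or missing data. Passing tests on these
synthetic conditions therefore demonstrates correctness of the machinery
and recoverability under the stated model, not robustness to the
misspecifications real 'omics data exhibit.

## Point estimation

`max_pear()` scores a candidate partition against a similarity matrix by
PEAR — over the $B = N(N-1)/2$ unordered pairs, with $I_{ij}$ the
candidate's co-clustering indicator and $s_{ij}$ the similarity,

$$\mathrm{PEAR} = \frac{\sum I_{ij} s_{ij} - \sum I_{ij} \sum s_{ij} / B}
{\tfrac12\left(\sum I_{ij} + \sum s_{ij}\right) - \sum I_{ij} \sum s_{ij} / B},$$

which is the posterior expectation of the adjusted Rand index when $s$
holds exact posterior co-clustering probabilities; for a consensus matrix it
is used heuristically with no further optimality claim. Candidates come
from hierarchical clusterings of $1 - s$ under four linkages (average,
complete, Ward, single) cut at $k = 1..\lceil N/2\rceil$ (capped at 30),
each refined by greedy single-item moves with O(1) incremental score
updates until no move improves; the linkage diversity is what keeps the
greedy refinement out of the local optima any single dendrogram
occasionally induces (validated against exhaustive enumeration). Ties are
broken towards fewer clusters, then lexicographically on canonical labels;
candidates whose PEAR is formally 0/0 (e.g. all singletons against an
identity similarity) score 0. `exhaustive_max_pear()` enumerates all set
partitions up to N = 10 as the oracle against which the candidate-search
heuristic is validated.

## Ensemble sizing: the stability heuristic

Because the ensemble deliberately forgoes convergence, it needs a different
stopping rule. `consensus_grid()` runs the widest ensemble once to the
greatest depth with checkpoints at every depth in the grid (a depth-$d$
prefix of a depth-$D$ chain *is* a depth-$d$ chain, so nothing is
recomputed), and `stability_curves()` reports the mean absolute difference
between consensus matrices at consecutive depths (per width) and consecutive
widths (per depth). The mean is taken over the $N(N-1)/2$ strictly
upper-triangular entries — the unit diagonal would only dilute the signal.
These sequential changes shrink as the ensemble grows; the user looks for
the elbow, exactly as with a PCA scree plot. No automatic threshold is
imposed: the `stable` flag (difference below `epsilon`, default 0.01) is
advisory, because the judgement is inherently contextual. Width comparisons
use nested chain prefixes (chains $1..w_j$), so width curves measure pure
ensemble-growth effects rather than chain-resampling noise.

## Long-chain diagnostics

The comparator workflow — a few long chains with convergence screening —
is implemented in full. `geweke_z()` compares sliding early-window means
against the mean of the final half of a scalar trace, scaled by
spectral-density-at-zero standard errors (smoothed tapered periodogram, 4%
taper). The diagnosed scalar defaults to the log-likelihood trace: it is
invariant to label switching, which makes per-parameter traces ill-defined
in mixtures. Under stationarity the Z-scores are approximately standard
normal, so `screen_chains()` applies a Shapiro–Wilk test to each chain's
Z-sequence and drops chains with p below 0.05; both the classic and the
rank-normalised split forms of R-hat are then computed across the kept
chains. `pooled_psm()` builds the posterior similarity matrix from the
pooled post-burn-in samples. A chain stuck in one mode shows the
characteristic all-0/1 within-chain PSM; stuck chains that disagree produce
intermediate pooled entries — the signature that motivates the ensemble
approach in the first place.

## The EM + BIC baseline

`em_gmm_bic()` is the maximum-likelihood comparator: EM fits over
$K = 1..9$ for per-component spherical, diagonal and full covariance
families (a reduced version of the reference tool's 14-model taxonomy),
each initialised from one agglomerative hierarchical clustering cut at $K$,
selected by $\mathrm{BIC} = 2\log L - \#\mathrm{params}\,\log N$. EM runs to
a $10^{-6}$ log-likelihood tolerance (at most 500 iterations) with a
monotonicity assertion on every step; components whose variance collapses or
whose covariance loses rank are pruned with a warning and the fit continues.

The initialisation default matters and is deliberate. With
`init = "model"`, the package reproduces the reference pipeline: mclust's
model-based agglomeration on an SVD-whitened copy of the data. In noisy
high-dimensional data this criterion tends to shave off single outlying
items rather than split the bulk, so EM never receives a genuine split to
refine and BIC falls back to one component — the characteristic collapse of
the maximum-likelihood baseline under many irrelevant features, which is
precisely the behaviour the consensus ensemble is shown to avoid. A
Ward-linkage initialisation (`init = "ward"`) is offered as a stronger
alternative; on the same noisy data it frequently finds genuine splits with
materially higher BIC, which is worth knowing when the baseline is used as
an actual analysis tool rather than as the comparator.

## Numerical choices

- Allocation probabilities are computed in log space; components trailing
  an item's maximum log-probability by more than 30 are skipped when
  exponentiating (relative error below $10^{-13}$).
- Weight draws use normalised Gammas floored at $10^{-300}$; Bernoulli
  rates are clamped to $[10^{-12}, 1 - 10^{-12}]$ before taking logs.
- PEAR ties are resolved by fewer clusters, then lexicographic canonical
  labels, making `max_pear()` fully deterministic.
- `ari()` returns 1 for the degenerate comparisons in which both partitions
  are structurally trivial in the same way (the 0/0 case), matching the
  "identical up to relabelling" convention.
- Zero-variance traces (or windows) are an error in `geweke_z()` rather
  than a silent NaN.

## Problem sizes used for validation

The test suite validates the sampler against exact enumeration at
$N \le 5$, $K_{max} \le 3$ with $10^5$ sweeps; structure recovery and the
stability heuristic on ten replicate `"2d"` datasets with ensembles of 100
chains checkpointed at depths 10–10,000; the stuck-chain signature on one
`"small_n_large_p"` dataset with five chains of $10^4$ sweeps; and the
baseline collapse on ten `"irrelevant_features"` replicates. These sizes
were chosen so the whole suite runs on a single CPU in well under half an
hour while still exercising every qualitative regime of interest —
ensembles wider or deeper than this change the constants, not the
behaviour.

## Limitations

- The ensemble is a heuristic: its consensus matrix is not a posterior, and
  PEAR's optimality argument does not transfer to it. Stability curves are
  a judgement aid, not a test with guarantees.
- Only diagonal-Gaussian and Bernoulli components are shipped; general
  multinomial components, Gaussian processes, and joint multi-dataset
  models are out of scope (the wrapper construction applies to them
  unchanged, but this package does not implement them).
- The Gibbs sampler has no split-merge or other bold moves; that weakness
  in single chains is the method's motivation, not a bug, but it means
  individual chains should never be interpreted alone.
- `em_gmm_bic()` is a comparator, not a replacement for a full-featured GMM
  package: three covariance families, no cross-validated alternatives to
  BIC.
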