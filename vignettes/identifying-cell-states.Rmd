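---
title: "Identifying cell states across perturbation conditions"
author: "scStates"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Identifying cell states across perturbation conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scStates)
```

## The problem

In a perturbation scRNA-seq experiment — control cells plus one or more
treated samples — the treatment shifts expression of many genes at once.
Distance-based clustering applied to the pooled data then tends to
separate cells by *treatment* rather than by *cell state*: a shared cell
type appears as two clusters, one per condition. Integration methods
remove this separation by warping the data into a shared embedding, but
they cannot distinguish technical from biological differences and may
erase genuinely condition-specific states.

`scStates` takes the opposite approach. Rather than minimizing
differences between conditions, it learns which genes *define* cell
states and re-weights the data so distances are dominated by those
genes, then co-clusters all cells while holding the control-derived
state labels fixed.

## The procedure

1. **Preprocess** (`preprocessCounts()`): size-factor normalization,
   `log1p`, optional selection of highly variable genes. Every gene is
   then min-max scaled to $[0,1]$ so a single kernel width applies to
   all of them.
2. **Cluster controls alone** (`clusterCells()`): Louvain community
   detection on a Euclidean kNN graph of the control cells.
3. **Learn gene weights** (`ncfsFit()`): neighborhood component feature
   selection. With per-gene weights $w_l$ and the weighted distance
   $D_w(x_i,x_j)=\sum_l w_l^2\,|x_{il}-x_{jl}|$, each cell picks a
   reference cell with probability
   $p_{ij} \propto \exp(-D_w(x_i,x_j)/\sigma)$, and the objective
   $$\xi(w)=\sum_i \sum_j y_{ij}\,p_{ij} \;-\; \lambda\sum_l w_l^2,$$
   a regularized leave-one-out classification accuracy, is maximized by
   gradient ascent from $w = \mathbf{1}$ ($w=\mathbf{0}$ is a stationary
   point, since every gradient component carries a factor $w_l$).
   Regularization drives uninformative weights to zero while
   state-defining genes end with weights above 1.
4. **Pool across treatments** (`poolWeights()`, the `"joint"` variant):
   each treatment is clustered and weighted independently and the
   vectors are reduced by an elementwise maximum, so genes marking
   treatment-only states survive. The `"control"` variant skips this
   and uses the control-derived weights alone; it is cheaper but will
   collapse structure that exists only in treated cells, so `"joint"`
   is the right choice whenever condition-asymmetric states are
   plausible.
5. **Transform and co-cluster**: columns are scaled by $w_l^2$
   (`applyGeneWeights()`), making Manhattan distance in the transformed
   matrix identical to $D_w$; a kNN graph is built in that metric; and
   `ssLouvain()` optimizes modularity with control cells pinned to
   their step-2 labels (immutable) and treated cells started as
   singletons. Control states keep labels `C1, C2, ...`; novel
   communities are labeled `N1, N2, ...`, so asymmetric states are
   visible at a glance.

For datasets larger than `subsampleThreshold` cells, the weight-learning
step runs on a representative subset chosen by stratified greedy
facility-location maximization (`selectRepresentativeCells()`), which
guarantees every control state stays represented and the greedy solution
is within $1-1/e$ of the optimal subset.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `sigma` | 1 | kernel width of the reference-point probabilities; matched to min-max scaled features |
| `lambda` | 1 | weight penalty; larger gives sparser gene sets |
| `eta0` | 0.01 | initial ascent step; grown 1% on accepted steps, halved on rejected ones, so the objective trace is monotone |
| `tol`, `maxIter` | 1e-4, 1000 | ascent stopping rules |
| `k` | 15 | kNN graph neighbors (all graphs) |
| `gamma` | 1 | Louvain resolution; larger splits finer |
| `snn` | `FALSE` | Jaccard shared-neighbor edge weights instead of unit weights |
| `subsampleThreshold` / `subsampleSize` | 2000 / 500 | when and how far to subsample for weight learning |
| `nHVG` | `NULL` | number of highly variable genes kept in preprocessing |

Weights are clamped to be nonnegative after every ascent step: distances
depend only on $w^2$, so the sign is unidentifiable and clamping keeps
the conventional "informative genes exceed 1" reading meaningful.
Weights falling below $10^{-3}$ are set to exactly zero — such a weight
contributes less than $10^{-6}$ to any distance and, because its
gradient is proportional to the weight itself, it cannot recover; this
also shrinks the active gene set and with it the cost of later
iterations. The fit itself contains no randomness; graph clustering uses
a seeded random traversal order, and `identifyStates()` fans one master
seed out into per-stage child seeds that are echoed in the provenance.

### Normalization and composition bias

`preprocessCounts()` defaults to pooled-deconvolution size factors
(`scran::calculateSumFactors()`) rather than total-count scaling. The
reason is composition bias: a strongly activated state whose marker
genes make up a large share of its library gets a proportionally larger
total count, and dividing by it removes much of the very signal that
distinguishes the state. In simulations with a stimulated population we
measured libraries 3–4 times larger in stimulated cells and, under
total-count scaling, a between-state displacement *smaller* than the
within-state spread — no downstream method can recover a state from
that. Deconvolution factors track sequencing depth while remaining
robust to a minority of composition-shifted genes. `method = "total"`
restores plain library-size scaling (it is also used automatically below
30 cells, where pooling is impossible).

## The simulator

`simulatePerturbation()` generates ground-truthed two-condition
experiments: baseline per-gene means are Gamma(2, 1) draws (floored at
0.01); each population receives a disjoint Poisson-sized marker set
(mean `avgMarkers`, at least one) whose means are shifted by independent
Gamma(3, 3) multipliers (shape–scale, mean 9); treatment perturbs a
random fraction of all genes with Gamma(2, 2) multipliers (mean 4)
in treated cells only; counts are drawn from a zero-inflated negative
binomial with size `r = 2` and dropout probability
$\pi(\mu)=e^{-\beta\mu}$, $\beta = 0.25$. Six composition scenarios
cover shared, condition-unique, and disjoint population structures, and
an `asym_stim` scenario adds a "stimulated" population whose markers
receive one further Gamma(3, 3) multiplier each in the treated
condition. We use per-marker draws rather than a single scalar because
a uniform modest boost is, after biological noise and log compression,
nearly invisible even to an oracle that knows the markers — activation
in real data is heterogeneous across genes, and the heterogeneous model
produces a state that is detectable in principle, which is what a
benchmark of detection methods requires.

The shape–scale reading of the Gamma parameters is deliberate: a
shape–rate reading would give multipliers with mean 1 that create
essentially no population substructure. Both Gamma conventions, the
dropout coefficient, and the dispersion are exposed as arguments.

What the simulator does *not* emulate: batch or library-depth effects
(libraries differ only through sampling and composition), doublets,
ambient RNA, gene–gene correlation beyond the population means, or
continuous trajectories between states. Passing benchmarks on these
simulations therefore demonstrates the algorithmic behavior — feature
weighting, label conservation, asymmetry detection — not robustness to
every artifact of real data.

## Evaluation metrics

`ariScore()` (Hubert–Arabie adjusted Rand index, pair-counting form),
`lisiScore()` (local inverse Simpson's index of condition mixing with a
perplexity-calibrated Gaussian kernel; a uniform-weight mode exists for
closed-form tests), `populationF1()` (F1 of the best-overlapping
cluster against one target population; ties break to the larger overlap
then the smaller cluster — a documented alternative to Hungarian
matching), `daviesBouldin()` (label-free compactness/separation), and
`giniCoefficient()` (population-size inequality). Scores that are
reported on a 0–1 scale use order-preserving maps: negative ARI values
clip to 0, mean LISI maps by $(\bar{\mathrm{ISI}}-1)/(L-1)$ for $L$
conditions, and Davies–Bouldin by $1/(1+\mathrm{DB})$; comparative
conclusions are unaffected by the choice of map.
`compositionTest()` runs a per-cluster G-test (likelihood-ratio
chi-squared) of cluster-vs-rest by treatment with Benjamini–Hochberg
correction across clusters, followed by pairwise two-sided Fisher's
exact tests between treatments for significant clusters.

## Numerical and design choices

- **Reference probabilities** are computed with a row-minimum shift
  before exponentiation (log-sum-exp), which is algebraically identical
  to the plain kernel normalization but immune to underflow in high
  dimension; a fully degenerate row falls back to uniform off-diagonal
  probabilities with a warning.
- **Semisupervised Louvain**: nodes sharing a seed label start in one
  community; seeded nodes never move; a community containing a seeded
  node stays immutable through aggregation, so two distinct seed labels
  can never merge — this is what holding labels immutable has to mean
  for label identity to survive. Equal-gain moves break to the lowest
  community id; traversal order is a seeded permutation per pass.
- **Manhattan metric downstream**: scaling columns by $w^2$ makes
  Manhattan distance in the transformed space *exactly* the learned
  NCFS metric (the identity
  $\sum_l |w_l^2 x_{il} - w_l^2 x_{jl}| = \sum_l w_l^2\,|x_{il}-x_{jl}|$
  holds termwise), which is why no PCA step is inserted after
  weighting; the weighted space is already low-dimensional in effect.
  Weighting by $w$ instead of $w^2$ would not reproduce the metric.
- **Degenerate inputs**: a single control cluster leaves all weights at
  1 with a warning (there is nothing to discriminate); zero-depth cells
  are dropped with a warning and recorded in the provenance; an
  experiment with no treated cells returns the control clustering.

## Problem sizes used in the shipped benchmarks

The test suite and `scripts/acceptance.R` replicate the simulated
benchmarks at desk scale: 1500 genes, 100 cells per population per
treatment, 10% of genes perturbed, an average of 50 markers per
population, three replicates per condition, with the 500 most variable
genes retained in preprocessing and the joint variant of the pipeline.
Per-scenario means over three replicates are inherently noisier than a
full 15-replicate design; an occasional replicate in which a strongly
perturbed, highly weighted marker gene legitimately displaces one
treated population is expected and visible as a single depressed ARI
value rather than a systematic failure.

## Known limitations

- The control-only variant collapses treated-unique structure by
  construction; use `"joint"` for asymmetric designs.
- Gene weights are learned from hard cluster labels; a poor control
  clustering propagates (garbage labels in, garbage weights out).
- NCFS keeps a *minimal* discriminative gene set: states that differ
  only as a diffuse shift across many weakly informative genes can be
  missed by the sparse representation.
- Louvain is a heuristic: on small graphs it reaches modularity within
  0.05 of the exhaustive optimum in our tests, not equality, and its
  resolution behavior can split large, elongated neighborhoods.
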