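# scStates

Identify and match transcriptional cell states between control and
perturbed conditions in single-cell RNA-seq experiments.

## The problem

In perturbation experiments (drug treatment, gene knockdown,
developmental disruption), treatment effects shift the expression of
many genes at once. Clustering the pooled control + treated cells then
typically separates cells by *treatment* instead of by *cell state*:
one biological population shows up as two clusters, one per condition,
and compositional comparisons between conditions become meaningless.
Integration methods fix the separation by warping conditions into a
shared embedding, but they cannot tell technical from biological
differences and can erase genuinely condition-specific states.

## The method

`scStates` implements a two-step, control-guided alternative:

1. **Self-supervised feature weighting.** Control cells are clustered
   alone (Louvain on a kNN graph) and the labels are fed to
   Neighborhood Component Feature Selection, which learns nonnegative
   per-gene weights $w_l$ by gradient ascent on a regularized
   leave-one-out classification objective

   $$\xi(w) = \sum_i \sum_j y_{ij}\, p_{ij} - \lambda \sum_l w_l^2,
   \qquad
   p_{ij} \propto \exp\!\big(-\tfrac{1}{\sigma}\textstyle\sum_l
   w_l^2 |x_{il} - x_{jl}|\big),$$

   where $y_{ij}=1$ when cells $i,j$ share a label. Regularization
   drives most weights to zero; state-defining genes end with weights
   above 1. In the *joint* variant each treatment is clustered and
   weighted independently and the weight vectors are pooled by an
   elementwise maximum, so genes marking treatment-only states survive.

2. **Semisupervised clustering.** The expression matrix is re-scaled by
   $w_l^2$ (so Manhattan distance equals the learned metric exactly), a
   kNN graph is built in that space, and Louvain modularity is
   optimized with the control cells' labels held immutable while
   treated cells start as singletons. Control states keep labels
   `C1, C2, ...`; genuinely novel communities appear as `N1, N2, ...`.

The package also ships the zero-inflated negative binomial simulator
used for benchmarking (populations defined by disjoint Gamma(3,3)
marker shifts, treatments as Gamma(2,2) perturbations of a random gene
fraction, six composition scenarios) and an evaluation suite (ARI,
LISI, population-specific F1, Davies–Bouldin, Gini, compositional
G-test/Fisher testing with FDR control).

## Worked example

```r
library(scStates)

# two shared populations plus one treatment-unique population
sim <- simulatePerturbation("rx_unique", seed = 7)
res <- identifyStates(sim, control = "control", variant = "joint",
                      nHVG = 500, seed = 7)
res
#> StateAssignment for 500 cells
#>   control states: C1, C2
#>   novel states: N1
#>
#>  C1  C2  N1
#> 200 200 100

truth <- SummarizedExperiment::colData(sim)$ground_truth
labs  <- stateLabels(res)[colnames(sim)]
table(truth, labs)
#>       labs
#> truth   C1  C2  N1
#>   pop1 200   0   0
#>   pop2   0 200   0
#>   pop3   0   0 100
ariScore(truth, labs)
#> [1] 1
```

The two shared populations are each assigned one state across both
conditions (`C1`, `C2` — no split by treatment), and the
treatment-unique population is reported as a novel state `N1` rather
than being absorbed into a control state. The highest pooled gene
weights identify the simulation's marker genes:

```r
head(sort(pooledWeights(res), decreasing = TRUE), 5)
#> gene0424 gene0391 gene0240 gene1283 gene1050
#>     1.64     1.38     1.27     1.20     1.16
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/scstates` (subcommands `simulate`, `run`, `evaluate`,
`benchmark`).

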