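---
title: "Methods: null models, distance-based tests, and diversity curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: null models, distance-based tests, and diversity curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commassembly)
```

This vignette documents the statistical machinery behind `commassembly`:
what each statistic measures, how the null models are constructed, and the
design decisions (and their caveats) behind the synthetic data generator.
It is the narrative companion to the function reference.

## The question

A recurring question in microbial ecology is whether community composition
is shaped by deterministic processes — environmental filtering,
competitive exclusion — or is indistinguishable from stochastic assembly.
The package operationalizes this along three axes:

1. **Spatial / environmental structure**: does community dissimilarity
   track geographic distance or environmental differences? (Mantel tests,
   stepwise regression on distance matrices.)
2. **Taxon co-occurrence**: do taxa co-occur less (segregation) or more
   (aggregation) than expected under randomization that preserves the
   observed richness structure? (CC and MA scores against SIM9 and IT
   nulls.)
3. **Functional redundancy**: are functional-group abundances more stable
   across samples than the taxa that carry them? (CV profiles, core-biome
   and collector's curves.)

## Co-occurrence scores

### CC score

For a presence/absence matrix with row (taxon) occupancies $N_i$ over $N$
samples and pairwise co-occurrence counts $N_{ij}$, the CC score is

$$\mathrm{CC} = 1 -
\frac{\sum_{i<j}(N_i - N_{ij})(N_j - N_{ij})}
     {\sum_{i<j}(N_i - N p_i p_j)(N_j - N p_i p_j)}, \qquad p_i = N_i/N.$$

The numerator is the classical checkerboard (C-score) sum; the denominator
replaces each observed co-occurrence with its independence expectation
$N p_i p_j$. CC is 1 when all taxa always co-occur, near 0 at
independence, and negative under segregation (a 2×2 perfect checkerboard
gives exactly −3).

`cc_score()` evaluates this in closed form. Writing $r = A A^\top
\mathbf{1}$ for row co-occurrence totals and $C = A A^\top$, both sums
reduce to power sums of $N_i$ and $\|C\|_F^2$, avoiding the explicit
$O(M^2)$ pair loop; the test suite checks it against a literal pairwise
double loop at $10^{-12}$.

### MA score

For a relative-abundance matrix $p_{ij}$ (taxon $i$, sample $j$), the
generalized Morisita score is

$$\mathrm{MA} = \frac{\sum_i\left[(\sum_j p_{ij})^2 - \sum_j p_{ij}^2\right]}
{(N-1)\sum_i \sum_j p_{ij}^2}.$$

It equals 1 when all samples have identical composition and 0 when no
taxon appears in more than one sample. Unlike CC it uses abundances, so it
is paired with an abundance-preserving null.

## Null models

### SIM9 (fixed–fixed)

SIM9 randomizes a binary matrix while preserving **both** row sums
(samples per taxon) and column sums (taxa per sample) via checkerboard
swaps: pick two random rows and two random columns; if the 2×2 submatrix
is `[[1,0],[0,1]]` or `[[0,1],[1,0]]`, flip it.

One subtlety matters for correctness. The proposal (uniform over
row-pairs × column-pairs) is symmetric, so the chain **indexed by
attempts** has the uniform distribution over all matrices with the given
marginals as its stationary law. If instead you record a matrix every $k$
*accepted* swaps, you sample the jump chain, whose stationary law weights
each state by the number of swappable submatrices it contains — a biased
null. `sim9_null()` therefore counts burn-in and thinning in attempts
(defaults: 100 × cells and 10 × cells). The test suite verifies
uniformity by exhaustively enumerating the fixed-marginal state space of a
4×4 matrix and applying a chi-square goodness-of-fit test to a long chain;
this test is what originally caught the accepted-swap bias.

Matrices with no checkerboard submatrix are frozen (the chain cannot
move); `sim9_null()` detects this and raises an error rather than
returning copies of the input.

### IT (abundance) null

The IT null reallocates every individual read to a cell $(i, j)$ with
probability proportional to (remaining row-$i$ quota) × (remaining
column-$j$ quota) until both marginal totals are met exactly. Because the
remaining-quota weights factorize at every step, the sequential fill is
distributionally identical to independently pairing a uniform random
permutation of the read-level taxon labels with the fixed read-level
sample labels. `it_null()` uses that equivalence and runs in $O(\text{reads})$;
the tests validate it against an exact recursive enumeration of the
sequential fill on small tables.

### Hypothesis tests

`null_test()` compares an observed score to its null distribution with
add-one permutation p-values,
$p_\text{low} = (1 + \#\{s_\text{null} \le s_\text{obs}\})/(1 + n_\text{null})$,
so the smallest attainable p-value is $1/(1+n_\text{null})$. CC is tested
against SIM9 and MA against IT; mixing a binary score with an abundance
null (or vice versa) is rejected. When many levels are tested,
`bonferroni_threshold()` provides family-wise thresholds.

## Distance-based tests

### Dissimilarities

`pairwise_dissimilarity()` offers Bray–Curtis, quantitative (Ruzicka)
Jaccard $J = 2\mathrm{BC}/(1+\mathrm{BC})$, and Hellinger (Euclidean
distance of square-root proportions, range $[0, \sqrt 2]$).
`geographic_distances()` returns great-circle kilometres.

### Mantel test

`mantel_test()` correlates the lower triangles of two distance matrices
with Spearman's $\rho$ and permutes rows and columns of one matrix
simultaneously. Because the permuted triangle is a fixed multiset, ranks
are computed once and the permuted statistics are Pearson correlations of
permuted rank matrices; with $n \le 8$ samples `exact = TRUE` enumerates
all $n!$ permutations. P-values use the add-one convention.

### Stepwise regression on distance matrices

`stepwise_mrm()` regresses an unfolded dissimilarity triangle on
candidate predictor matrices (environmental absolute differences,
geographic distance), adding at each step the candidate with the smallest
permutation p-value (pseudo-$t$, rows and columns of the response permuted
simultaneously) until none clears `alpha`. Ties are broken by the larger
standardized coefficient; candidates collinear with the selected set are
skipped with a warning; a numerically perfect fit stops selection.
`loso_cv_r2()` reports a leave-one-sample-out cross-validated $R^2$: all
pairs touching the held-out sample are predicted from a model fitted
without them.

## Diversity and stability curves

`core_biome_curve()` gives the expected number of taxa shared by $n$
randomly chosen samples, exactly
($\sum_i \binom{k_i}{n}/\binom{N}{n}$ for occupancies $k_i$) or by Monte
Carlo. `collectors_curve()` is exact hypergeometric rarefaction of one
sample. `cv_profile()` returns per-row means and coefficients of
variation of a proportions table; contrasting taxon CVs with
functional-group CVs at comparable means is the package's operational
definition of functional redundancy.

## The synthetic data generator

`generate_dataset()` produces surveys with known ground truth:

- **Heavy-tailed taxa**: lognormal base abundances.
- **Stable function by construction**: taxa are assigned round-robin to
  functional groups and each group's abundance budget is fixed across
  samples; all perturbations below act on within-group shares only, so
  group proportions stay nearly constant while membership turns over.
- **Sparsity**: an independent Bernoulli detection mask (`occupancy`).
- **Segregation** (`segregation` $s > 0$): each group carries two
  dominant contenders; per sample one wins and all other members are
  suppressed by $1 - s$. Winners are exempt from the detection mask so
  the two contenders alternate at intermediate occupancy — exactly the
  pattern marginal-preserving nulls can see. With $s = 1$ the CC test
  flags the dataset in well over 80% of replicates. Negative $s$ damps
  whole groups in half the samples (aggregation in abundance), which by
  design leaves presence/absence marginals nearly untouched.
- **Distance decay** (`distance_decay` $\lambda$): a lognormal spatial
  field with inter-sample correlation $e^{-\lambda d}$.
- **Environmental drivers** (`env_effects`): per-taxon sensitivities times
  covariate values added on the log scale.

Two calibration caveats, found empirically and worth knowing:

- With `occupancy < 1`, the detection mask itself creates real
  compositional turnover, which the IT null correctly flags — so MA
  neutrality checks use `occupancy = 1`.
- Spatial signal is likewise much cleaner without the mask; the
  distance-decay power checks use `occupancy = 1`, $\lambda = 0.01$,
  `spatial_sd = 2`.

These are properties of the generator's sparsity model, not of the tests.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(n_samples = 10, n_taxa = 500,
                        n_functional_groups = 25, occupancy = 1,
                        segregation = 0.8, distance_decay = 0.01,
                        spatial_sd = 2, env_effects = c(1.5, 0, 0),
                        seed = 1)
dat <- generate_dataset(cfg)
res <- run_full_analysis(dat, n_perm = 999, n_null = 499, seed = 2)
print(res)
res$mantel[res$mantel$level == "taxon", ]
res$null_tests[res$null_tests$level == "taxon", ]
```

## Limitations

- The permutation tests assume exchangeable samples; block or nested
  designs need a restricted permutation scheme the package does not
  provide.
- SIM9 mixing is assessed for the matrix sizes used here; extremely large
  and sparse matrices may need longer `thin` than the default.
- The stepwise selection inherits the usual caveats of forward selection
  (greedy, order-dependent with correlated predictors); the
  cross-validated $R^2$ is the honest summary of fit.
- Coarse taxonomic collapses (e.g. domain level) are often degenerate for
  the CC score (every row ubiquitous); `run_full_analysis()` reports NA
  for such levels.
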