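---
title: "Evaluating unsupervised subtype discovery: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating unsupervised subtype discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cluster analysis is routinely used to search for novel disease subtypes in
high-dimensional expression data, but tumor cohorts are heterogeneous:
expression is shaped not only by the subtype of interest but also by sex,
age and other factors. `clustbench` provides a controlled environment for
studying how such heterogeneity, the sample size, and the relative size of
the subtypes affect the chance that an unsupervised partition recovers the
subtype labelling. It combines

* a factor-model simulator for log-scale expression cohorts,
* the standard pre-processing and feature-selection steps,
* six clustering methods configured to return two clusters,
* chance-corrected agreement measures between partitions, and
* three subsampling experiment designs with replicate and seed machinery.

# The generative model

`simulate_factor_cohort()` draws a genes x samples matrix in which samples
are cross-classified by three binary factors -- sex (male/female), age
(young/old) and subtype (A/B) -- and each factor perturbs its own disjoint
block of genes. For a non-affected gene, expression is
$x \sim N(0, \sigma^2)$; for a gene in a factor's block,

$$x \sim N(-\delta, \sigma^2) \text{ (male / young / type A)}, \qquad
  x \sim N(+\delta, \sigma^2) \text{ (female / old / type B)},$$

with defaults $\delta = 1$, $\sigma = 1$, 1000 genes, and 20 genes per
factor. Effects are additive on the simulated (log-like) scale and each
gene is affected by at most one factor; there are no interaction terms.
With balanced factors and `n_samples` divisible by 8 the cohort splits
into eight equally sized homogeneous groups; otherwise group sizes are
assigned round-robin, which is deterministic and near-balanced.

The `condition` field controls the gene set visible to the analyst:
`"All"` (three competing factors), `"Without"` (sex- and age-affected
genes removed, a single-factor problem), and `"Only"` (only the
subtype-affected genes, the ideal problem). The full matrix is generated
once and conditions are row-subsets, so under the same seed `"Only"` is
exactly a sub-matrix of `"All"`. Affected gene indices are re-drawn per
seed; since genes are exchangeable in the model, fixing them would give
statistically identical results.

`simulate_tcga_like()` reuses the same block architecture as a stand-in
for a real tumor cohort. Its defaults -- 1200 genes with 100 subtype-, 60
sex- and 40 age-affected genes at effect size 1 -- were chosen once to
emulate cohorts in which the known subtypes carry a strong, supervisedly
separable signal while sex and age contribute real but weaker structure.
For experiments that specifically probe sex heterogeneity we simulate a
cohort with a sex block as large as the subtype block (100/100): a
pronounced sex effect is the condition that design exists to study.

**What the simulator does not emulate.** Values are Gaussian on a
log-like scale: there is no count noise, no library-size or
sequencing-depth variation, and no mean-variance relationship. Genes are
independent given the factors, so co-expression modules, pathway
correlation structure and technical batch effects are absent, and every
affected gene has the same effect size. Tests passing on these cohorts
demonstrate that the machinery is correct and that the qualitative
mechanisms (heterogeneity hurts, imbalance hurts, homogeneous subsets
help) operate as designed -- not that any particular method will perform
identically on real tumor data.

# Pre-processing

Expression values are assumed non-negative on the raw scale and are
log2-transformed with a pseudocount: `log2(x + 1)` by default, since
normalized abundance estimates can be exactly zero. Two gene filters are
then applied, in order:

1. genes with standard deviation exactly 0 across samples are removed;
2. genes for which strictly more than 75% of samples lie below the 15th
   percentile of the pooled value distribution are removed.

The percentile is computed globally over all entries of the matrix (after
rule 1), using the linear-interpolation quantile convention. A per-gene
reference distribution would make the rule degenerate -- roughly 15% of
each gene's own values are below its own 15th percentile by construction
-- so the global reading is used; the threshold fraction and percentile
are both exposed as arguments. A gene failing both rules is tallied once,
under the zero-SD rule. The filter is idempotent and invariant to row and
column order.

# Feature selection and extraction

Five canonical selections define one axis of the evaluation grid: the top
100 or top 1000 genes by standard deviation, all genes, and the first 5
or 30 principal components. Standard deviations use the $n-1$
denominator; ties are broken by original row order so selection is
deterministic. PCA treats samples as observations, centers but does not
scale variables (the conventional default; scaling is available via a
flag), and fixes component signs so that each component's
largest-magnitude gene loading is positive -- PC signs are otherwise
arbitrary and would differ across platforms. PCA operates on the full
filtered matrix, not on a pre-selected subset, because feature extraction
is an alternative to gene selection, not a refinement of it.

# Clustering methods

All six methods are run so that exactly two clusters result ($k = 2$
throughout; there is no automatic selection of $k$).

* **hclust(M), hclust(cor)** -- agglomerative clustering with Ward's
  linkage on the Manhattan distance or on the absolute Pearson
  correlation distance $d(x,y) = 1 - |\rho(x,y)|$, cut at two clusters.
  Two Ward variants are exposed (`ward.D2`, the default, squares the
  dissimilarities inside the Lance-Williams update; `ward.D` does not)
  because historical software defaults differ.
* **k-means** -- Lloyd fixed-point iterations from 10 random starts,
  keeping the run with the smallest within-cluster sum of squares
  $\sum_i \sum_{x \in S_i} \lVert x - \mu_i \rVert^2$. Lloyd was chosen
  for its simple fixed-point contract; on well-separated data the
  multi-start minimum makes the difference from Hartigan-Wong immaterial.
  Starts that collapse to an empty cluster are repaired by re-seeding the
  offending center with the farthest sample.
* **SOM** -- an online self-organizing map on a two-node grid, trained for
  1000 presentations of the data with the learning rate decaying linearly
  from 0.05 to 0.01 (a common package default; the neighborhood radius is
  immaterial for two nodes, where updates are winner-only). Training is
  repeated 10 times and the run with the lowest within-variation is kept;
  samples join the cluster of their nearest codebook vector.
* **Affinity propagation** -- responsibility/availability message passing
  with damping 0.9, at most 2000 iterations, convergence declared after
  200 iterations of a stable exemplar set, and no noise jitter, on
  similarities defined as negative unsquared Euclidean distances (the
  squared variant is available via a flag). The shared exemplar
  preference is searched by bisection, starting from the interval between
  the minimum and the median similarity, until exactly $k$ exemplars
  emerge. On realistic data the minimum similarity can still yield more
  than $k$ exemplars, so the lower bound is extended geometrically (a
  bounded number of times) before bisection; if $k$ still cannot be
  bracketed, the method raises an error rather than returning a partition
  with the wrong number of clusters.
* **Cluster ensemble** -- a hard Euclidean least-squares consensus over
  the other five methods' partitions *within the same selection* (so the
  canonical grid is 5 selections x 6 methods = 30 approaches). The
  consensus minimizes the total squared distance between membership
  matrices after optimal per-input label matching; label matching is
  solved exactly (both swaps for $k = 2$, full permutation enumeration
  for small $k$), and the relabel-then-reassign fixed point is restarted
  from every input partition plus 10 random partitions, keeping the best
  objective. Reassignment ties go to the smallest label.

A method that collapses to fewer than $k$ non-empty clusters is flagged
degenerate rather than rejected; downstream ARIs are computed as-is and
the flag is carried through the result records.

# Agreement measures

The adjusted Rand index is computed from the contingency table
$[n_{ij}]$ of the two partitions with margins $a_j$, $b_i$:

$$\mathrm{ARI} =
 \frac{\sum_{ij}\binom{n_{ij}}{2} -
       \sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}/\binom{n}{2}}
      {\tfrac12\!\left[\sum_i\binom{a_i}{2}+\sum_j\binom{b_j}{2}\right] -
       \sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}/\binom{n}{2}}.$$

It is 1 iff the partitions coincide up to relabeling, has expectation 0
under random labelings with fixed margins, and can be negative. The
binomial sums are accumulated before the single final division, so no
catastrophic cancellation occurs. When the denominator is exactly zero
(both partitions all singletons, or both a single cluster) the value is
defined as 1 if the partitions coincide up to relabeling and 0 otherwise,
and the result carries a `degenerate` attribute. `apari()` averages the
ARI over all unordered pairs of a set of partitions, quantifying how
similarly different approaches cluster the same samples. The variation of
information $VI = H(A) + H(B) - 2I(A;B)$ uses natural logarithms (the
measure is defined up to a base; the base is a documented constant here)
and is a true metric on partitions.

# Experiment designs

All designs subsample without replacement, re-apply the gene filters and
the feature selection *within* each subsample (re-use of globally derived
features would leak information across conditions and break the
unsupervised contract), cluster with every approach, and score against
the subtype gold standard. At most 70% of each stratum may be drawn, so
small strata are never resampled nearly in full. Subtype-1 counts are
`round(n * fraction)` with halves rounded up and the remainder assigned
to subtype 2. A master seed spawns per-replicate child seeds as
`seed + replicate`, making every run a pure function of (data, design,
seed). Approaches using 30 principal components are recorded as skipped
when a condition has fewer than 30 samples; per-record failures are
logged with their condition coordinates and never abort a grid.

* **Sample-size sweep**: `n` varies at a fixed subtype fraction (default
  50/50).
* **Distribution sweep**: the subtype-1 fraction varies (e.g. 10% to 50%)
  at fixed `n`.
* **Sex-homogeneity design**: per replicate, three arms of equal size and
  balanced subtypes -- females only, males only, and a 50/50 mixed arm.
  The mixed arm is clustered on all samples but scored on all samples,
  on its female subset and on its male subset (restricting both the
  cluster labels and the gold standard), giving the five strata
  `Females, Males, Mixed_all, Mixed_females, Mixed_males`.

Replicate-averaged comparisons use the one-sample Wilcoxon signed-rank
test on per-approach ARI differences (two-sided; the exact distribution
with at most 25 non-zero differences, otherwise the normal approximation
with continuity correction), reporting the median difference and the
p-value; apARI contrasts use the rank-sum test. Per-approach ARIs are
averaged over replicates *before* pairing; averaging after pairing is
possible by calling the test per replicate, and neither ordering is
asserted to be canonical.

The simulation study (`simulation_study()`) is deliberately simpler than
the approach grid: each simulated cohort is clustered by agglomerative
hierarchical clustering with Manhattan distance and *complete* linkage,
cut at two clusters, under the three gene conditions, and the mean ARI
against the subtype partition is reported per condition and sample size
with its Monte-Carlo standard error.

# Problem sizes used by the test suite

The suite exercises the designs at sizes chosen to make the qualitative
effects detectable with comfortable Monte-Carlo margins: the simulation
study runs 100 cohorts per sample size at $n \in \{40, 160\}$; the
distribution sweep uses a 400-sample simulated cohort, `n = 100`, 10
replicates and fractions 10% vs 50%; the sex-homogeneity design uses 36
samples per arm and 5 replicates on a cohort with a pronounced sex
effect. Formula-level checks (ARI against a brute-force pair
classification, consensus against exhaustive enumeration over all
2-group labelings of 8 samples) are exact.

# Known limitations

* The simulator's independence and Gaussianity assumptions (above) mean
  absolute ARI levels are not transferable to real cohorts; only relative
  orderings across conditions are meaningful.
* Consensus label matching enumerates permutations and is limited to
  $k \le 8$; the evaluation framework only ever uses $k = 2$.
* The affinity-propagation preference search targets an exact exemplar
  count; data whose similarity structure never yields exactly $k$
  exemplars at any shared preference cause a recorded per-record failure.
* No survival modelling, no automatic choice of $k$, and no supervised
  separability scoring are provided; the framework evaluates partitions
  against a known gold standard only.
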