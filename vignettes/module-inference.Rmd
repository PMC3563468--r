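---
title: "Inferring gene regulatory modules with TF decision trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene regulatory modules with TF decision trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gremod)
```

## The model

gremod models a *regulatory module* as a set of co-expressed genes together
with a binary *regulatory decision tree* that explains their expression
across experimental conditions. Internal tree nodes query the discretized
expression level of a candidate transcription factor (TF) — "is this TF
highly expressed (+1) under the condition?" or "lowly expressed (−1)?" — and
each root-to-leaf path is one combinatorial TF state. The leaves therefore
partition the conditions into subgroups $S_1, \dots, S_m$, and within
subgroup $S_k$ the expression of every member gene is modeled as
Gaussian with mean $\mu_k$ and standard deviation $\sigma_k$.

The log-likelihood of gene $g_i$ with profile $x_{ij}$ under a tree is

$$ l(g_i) = \sum_{k=1}^{m} \sum_{j \in S_k}
   \left[ -\frac{(x_{ij} - \mu_k)^2}{2\sigma_k^2} - \ln \sigma_k \right], $$

i.e. the normal log-density with the constant $-\tfrac12\ln 2\pi$ dropped.
Because every tree covers the same conditions, the dropped constant is
identical across trees and cannot change any comparison. A module's
log-likelihood $l(M)$ is the sum of $l(g_i)$ over its members. The model
treats conditions as independent given the leaf — expression co-variation
beyond what the tree captures is not modeled — and assumes a TF's activity is
readable from its own transcript level, which ignores post-translational
regulation such as phosphorylation.

## The procedure

1. **DEG selection.** Genes whose normalized log-expression exceeds the
   threshold (default 3) in absolute value, strictly, in at least one
   condition are retained. Values exactly at the threshold are excluded.
2. **TF discretization.** Each candidate TF's profile is clustered into 2 or
   3 levels by exact one-dimensional K-means; it gets 3 levels exactly when
   the profile contains values above the threshold, below its negative, and
   in between, otherwise 2. Clusters are relabeled by ascending centroid;
   with two levels the pair is {0,+1} when both centroids are non-negative,
   {−1,0} when both are non-positive, and {−1,+1} otherwise, preserving the
   high/normal/low sign semantics. Constant-profile TFs cannot split
   anything and are dropped with a warning.
3. **Initial clustering.** DEGs are clustered with K-means (best of several
   restarts by within-cluster SSE). The number of clusters is either fixed
   (100 at the scale of a ~10k-gene stress compendium) or chosen by the knee
   of the (mean cluster size, mean within-cluster correlation) curve.
4. **Iterative refinement.** For every cluster a tree is grown greedily:
   each node takes the (TF, level) split with the highest summed Gaussian
   log-likelihood of the two resulting condition subgroups, with leaf
   parameters fit by pooling all member-gene values (population standard
   deviation). Then every gene is reassigned to the tree maximizing $l(g_i)$
   with leaf parameters frozen. The two steps alternate until no gene moves.
5. **Validation.** Module coherence is the mean Pearson correlation over all
   gene pairs; function-term enrichment uses the upper-tail hypergeometric
   test with Benjamini–Hochberg correction; promoter windows (500 bp
   upstream of the start codon) can be exported as FASTA for external motif
   discovery (MEME-style, widths 6–18 nt, site p < 0.001).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `threshold` | 3 | DEG cutoff on the normalized log scale; also sets the TF level categories |
| `max_depth` | 5 | depth cap on trees — regulatory trees typically carry one to five TF levels |
| `min_leaf_conditions` | 2 | nodes at or below this many conditions are not split |
| `min_gain` | 0 | minimum log-likelihood improvement a split must deliver; stands in for the qualitative "similar enough" stopping idea |
| `window` | 500 bp | promoter window upstream of the start codon |
| `seed` | 0 | single seed fanned out to every stochastic step |

## Numerical and design choices

* **Variance floor.** Leaf $\sigma$ is clamped below at $10^{-4}$ so
  zero-variance leaves stay finite and likelihoods comparable. The
  population (1/n) standard deviation is used so single-condition leaves are
  well defined.
* **Exact 1-D K-means.** TF discretization solves the 1-D problem exactly by
  dynamic programming over contiguous partitions of the sorted values; 1-D
  optima are contiguous, so this removes all initialization nondeterminism
  from the discretization.
* **Knee operationalization.** The "knee" of the size/correlation trade-off
  is the grid point with maximum perpendicular distance to the chord joining
  the curve's endpoints. Both axes are rescaled to [0, 1] first — mean size
  is O(100) while correlation is O(1), and without rescaling the distance
  would be dominated by the size axis. Ties break toward the smallest k.
* **Monotone ascent.** Reassignment under frozen parameters and leaf-wise
  refitting both maximize the shared objective, but a greedy *rebuild* of a
  tree is not guaranteed to match the previous structure's likelihood on the
  new member set. The fit therefore keeps the incumbent tree (parameters
  refit) whenever the greedy rebuild scores lower; the per-iteration total
  log-likelihood trace is then non-decreasing and the loop must terminate.
* **Tie-breaks.** Equal-scoring splits resolve by TF id (lexicographic),
  queried level +1 first; equal gene-to-tree likelihoods resolve to the
  lowest tree index. Together with the single top-level seed this makes runs
  bit-reproducible.
* **Level-0 queries.** A node may query only +1 or −1; "normally expressed"
  conditions always fall to the no-branch. Splitting directly on level 0 is
  representable in principle but not part of the query vocabulary here.
* **Self-regulation.** A TF may appear in the tree of the cluster containing
  its own gene; `self_exclude = TRUE` disables this.
* **Empty clusters** after reassignment are dropped rather than reseeded, so
  the module count can shrink below the initial k.
* **Coordinates.** Condition and gene indices are 1-based internally and in
  the JSON tree serialization, the natural convention in R; external
  identifiers are opaque strings carried alongside. GFF3 input coordinates
  (1-based inclusive) are converted to 0-based half-open forward-strand
  coordinates in promoter output, stated explicitly to prevent off-by-one
  drift. Upstream windows anchor at the first CDS start when CDS features
  exist, else at the gene feature's 5′ end, and truncate at contig edges.

## What the synthetic generator emulates — and what it does not

`generate_regulatory_data()` inverts the likelihood model into a sampler:
random discrete TF level vectors, a random decision tree per module with
non-empty leaves, leaf means drawn from a centered grid with a chosen
spacing, gene values drawn Normal(leaf mean, noise σ), and TF profiles equal
to `level × (threshold + 1)` plus a small uniform jitter so discretization
recovers the planted levels. Defaults (5 modules × 40 genes, 30 conditions,
10 TFs, leaf-mean separation 3, noise σ 1) describe a modest stress-response
compendium with clear but noisy modular structure — separation three times
the noise is the regime where condition subgroups are visibly distinct yet
individual values overlap.

Passing planted-recovery tests on this generator shows the estimator can
invert its own generative model; it does *not* show robustness to what real
arrays add: probe-level noise that is neither Gaussian nor homoscedastic,
TFs regulated post-translationally (flat transcripts, active protein),
overlapping module membership, and correlated replicate structure. Those
caveats are inherent to the model class, not to the implementation.

## A worked example

```{r example}
sim <- generate_regulatory_data(seed = 1)
tf_levels <- discretize_tf_matrix(sim$matrix, sim$tf_ids)
xd <- sim$matrix[names(sim$truth$module_labels), ]
init <- kmeans_cluster(xd, 5, seed = 1)
fit <- grn_fit(xd, tf_levels, init$labels)
fit
summarize_modules(fit)$report[, c("module_id", "n_genes", "n_tfs", "coherence")]
fit$modules[[1]]$tree
```

## Problem sizes and limitations

The shipped tests and the acceptance script run on deliberately small
problems: split-oracle checks on instances of up to 8 genes × 6 conditions ×
3 TFs (where exhaustive enumeration is feasible), ascent checks on one
hundred 24-gene datasets, and recovery checks at the generator defaults
(200 genes × 30 conditions). These sizes exercise every code path while
keeping the suite quick; the algorithms scale to array-compendium sizes
(10⁴ genes, dozens of conditions, 10³ TFs) since tree building is linear in
genes × conditions × TF candidates per node and reassignment is one
vectorized pass per tree.

Known limitations: greedy tree construction can miss globally better trees
(only the root split is provably optimal per step); likelihoods are
comparable only across trees covering identical condition sets; enrichment
treats annotations as fixed and ignores annotation uncertainty; and the
knee rule inherits K-means' sensitivity to the restart budget on hard
instances.
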