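# gremod — gene regulatory module inference via TF decision trees

Stress experiments on plant expression arrays perturb thousands of genes at
once; the question systems biologists ask is not just *which* genes move but
*which transcription factors (TFs) move them together*. gremod answers it by
inferring **regulatory modules**: sets of co-expressed, differentially
expressed genes paired with a **binary regulatory decision tree** whose
internal nodes query a TF's discretized expression level (+1 highly / −1
lowly expressed) and whose leaves are condition subgroups modeled as
Gaussians. It is aimed at anyone with a normalized genes × conditions
log-expression matrix and a candidate TF list — no raw-array processing is
done here.

## The model in brief

A tree partitions the conditions into subgroups S₁…Sₘ with parameters
(μₖ, σₖ) fit from the member genes. The log-likelihood of gene gᵢ under a
tree is

    l(gᵢ) = Σₖ Σ_{j∈Sₖ} [ −(xᵢⱼ − μₖ)² / (2σₖ²) − ln σₖ ]

(the normal log-density with the constant −½ln 2π dropped), and a module's
likelihood l(M) is the sum over its members. Fitting alternates:

1. **Tree building** — per cluster, greedily pick the (TF, level) condition
   split with the highest summed Gaussian log-likelihood; recurse to a depth
   cap (default 5 TF levels).
2. **Reassignment** — move every gene to the tree maximizing l(gᵢ), leaf
   parameters frozen.

until no gene moves. Upstream sit DEG selection (|x| > 3, strict), exact 1-D
K-means TF discretization into {−1, 0, +1}, and knee-based choice of the
initial K-means cluster count; downstream sit module coherence (mean
pairwise Pearson r), hypergeometric GO-term enrichment with BH correction,
and 500 bp promoter-window export for external motif tools (MEME-style).

## Worked example

```r
library(gremod)

sim <- generate_regulatory_data(seed = 1)        # 5 planted modules x 40 genes,
                                                 # 30 conditions, 10 TFs
tf_levels <- discretize_tf_matrix(sim$matrix, sim$tf_ids)
xd <- sim$matrix[names(sim$truth$module_labels), ]
init <- kmeans_cluster(xd, 5, seed = 1)
fit <- grn_fit(xd, tf_levels, init$labels)
fit
#> <grn_fit: 5 modules, 200 genes, converged after 1 iteration(s), total log-likelihood -3011.0590>

summarize_modules(fit)$report[, c("module_id", "n_genes", "n_tfs", "coherence")]
#>   module_id n_genes n_tfs coherence
#> 1      M001      40     8 0.9127137
#> 2      M002      40     9 0.9375548
#> 3      M003      40     8 0.8978151
#> 4      M004      40     9 0.8987071
#> 5      M005      40     7 0.8906544

fit$modules[[1]]$tree
#> <regulatory_tree: 30 conditions, 5 TF level(s), 16 leaves>
#>   TF03 == -1 ?
#>     TF05 == +1 ?
#>       TF09 == +1 ?
#>         leaf {30} mu=-4.63 sigma=0.876
#>         ...
```

Each module row reports how many genes ended up in the module, how many
distinct TFs its tree queries, and how tightly co-expressed the members are
(mean pairwise Pearson r; here ≈0.9, consistent with noise σ = 1 around
leaf means separated by 3). The printed tree reads top-down: conditions
where TF03 is lowly expressed flow to the yes-branch, and every
root-to-leaf path is one combinatorial TF state explaining the leaf's
condition subgroup.

The same workflow runs from a YAML config over TSV inputs:

```r
run_pipeline("config.yaml")   # or: Rscript inst/cli/gremod.R run --config config.yaml
```

writing `degs.txt`, `assignments.tsv`, `modules.json`, `trace.tsv`,
`report.tsv`, enrichment tables and per-module promoter FASTAs to the
configured output directory.

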