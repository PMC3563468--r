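# Independent oracles used across the suite. Everything here recomputes
# quantities from first principles, never through the package's own code
# paths, so agreement is evidence rather than tautology.

# Gaussian log-density sum with the -log(2*pi)/2 constant dropped.
oracle_leaf_ll <- function(values, mu, sigma) {
  total <- 0
  for (v in values) total <- total - (v - mu)^2 / (2 * sigma^2) - log(sigma)
  total
}

# Pooled leaf fit + log-likelihood for a cell block (population sd, floored).
oracle_pooled_ll <- function(x, gene_idx, cond_idx) {
  cells <- as.vector(x[gene_idx, cond_idx, drop = FALSE])
  mu <- sum(cells) / length(cells)
  s <- max(sqrt(sum((cells - mu)^2) / length(cells)), 1e-4)
  oracle_leaf_ll(cells, mu, s)
}

# Per-condition summation of a gene's log-likelihood under a tree: walks the
# leaves, locates each condition's leaf, and sums term by term.
oracle_gene_tree_ll <- function(profile, tree) {
  leaves <- tree_leaves(tree)
  total <- 0
  for (j in seq_along(profile)) {
    for (leaf in leaves) {
      if (j %in% leaf$conditions) {
        total <- total - (profile[j] - leaf$mu)^2 / (2 * leaf$sigma^2) -
          log(leaf$sigma)
        break
      }
    }
  }
  total
}

# Exhaustive enumeration of every (TF, queried level) condition split with
# both sides non-empty; returns the best score and all argmax splits.
oracle_best_split <- function(x, gene_idx, conditions, tf_levels) {
  best_score <- -Inf
  best <- list()
  for (tf in rownames(tf_levels)) {
    for (lv in c(1L, -1L)) {
      yes <- conditions[tf_levels[tf, conditions] == lv]
      no <- setdiff(conditions, yes)
      if (length(yes) == 0 || length(no) == 0) next
      s <- oracle_pooled_ll(x, gene_idx, yes) + oracle_pooled_ll(x, gene_idx, no)
      if (s > best_score + 1e-12) {
        best_score <- s
        best <- list(list(tf = tf, level = lv))
      } else if (abs(s - best_score) <= 1e-12) {
        best[[length(best) + 1L]] <- list(tf = tf, level = lv)
      }
    }
  }
  list(score = best_score, argmax = best)
}

# Upper-tail hypergeometric probability by direct combinatorial summation.
oracle_hyper_p <- function(N, K, n, a) {
  total <- 0
  for (i in a:min(n, K)) {
    total <- total + choose(K, i) * choose(N - K, n - i)
  }
  total / choose(N, n)
}

# Random regulatory tree over n_conditions with random partition leaves.
random_tree <- function(n_conditions, n_leaves) {
  cuts <- sort(sample(seq_len(n_conditions - 1), n_leaves - 1))
  bounds <- c(0, cuts, n_conditions)
  perm <- sample(n_conditions)
  leaves <- lapply(seq_len(n_leaves), function(i) {
    conds <- perm[(bounds[i] + 1):bounds[i + 1]]
    gremod:::new_subgroup(sort(conds), mu = rnorm(1, 0, 3),
                          sigma = runif(1, 0.2, 2))
  })
  # chain the leaves under dummy TF queries to form a valid binary tree
  node <- leaves[[n_leaves]]
  if (n_leaves > 1) {
    for (i in (n_leaves - 1):1) {
      node <- gremod:::new_tree_node(sprintf("TF%02d", i), 1L,
                                     leaves[[i]], node)
    }
  }
  regulatory_tree(node, n_conditions)
}

# Small random problem instance for split-oracle tests.
random_small_instance <- function() {
  n_genes <- sample(2:8, 1)
  n_cond <- sample(3:6, 1)
  n_tfs <- sample(1:3, 1)
  x <- matrix(rnorm(n_genes * n_cond, sd = 2), n_genes, n_cond,
              dimnames = list(sprintf("g%d", seq_len(n_genes)),
                              sprintf("c%d", seq_len(n_cond))))
  tf_levels <- matrix(sample(c(-1L, 0L, 1L), n_tfs * n_cond, replace = TRUE),
                      n_tfs, n_cond,
                      dimnames = list(sprintf("TF%02d", seq_len(n_tfs)),
                                      sprintf("c%d", seq_len(n_cond))))
  list(x = x, tf_levels = tf_levels)
}

# Write a small two-contig genome + GFF3 for promoter tests; returns paths
# and the raw contig strings for hand-computed expectations.
make_promoter_fixture <- function(dir) {
  set.seed(42)
  contig1 <- paste(sample(c("A", "C", "G", "T"), 700, replace = TRUE),
                   collapse = "")
  contig2 <- paste0(
    paste(sample(c("A", "C", "G", "T"), 96, replace = TRUE), collapse = ""),
    "ACGT")  # last four bases fixed
  fa <- file.path(dir, "genome.fa")
  writeLines(c(">chr1 test contig", contig1, ">chr2", contig2), fa)
  gff <- file.path(dir, "genes.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t501\t650\t.\t+\t.\tID=geneA",
    "chr1\ttest\tgene\t3\t120\t.\t+\t.\tID=geneB",
    "chr1\ttest\tgene\t200\t400\t.\t+\t.\tID=geneD",
    "chr1\ttest\tmRNA\t200\t400\t.\t+\t.\tID=geneD.t1;Parent=geneD",
    "chr1\ttest\tCDS\t260\t400\t.\t+\t0\tID=geneD.cds;Parent=geneD.t1",
    "chr2\ttest\tgene\t20\t96\t.\t-\t.\tID=geneC"), gff)
  list(fa = fa, gff = gff, contig1 = contig1, contig2 = contig2)
}

revcomp_str <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
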