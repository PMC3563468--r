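#' Generate synthetic expression data with planted regulatory modules
#'
#' Inverts the model the inference assumes into a sampler: discrete TF level
#' vectors are drawn per condition; each module gets a random regulatory
#' decision tree over those TFs (every node split keeps both sides
#' non-empty); each leaf is assigned a mean from a centered grid with spacing
#' `leaf_mean_separation`, shuffled per module; and each member gene's
#' expression in a condition is drawn Normal(leaf mean, `noise_sigma`). TF
#' genes are added to the matrix with continuous profiles
#' `level * (threshold + 1) + jitter`, so discretization recovers the planted
#' levels whenever `jitter < leaf_mean_separation / 4`.
#'
#' @param n_modules number of planted modules (default 5).
#' @param genes_per_module member genes per module (default 40).
#' @param n_conditions number of conditions (default 30; must be >=
#'   2^max_depth).
#' @param n_tfs number of candidate TFs (default 10; must be >= max_depth).
#' @param max_depth depth of the planted trees (default 2).
#' @param leaf_mean_separation spacing of the leaf-mean grid, log-expression
#'   units (default 3).
#' @param noise_sigma Gaussian noise standard deviation (default 1).
#' @param threshold DEG threshold the TF profiles are scaled against
#'   (default 3).
#' @param jitter amplitude of the uniform jitter on TF profiles
#'   (default 0.25).
#' @param seed integer seed; the output is fully reproducible.
#' @return list with `matrix` (expression matrix: target genes then TF
#'   genes), `tf_ids`, and `truth` (list: `module_labels` named integer
#'   vector over target genes, `trees` list of planted `regulatory_tree`s,
#'   `tf_levels` planted discrete levels, `root_tfs`, `noise_sigma`,
#'   `leaf_mean_separation`, `seed`).
#' @export
generate_regulatory_data <- function(n_modules = 5L, genes_per_module = 40L,
                                     n_conditions = 30L, n_tfs = 10L,
                                     max_depth = 2L,
                                     leaf_mean_separation = 3,
                                     noise_sigma = 1, threshold = 3,
                                     jitter = 0.25, seed = 0L) {
  if (n_tfs < max_depth)
    stop("n_tfs must be at least max_depth")
  if (n_conditions < 2^max_depth)
    stop("n_conditions must be at least 2^max_depth")
  if (n_modules < 1L || genes_per_module < 1L)
    stop("n_modules and genes_per_module must be positive")
  set.seed(seed)

  cond_ids <- sprintf("C%02d", seq_len(n_conditions))
  tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
  tf_levels <- matrix(sample(c(-1L, 0L, 1L), n_tfs * n_conditions,
                             replace = TRUE),
                      n_tfs, n_conditions,
                      dimnames = list(tf_ids, cond_ids))

  planted_sigma <- max(noise_sigma, SIGMA_FLOOR)

  random_structure <- function(conditions, depth) {
    if (depth < max_depth && length(conditions) >= 2L) {
      cands <- list()
      for (tf in tf_ids) for (lv in c(1L, -1L)) {
        yes <- conditions[tf_levels[tf, conditions] == lv]
        no <- setdiff(conditions, yes)
        if (length(yes) > 0L && length(no) > 0L)
          cands[[length(cands) + 1L]] <- list(tf, lv, yes, no)
      }
      if (length(cands) > 0L) {
        pick <- cands[[sample.int(length(cands), 1L)]]
        return(new_tree_node(pick[[1]], pick[[2]],
                             random_structure(pick[[3]], depth + 1L),
                             random_structure(pick[[4]], depth + 1L)))
      }
    }
    new_subgroup(sort(conditions), mu = NA_real_, sigma = planted_sigma)
  }

  assign_leaf_means <- function(node) {
    n_leaves <- 0L
    count <- function(nd) if (is_leaf(nd)) n_leaves <<- n_leaves + 1L else {
      count(nd$yes); count(nd$no)
    }
    count(node)
    means <- sample(leaf_mean_separation *
                      (seq_len(n_leaves) - (n_leaves + 1) / 2))
    i <- 0L
    fill <- function(nd) {
      if (is_leaf(nd)) {
        i <<- i + 1L
        new_subgroup(nd$conditions, means[i], planted_sigma)
      } else new_tree_node(nd$tf_id, nd$queried_level,
                           fill(nd$yes), fill(nd$no))
    }
    fill(node)
  }

  trees <- lapply(seq_len(n_modules), function(m) {
    regulatory_tree(assign_leaf_means(random_structure(seq_len(n_conditions), 0L)),
                    n_conditions, cond_ids)
  })

  n_genes <- n_modules * genes_per_module
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  labels <- rep(seq_len(n_modules), each = genes_per_module)
  names(labels) <- gene_ids
  x <- matrix(NA_real_, n_genes, n_conditions,
              dimnames = list(gene_ids, cond_ids))
  for (m in seq_len(n_modules)) {
    mu_vec <- tree_condition_params(trees[[m]])["mu", ]
    rows <- which(labels == m)
    x[rows, ] <- matrix(stats::rnorm(length(rows) * n_conditions,
                                     mean = rep(mu_vec, each = length(rows)),
                                     sd = noise_sigma),
                        length(rows), n_conditions)
  }

  tf_x <- tf_levels * (threshold + 1) +
    matrix(stats::runif(n_tfs * n_conditions, -jitter, jitter),
           n_tfs, n_conditions)
  rownames(tf_x) <- tf_ids
  colnames(tf_x) <- cond_ids

  list(matrix = rbind(x, tf_x),
       tf_ids = tf_ids,
       truth = list(module_labels = labels,
                    trees = trees,
                    tf_levels = tf_levels,
                    root_tfs = vapply(trees, function(t)
                      if (is_leaf(t$root)) NA_character_ else t$root$tf_id,
                      character(1)),
                    noise_sigma = noise_sigma,
                    leaf_mean_separation = leaf_mean_separation,
                    seed = seed))
}

#' Generate a planted annotation table for enrichment validation
#'
#' Each planted module gets one dedicated term annotated on a fixed fraction
#' of its member genes; additional noise terms are annotated gene-wise at a
#' background rate, so every module carries one planted positive over a null
#' background.
#'
#' @param truth the `truth` component of [generate_regulatory_data()].
#' @param enriched_term_fraction fraction of each module's genes carrying its
#'   planted term, in (0, 1] (default 0.8).
#' @param background_rate per-gene probability of carrying each noise term
#'   (default 0.05).
#' @param n_noise_terms number of noise terms (default 5).
#' @param seed integer seed.
#' @return an `annotation_table` whose background is the set of target genes;
#'   planted terms are named `PLANT_M<module>`.
#' @export
generate_annotations <- function(truth, enriched_term_fraction = 0.8,
                                 background_rate = 0.05, n_noise_terms = 5L,
                                 seed = 0L) {
  if (enriched_term_fraction <= 0 || enriched_term_fraction > 1)
    stop("enriched_term_fraction must be in (0, 1]")
  set.seed(seed)
  genes <- names(truth$module_labels)
  if (length(genes) == 0L)
    return(annotation_table(character(), character(),
                            background = character()))
  g <- character(); t <- character()
  for (m in sort(unique(truth$module_labels))) {
    members <- genes[truth$module_labels == m]
    n_hit <- max(1L, round(enriched_term_fraction * length(members)))
    hits <- sample(members, n_hit)
    g <- c(g, hits)
    t <- c(t, rep(sprintf("PLANT_M%d", m), n_hit))
  }
  for (j in seq_len(n_noise_terms)) {
    hits <- genes[stats::runif(length(genes)) < background_rate]
    g <- c(g, hits)
    t <- c(t, rep(sprintf("NOISE_T%d", j), length(hits)))
  }
  annotation_table(g, t, background = genes)
}
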