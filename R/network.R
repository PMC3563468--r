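# Pooled Gaussian log-likelihood of a cell block under its own fitted
# (mu, sigma): the score contribution of one condition subgroup.
pooled_leaf_loglik <- function(x, gene_idx, cond_idx) {
  sg <- subgroup_fit(x, gene_idx, cond_idx)
  cells <- x[gene_idx, cond_idx, drop = FALSE]
  sum(-(cells - sg$mu)^2 / (2 * sg$sigma^2)) - length(cells) * log(sg$sigma)
}

resolve_gene_idx <- function(x, cluster_genes) {
  if (is.character(cluster_genes)) {
    idx <- match(cluster_genes, rownames(x))
    if (anyNA(idx)) stop("cluster gene id(s) absent from the expression matrix")
    idx
  } else as.integer(cluster_genes)
}

#' Enumerate candidate condition splits at a tree node
#'
#' A TF splits a set of conditions into the conditions where its discrete
#' level equals the queried level (+1 or -1, the yes side) versus all others.
#' For each TF there are up to two candidates (one per queried level);
#' candidates with an empty side are omitted. Each candidate is scored by
#' [score_split()]. Candidates are ordered by TF id (lexicographic), queried
#' level +1 before -1 — the tie-break order used by [build_tree()].
#'
#' @param x expression matrix.
#' @param cluster_genes gene ids or row indices of the cluster's members.
#' @param conditions integer vector of condition column indices at this node.
#' @param tf_levels integer matrix of discrete TF levels (TFs x all
#'   conditions), as from [discretize_tf_matrix()].
#' @return list of candidate splits: `tf_id`, `queried_level`,
#'   `yes_conditions`, `no_conditions`, `score`. May be empty.
#' @export
enumerate_splits <- function(x, cluster_genes, conditions, tf_levels) {
  if (length(conditions) == 0L) stop("conditions must be non-empty")
  gene_idx <- resolve_gene_idx(x, cluster_genes)
  tf_ids <- rownames(tf_levels)
  if (is.null(tf_ids)) tf_ids <- character()
  out <- list()
  for (tf in tf_ids[order(tf_ids, method = "radix")]) {
    lv_here <- tf_levels[tf, conditions]
    for (lv in c(1L, -1L)) {
      yes <- conditions[lv_here == lv]
      no <- conditions[lv_here != lv]
      if (length(yes) == 0L || length(no) == 0L) next
      cand <- list(tf_id = tf, queried_level = lv,
                   yes_conditions = yes, no_conditions = no)
      cand$score <- score_split(x, gene_idx, cand)
      out[[length(out) + 1L]] <- cand
    }
  }
  out
}

#' Score a candidate condition split
#'
#' Fits a Gaussian (mu, sigma) to each side of the split from the cluster
#' genes' expression values there, and returns the summed Gaussian
#' log-likelihood of all member-gene values over both sides.
#'
#' @param x expression matrix.
#' @param cluster_genes gene ids or row indices of the cluster's members.
#' @param split list with `yes_conditions` and `no_conditions` (both
#'   non-empty integer vectors of condition indices).
#' @return scalar log-likelihood score.
#' @export
score_split <- function(x, cluster_genes, split) {
  if (length(split$yes_conditions) == 0L || length(split$no_conditions) == 0L)
    stop("both sides of a split must be non-empty")
  gene_idx <- resolve_gene_idx(x, cluster_genes)
  pooled_leaf_loglik(x, gene_idx, split$yes_conditions) +
    pooled_leaf_loglik(x, gene_idx, split$no_conditions)
}

#' Build a regulatory decision tree for a gene cluster
#'
#' Greedy recursive construction: at each node the best-scoring candidate
#' split (over all TFs and queried levels) is taken and both sides are split
#' further. Recursion stops when the depth cap is reached, when the node holds
#' no more than `min_leaf_conditions` conditions, when no candidate splits
#' exist, or when the best split improves on the unsplit leaf's log-likelihood
#' by less than `min_gain`. Leaf (mu, sigma) are fit from the cluster members'
#' values in the leaf's conditions.
#'
#' @param x expression matrix.
#' @param cluster_genes gene ids or row indices of the cluster's members
#'   (non-empty).
#' @param tf_levels integer matrix of discrete TF levels (TFs x conditions).
#' @param max_depth maximum number of TF levels (default 5).
#' @param min_leaf_conditions do not split nodes at or below this many
#'   conditions (default 2).
#' @param min_gain minimum log-likelihood improvement required to split
#'   (default 0).
#' @param self_exclude if TRUE, TFs that are themselves members of the cluster
#'   are not used as split candidates (default FALSE).
#' @return a `regulatory_tree` covering all conditions of `x`.
#' @export
build_tree <- function(x, cluster_genes, tf_levels, max_depth = 5L,
                       min_leaf_conditions = 2L, min_gain = 0,
                       self_exclude = FALSE) {
  gene_idx <- resolve_gene_idx(x, cluster_genes)
  if (length(gene_idx) == 0L) stop("cluster must be non-empty")
  if (max_depth < 0L) stop("max_depth must be >= 0")
  if (self_exclude && !is.null(rownames(tf_levels))) {
    keep <- !(rownames(tf_levels) %in% rownames(x)[gene_idx])
    tf_levels <- tf_levels[keep, , drop = FALSE]
  }
  tf_ids <- rownames(tf_levels)
  if (is.null(tf_ids)) tf_ids <- character()
  tf_ids_sorted <- tf_ids[order(tf_ids, method = "radix")]

  grow <- function(conditions, depth) {
    leaf <- subgroup_fit(x, gene_idx, conditions)
    if (depth >= max_depth || length(conditions) <= min_leaf_conditions)
      return(leaf)
    leaf_score <- pooled_leaf_loglik(x, gene_idx, conditions)
    best <- NULL
    for (tf in tf_ids_sorted) {
      lv_here <- tf_levels[tf, conditions]
      for (lv in c(1L, -1L)) {
        yes <- conditions[lv_here == lv]
        no <- conditions[lv_here != lv]
        if (length(yes) == 0L || length(no) == 0L) next
        s <- pooled_leaf_loglik(x, gene_idx, yes) +
          pooled_leaf_loglik(x, gene_idx, no)
        if (is.null(best) || s > best$score)
          best <- list(tf_id = tf, queried_level = lv, yes = yes, no = no,
                       score = s)
      }
    }
    if (is.null(best) || best$score - leaf_score < min_gain)
      return(leaf)
    new_tree_node(best$tf_id, best$queried_level,
                  grow(best$yes, depth + 1L),
                  grow(best$no, depth + 1L))
  }

  regulatory_tree(grow(seq_len(ncol(x)), 0L), ncol(x), colnames(x))
}

# Refit leaf parameters of an existing tree structure to a new member set.
refit_tree_params <- function(tree, x, gene_idx) {
  walk <- function(node) {
    if (is_leaf(node)) subgroup_fit(x, gene_idx, node$conditions)
    else new_tree_node(node$tf_id, node$queried_level,
                       walk(node$yes), walk(node$no))
  }
  regulatory_tree(walk(tree$root), tree$n_conditions, tree$condition_ids)
}

# Summed log-likelihood of a gene set under one tree.
tree_score <- function(x, gene_idx, tree) {
  p <- tree_condition_params(tree)
  cells <- x[gene_idx, , drop = FALSE]
  dev <- sweep(cells, 2L, p["mu", ])
  sum(sweep(dev^2, 2L, -2 * p["sigma", ]^2, "/")) -
    length(gene_idx) * sum(log(p["sigma", ]))
}

#' Reassign genes to their maximum-likelihood regulatory trees
#'
#' Each gene is assigned to the tree under which its full expression profile
#' has the highest log-likelihood ([gene_tree_loglik()]); ties break toward
#' the lowest tree index. Leaf parameters are frozen during reassignment.
#'
#' @param x expression matrix.
#' @param trees non-empty list of `regulatory_tree`s, all covering the
#'   conditions of `x`.
#' @return named integer vector: tree index per gene.
#' @export
reassign_genes <- function(x, trees) {
  if (length(trees) == 0L) stop("at least one tree is required")
  nc <- vapply(trees, `[[`, integer(1), "n_conditions")
  if (any(nc != ncol(x)))
    stop("all trees must cover the same condition set as the matrix")
  ll <- genes_trees_loglik(x, trees)
  assign <- max.col(ll, ties.method = "first")
  names(assign) <- rownames(x)
  assign
}

#' Fit gene regulatory modules by iterative tree building and reassignment
#'
#' Alternates (1) building a regulatory decision tree per cluster
#' ([build_tree()]) and (2) reassigning every gene to its maximum-likelihood
#' tree ([reassign_genes()]) until the assignment no longer changes or
#' `max_iterations` is reached. When a greedy rebuild scores below the
#' cluster's previous tree refit to the current members, the previous tree is
#' retained, so the total log-likelihood trace is non-decreasing. Clusters
#' emptied by reassignment are dropped (k may shrink).
#'
#' @param x expression matrix restricted to the genes being modeled (e.g. the
#'   DEGs).
#' @param tf_levels integer matrix of discrete TF levels (TFs x conditions).
#' @param initial_labels named integer cluster labels covering every row of
#'   `x` (e.g. `kmeans_cluster(x, k)$labels`).
#' @param max_depth,min_leaf_conditions,min_gain,self_exclude tree-building
#'   controls, see [build_tree()].
#' @param max_iterations iteration cap (default 50).
#' @param verbose print per-iteration progress (default FALSE).
#' @return object of class `grn_fit`: list with `modules` (each: `module_id`,
#'   `gene_ids`, `tree`, `coherence`, `log_likelihood`), `assignments` (named
#'   module index per gene), `n_iterations`, `total_log_likelihood`,
#'   `converged`, and `trace` (data.frame: iteration, total_log_likelihood).
#' @export
grn_fit <- function(x, tf_levels, initial_labels, max_depth = 5L,
                    min_leaf_conditions = 2L, min_gain = 0,
                    max_iterations = 50L, self_exclude = FALSE,
                    verbose = FALSE) {
  validate_expression_matrix(x)
  if (is.null(names(initial_labels)) ||
      !setequal(names(initial_labels), rownames(x)))
    stop("initial_labels must be named and cover every gene in the matrix")
  labels <- as.integer(initial_labels[rownames(x)])
  names(labels) <- rownames(x)
  occ <- sort(unique(labels))
  labels <- stats::setNames(match(labels, occ), names(labels))

  prev_trees <- NULL
  trace_ll <- numeric()
  it <- 0L
  converged <- FALSE
  repeat {
    it <- it + 1L
    k <- max(labels)
    trees <- vector("list", k)
    scores <- numeric(k)
    for (cl in seq_len(k)) {
      gene_idx <- which(labels == cl)
      t_new <- build_tree(x, gene_idx, tf_levels, max_depth = max_depth,
                          min_leaf_conditions = min_leaf_conditions,
                          min_gain = min_gain, self_exclude = self_exclude)
      s_new <- tree_score(x, gene_idx, t_new)
      if (!is.null(prev_trees) && !is.null(prev_trees[[cl]])) {
        t_old <- refit_tree_params(prev_trees[[cl]], x, gene_idx)
        s_old <- tree_score(x, gene_idx, t_old)
        if (s_old > s_new) { t_new <- t_old; s_new <- s_old }
      }
      trees[[cl]] <- t_new
      scores[cl] <- s_new
    }
    trace_ll <- c(trace_ll, sum(scores))
    if (verbose)
      message(sprintf("iteration %d: %d clusters, total log-likelihood %.4f",
                      it, k, sum(scores)))
    if (it >= max_iterations) break
    new_labels <- reassign_genes(x, trees)
    if (identical(unname(new_labels), unname(labels))) {
      converged <- TRUE
      break
    }
    occ <- sort(unique(new_labels))
    if (length(occ) < k && verbose)
      message(sprintf("iteration %d: %d cluster(s) emptied and dropped",
                      it, k - length(occ)))
    labels <- stats::setNames(match(new_labels, occ), names(new_labels))
    prev_trees <- trees[occ]
  }

  modules <- lapply(seq_len(max(labels)), function(cl) {
    ids <- names(labels)[labels == cl]
    list(module_id = sprintf("M%03d", cl),
         gene_ids = ids,
         tree = trees[[cl]],
         coherence = if (length(ids) >= 2L)
           mean_pairwise_correlation(x, ids, warn_zero_variance = FALSE)
         else NA_real_,
         log_likelihood = scores[cl])
  })
  structure(list(modules = modules,
                 assignments = labels,
                 n_iterations = it,
                 total_log_likelihood = sum(scores),
                 converged = converged,
                 trace = data.frame(iteration = seq_along(trace_ll),
                                    total_log_likelihood = trace_ll)),
            class = "grn_fit")
}

#' @export
print.grn_fit <- function(x, ...) {
  cat(sprintf("<grn_fit: %d modules, %d genes, %s after %d iteration(s), total log-likelihood %.4f>\n",
              length(x$modules), length(x$assignments),
              if (x$converged) "converged" else "not converged",
              x$n_iterations, x$total_log_likelihood))
  invisible(x)
}

#' Write the artifacts of a fit to a directory
#'
#' Writes `modules.json` (gene lists, trees, coherence, log-likelihoods),
#' `assignments.tsv` (gene_id, module_id) and `trace.tsv` (iteration, total
#' log-likelihood).
#'
#' @param fit a `grn_fit`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fit_outputs <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mods <- lapply(fit$modules, function(m) {
    list(module_id = m$module_id, gene_ids = m$gene_ids,
         coherence = m$coherence, log_likelihood = m$log_likelihood,
         tree = tree_to_list(m$tree))
  })
  jsonlite::write_json(mods, file.path(dir, "modules.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  module_ids <- vapply(fit$modules, `[[`, character(1), "module_id")
  utils::write.table(
    data.frame(gene_id = names(fit$assignments),
               module_id = module_ids[fit$assignments],
               stringsAsFactors = FALSE),
    file.path(dir, "assignments.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit$trace, file.path(dir, "trace.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
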