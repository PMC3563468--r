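#' gremod: gene regulatory module inference via TF decision trees
#'
#' Starting from differentially expressed genes, gremod alternates two steps
#' until gene assignments stabilize: it builds, for each gene cluster, a binary
#' regulatory decision tree whose internal nodes query the discretized
#' expression level of a transcription factor (TF) and whose leaves are
#' condition subgroups modeled as Gaussians; and it reassigns every gene to the
#' tree under which its expression profile has maximum likelihood. Modules are
#' then validated by expression coherence and hypergeometric function-term
#' enrichment, and promoter windows can be exported for external motif tools.
#'
#' The main entry points are [run_pipeline()] for the full workflow and
#' [grn_fit()] for the core iterative algorithm. See the package vignette for
#' the model and its assumptions.
#'
#' @name gremod-package
#' @keywords internal
"_PACKAGE"

# Lower bound on leaf standard deviations: a zero-variance condition subgroup
# would otherwise make the Gaussian log-density infinite and likelihood
# comparisons meaningless.
SIGMA_FLOOR <- 1e-4

#' Validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix of normalized log-expression
#' values with genes as rows and experimental conditions as columns. Row and
#' column names are the (opaque, unique) gene and condition identifiers.
#'
#' @param x numeric matrix with unique, non-missing dimnames.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have gene ids as rownames and condition ids as colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(x)))
    stop("duplicate condition ids in expression matrix")
  if (any(rowSums(is.finite(x)) == 0))
    stop("every gene row must contain at least one finite value")
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expected layout: header row of condition ids, first column gene ids,
#' tab-separated numeric values.
#'
#' @param path path to a TSV file.
#' @return numeric matrix (genes x conditions) with dimnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- gene_ids
  validate_expression_matrix(m)
  m
}

#' Write an expression matrix to TSV
#'
#' @param x numeric matrix (genes x conditions) with dimnames.
#' @param path output path.
#' @export
write_expression_tsv <- function(x, path) {
  validate_expression_matrix(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gaussian log-likelihood of values under a leaf's parameters
#'
#' Computes the sum over values of the normal log-density with the constant
#' -log(2*pi)/2 dropped: sum_j ( -(x_j - mu)^2 / (2 sigma^2) - log(sigma) ).
#' Dropping the constant leaves all likelihood comparisons unaffected because
#' every tree covers the same number of conditions.
#'
#' @param values numeric vector of expression values (non-empty, finite).
#' @param mu leaf mean.
#' @param sigma leaf standard deviation (> 0).
#' @return scalar log-likelihood.
#' @export
gaussian_leaf_loglik <- function(values, mu, sigma) {
  if (length(values) == 0L || !all(is.finite(values)))
    stop("values must be non-empty and finite")
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be positive")
  sum(-(values - mu)^2 / (2 * sigma^2) - log(sigma))
}

#' Fit a condition subgroup (leaf) from matrix cells
#'
#' Pools the expression values of the selected genes across the selected
#' conditions and estimates the leaf mean and standard deviation. The
#' population (1/n) standard deviation is used so that single-cell leaves are
#' well defined, and sigma is clamped below at the variance floor (1e-4).
#'
#' @param x expression matrix.
#' @param gene_idx integer vector of gene row indices (non-empty).
#' @param cond_idx integer vector of condition column indices (non-empty).
#' @return a `condition_subgroup`: list with `conditions`, `mu`, `sigma`.
#' @export
subgroup_fit <- function(x, gene_idx, cond_idx) {
  if (length(gene_idx) == 0L || length(cond_idx) == 0L)
    stop("gene and condition index sets must be non-empty")
  cells <- x[gene_idx, cond_idx, drop = FALSE]
  mu <- mean(cells)
  sigma <- max(sqrt(mean((cells - mu)^2)), SIGMA_FLOOR)
  new_subgroup(sort(as.integer(cond_idx)), mu, sigma)
}

new_subgroup <- function(conditions, mu, sigma) {
  structure(list(conditions = as.integer(conditions), mu = mu, sigma = sigma),
            class = "condition_subgroup")
}

new_tree_node <- function(tf_id, queried_level, yes, no) {
  structure(list(tf_id = tf_id, queried_level = as.integer(queried_level),
                 yes = yes, no = no),
            class = "tree_node")
}

#' @export
print.condition_subgroup <- function(x, ...) {
  cat(sprintf("<leaf: %d conditions, mu=%.4g, sigma=%.4g>\n",
              length(x$conditions), x$mu, x$sigma))
  invisible(x)
}

is_leaf <- function(node) inherits(node, "condition_subgroup")

#' Construct a regulatory decision tree
#'
#' A regulatory tree is a binary tree whose internal nodes query a TF's
#' discretized expression level (+1 or -1) and whose leaves are condition
#' subgroups with Gaussian parameters. The leaves partition the full condition
#' set.
#'
#' @param root a `tree_node` or a single `condition_subgroup`.
#' @param n_conditions total number of conditions the tree covers.
#' @param condition_ids optional character vector of condition identifiers.
#' @return an object of class `regulatory_tree`.
#' @export
regulatory_tree <- function(root, n_conditions, condition_ids = NULL) {
  tree <- structure(list(root = root, n_conditions = as.integer(n_conditions),
                         condition_ids = condition_ids),
                    class = "regulatory_tree")
  validate_tree(tree)
  tree
}

#' Leaves of a regulatory tree
#'
#' @param tree a `regulatory_tree`.
#' @return list of `condition_subgroup` leaves, in left-to-right order.
#' @export
tree_leaves <- function(tree) {
  out <- list()
  walk <- function(node) {
    if (is_leaf(node)) out[[length(out) + 1L]] <<- node
    else { walk(node$yes); walk(node$no) }
  }
  walk(tree$root)
  out
}

#' TFs appearing in a regulatory tree
#'
#' @param tree a `regulatory_tree`.
#' @return character vector of unique TF identifiers (empty for a single-leaf
#'   tree).
#' @export
tree_tfs <- function(tree) {
  out <- character()
  walk <- function(node) {
    if (!is_leaf(node)) {
      out[[length(out) + 1L]] <<- node$tf_id
      walk(node$yes); walk(node$no)
    }
  }
  walk(tree$root)
  unique(out)
}

#' Depth (number of TF levels) of a regulatory tree
#'
#' @param tree a `regulatory_tree`.
#' @return integer: 0 for a single-leaf tree.
#' @export
tree_depth <- function(tree) {
  walk <- function(node) {
    if (is_leaf(node)) 0L else 1L + max(walk(node$yes), walk(node$no))
  }
  walk(tree$root)
}

#' Validate the partition invariant of a regulatory tree
#'
#' Checks that the leaf condition sets are disjoint, non-empty, and together
#' cover exactly the conditions 1..n_conditions, and that every leaf sigma is
#' at or above the variance floor.
#'
#' @param tree a `regulatory_tree`.
#' @return `tree`, invisibly.
#' @export
validate_tree <- function(tree) {
  leaves <- tree_leaves(tree)
  conds <- unlist(lapply(leaves, `[[`, "conditions"))
  if (any(vapply(leaves, function(l) length(l$conditions) == 0L, logical(1))))
    stop("tree has an empty leaf")
  if (anyDuplicated(conds))
    stop("tree leaves overlap")
  if (!setequal(conds, seq_len(tree$n_conditions)))
    stop("tree leaves do not cover all conditions")
  sig <- vapply(leaves, `[[`, numeric(1), "sigma")
  if (any(sig < SIGMA_FLOOR - 1e-12))
    stop("leaf sigma below variance floor")
  invisible(tree)
}

# Per-condition (mu, sigma) vectors implied by a tree: row 1 = mu, row 2 =
# sigma, one column per condition. The workhorse for fast likelihood sums.
tree_condition_params <- function(tree) {
  mu <- numeric(tree$n_conditions)
  sg <- numeric(tree$n_conditions)
  for (leaf in tree_leaves(tree)) {
    mu[leaf$conditions] <- leaf$mu
    sg[leaf$conditions] <- leaf$sigma
  }
  rbind(mu = mu, sigma = sg)
}

#' Log-likelihood of a gene's profile under a regulatory tree
#'
#' Sums, over the tree's leaves, the Gaussian log-likelihood of the gene's
#' expression values in each leaf's conditions under that leaf's (mu, sigma).
#' Leaf parameters are not refit to the query gene.
#'
#' @param profile numeric vector of the gene's expression over all conditions,
#'   in tree condition order.
#' @param tree a `regulatory_tree` covering `length(profile)` conditions.
#' @return scalar log-likelihood.
#' @export
gene_tree_loglik <- function(profile, tree) {
  if (length(profile) != tree$n_conditions)
    stop("profile length does not match the tree's condition count")
  p <- tree_condition_params(tree)
  sum(-(profile - p["mu", ])^2 / (2 * p["sigma", ]^2) - log(p["sigma", ]))
}

# Log-likelihood of many genes under many trees: genes x trees matrix.
# Used by reassignment; one pass of vectorized arithmetic per tree.
genes_trees_loglik <- function(x, trees) {
  out <- matrix(NA_real_, nrow(x), length(trees))
  for (t in seq_along(trees)) {
    p <- tree_condition_params(trees[[t]])
    mu <- p["mu", ]; sg <- p["sigma", ]
    dev <- sweep(x, 2L, mu)
    out[, t] <- -rowSums(sweep(dev^2, 2L, 2 * sg^2, "/")) - sum(log(sg))
  }
  rownames(out) <- rownames(x)
  out
}

tree_node_to_list <- function(node) {
  if (is_leaf(node)) {
    list(type = "leaf", conditions = node$conditions,
         mu = node$mu, sigma = node$sigma)
  } else {
    list(type = "node", tf_id = node$tf_id, queried_level = node$queried_level,
         yes = tree_node_to_list(node$yes), no = tree_node_to_list(node$no))
  }
}

tree_node_from_list <- function(lst) {
  if (identical(lst$type, "leaf")) {
    new_subgroup(as.integer(unlist(lst$conditions)), lst$mu, lst$sigma)
  } else {
    new_tree_node(lst$tf_id, lst$queried_level,
                  tree_node_from_list(lst$yes), tree_node_from_list(lst$no))
  }
}

#' Serialize a regulatory tree to a JSON-ready list
#'
#' @param tree a `regulatory_tree`.
#' @return nested list mirroring the tree (leaf conditions are 1-based column
#'   indices; `condition_ids`, if set, gives the identifier for each index).
#' @export
tree_to_list <- function(tree) {
  list(n_conditions = tree$n_conditions,
       condition_ids = tree$condition_ids,
       root = tree_node_to_list(tree$root))
}

#' Rebuild a regulatory tree from its serialized list form
#'
#' @param lst list as produced by [tree_to_list()] (or parsed from its JSON).
#' @return a `regulatory_tree`.
#' @export
tree_from_list <- function(lst) {
  regulatory_tree(tree_node_from_list(lst$root),
                  as.integer(lst$n_conditions),
                  if (is.null(lst$condition_ids)) NULL
                  else as.character(unlist(lst$condition_ids)))
}

#' Write a regulatory tree as JSON
#'
#' @param tree a `regulatory_tree`.
#' @param path output path.
#' @export
write_tree_json <- function(tree, path) {
  jsonlite::write_json(tree_to_list(tree), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a regulatory tree from JSON
#'
#' @param path path to a JSON file written by [write_tree_json()].
#' @return a `regulatory_tree`.
#' @export
read_tree_json <- function(path) {
  tree_from_list(jsonlite::read_json(path))
}

#' @export
print.regulatory_tree <- function(x, ...) {
  cat(sprintf("<regulatory_tree: %d conditions, %d TF level(s), %d leaves>\n",
              x$n_conditions, tree_depth(x), length(tree_leaves(x))))
  walk <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (is_leaf(node)) {
      cat(sprintf("%sleaf {%s} mu=%.3g sigma=%.3g\n", pad,
                  paste(node$conditions, collapse = ","), node$mu, node$sigma))
    } else {
      cat(sprintf("%s%s == %+d ?\n", pad, node$tf_id, node$queried_level))
      walk(node$yes, indent + 1L)
      walk(node$no, indent + 1L)
    }
  }
  walk(x$root, 1L)
  invisible(x)
}
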