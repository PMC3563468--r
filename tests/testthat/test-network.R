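small_matrix <- function(n_genes = 3, n_cond = 4, seed = 1, sd = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_cond, sd = sd), n_genes, n_cond,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("c", seq_len(n_cond))))
}

test_that("split enumeration yields one candidate per usable (TF, level)", {
  x <- small_matrix(3, 4)
  lev <- matrix(c(1L, 1L, 0L, 0L), 1, 4,
                dimnames = list("TF01", colnames(x)))
  cands <- enumerate_splits(x, 1:3, 1:4, lev)
  expect_length(cands, 1L)
  expect_equal(cands[[1]]$queried_level, 1L)
  expect_equal(cands[[1]]$yes_conditions, 1:2)
  expect_equal(cands[[1]]$no_conditions, 3:4)

  lev0 <- matrix(0L, 1, 4, dimnames = list("TF01", colnames(x)))
  expect_length(enumerate_splits(x, 1:3, 1:4, lev0), 0L)

  x3 <- small_matrix(2, 3)
  lev3 <- matrix(c(1L, -1L, 0L), 1, 3, dimnames = list("TF01", colnames(x3)))
  cands <- enumerate_splits(x3, 1:2, 1:3, lev3)
  expect_length(cands, 2L)
  expect_equal(sapply(cands, `[[`, "queried_level"), c(1L, -1L))
  expect_equal(cands[[1]]$yes_conditions, 1L)   # +1 candidate: {c1} vs rest
  expect_equal(cands[[2]]$yes_conditions, 2L)   # -1 candidate: {c2} vs rest
})

test_that("split scores equal an independent term-by-term summation", {
  x <- matrix(c(0.1, 0.2, 1.1, 1.3,
                -0.1, 0.0, 0.9, 1.2), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("c", 1:4)))
  split <- list(yes_conditions = 1:2, no_conditions = 3:4)
  expect_equal(score_split(x, 1:2, split),
               oracle_pooled_ll(x, 1:2, 1:2) + oracle_pooled_ll(x, 1:2, 3:4),
               tolerance = 1e-12)
  # a clean split scores above the unsplit leaf
  expect_gt(score_split(x, 1:2, split), oracle_pooled_ll(x, 1:2, 1:4))
  expect_error(score_split(x, 1:2, list(yes_conditions = integer(),
                                        no_conditions = 1:4)), "non-empty")
})

test_that("tree building respects stopping rules", {
  x <- small_matrix(4, 6, seed = 2)
  no_tfs <- matrix(integer(), 0, 6, dimnames = list(NULL, colnames(x)))
  tree <- build_tree(x, 1:4, no_tfs)
  expect_equal(tree_depth(tree), 0L)
  expect_length(tree_leaves(tree), 1L)

  lev <- matrix(sample(c(-1L, 0L, 1L), 12, replace = TRUE), 2, 6,
                dimnames = list(c("TF01", "TF02"), colnames(x)))
  tree1 <- build_tree(x, 1:4, lev, max_depth = 1, min_leaf_conditions = 1,
                      min_gain = -Inf)
  expect_lte(tree_depth(tree1), 1L)
  expect_error(build_tree(x, integer(), lev), "non-empty")
})

test_that("greedy root split equals exhaustive enumeration on small instances", {
  set.seed(101)
  for (i in 1:40) {
    inst <- random_small_instance()
    oracle <- oracle_best_split(inst$x, seq_len(nrow(inst$x)),
                                seq_len(ncol(inst$x)), inst$tf_levels)
    tree <- build_tree(inst$x, seq_len(nrow(inst$x)), inst$tf_levels,
                       max_depth = 1, min_leaf_conditions = 1,
                       min_gain = -Inf)
    if (!is.finite(oracle$score)) {
      expect_equal(tree_depth(tree), 0L)
      next
    }
    expect_false(gremod:::is_leaf(tree$root))
    yes <- tree_leaves(tree)[[1]]$conditions
    score <- oracle_pooled_ll(inst$x, seq_len(nrow(inst$x)), yes) +
      oracle_pooled_ll(inst$x, seq_len(nrow(inst$x)),
                       setdiff(seq_len(ncol(inst$x)), yes))
    expect_equal(score, oracle$score, tolerance = 1e-9)
  }
})

test_that("greedy trees never score below any depth-1 tree", {
  set.seed(55)
  for (i in 1:10) {
    inst <- random_small_instance()
    gi <- seq_len(nrow(inst$x))
    full <- build_tree(inst$x, gi, inst$tf_levels, max_depth = 3,
                       min_leaf_conditions = 1, min_gain = 0)
    s_full <- gremod:::tree_score(inst$x, gi, full)
    for (cand in enumerate_splits(inst$x, gi, seq_len(ncol(inst$x)),
                                  inst$tf_levels)) {
      expect_gte(s_full, cand$score - 1e-9)
    }
  }
})

test_that("reassignment is the row-argmax of the gene-by-tree likelihoods", {
  set.seed(17)
  n_cond <- 8
  trees <- lapply(1:3, function(i) random_tree(n_cond, sample(2:3, 1)))
  x <- matrix(rnorm(20 * n_cond, sd = 3), 20, n_cond,
              dimnames = list(sprintf("g%02d", 1:20), paste0("c", 1:n_cond)))
  got <- reassign_genes(x, trees)
  for (g in seq_len(nrow(x))) {
    lls <- vapply(trees, function(t) oracle_gene_tree_ll(x[g, ], t),
                  numeric(1))
    expect_equal(unname(got[g]), which.max(lls))
  }
  # a single tree takes everything
  expect_true(all(reassign_genes(x, trees[1]) == 1L))
  # a gene at tree A's leaf means beats a shifted tree B
  pA <- gremod:::tree_condition_params(trees[[1]])["mu", ]
  x2 <- rbind(gene = pA)
  colnames(x2) <- paste0("c", 1:n_cond)
  shifted <- trees[[1]]
  shifted$root <- gremod:::new_subgroup(1:n_cond, mean(pA) + 10, 1)
  expect_equal(unname(reassign_genes(x2, list(shifted, trees[[1]]))), 2L)
  expect_error(reassign_genes(x, list(random_tree(n_cond - 1, 2))), "condition")
})

test_that("fitting noise-free data initialized at truth is a fixed point", {
  sim <- generate_regulatory_data(n_modules = 3, genes_per_module = 6,
                                  n_conditions = 12, n_tfs = 6,
                                  noise_sigma = 0, seed = 3)
  tf_lev <- discretize_tf_matrix(sim$matrix, sim$tf_ids)
  xd <- sim$matrix[names(sim$truth$module_labels), ]
  fit <- grn_fit(xd, tf_lev, sim$truth$module_labels)
  expect_true(fit$converged)
  expect_equal(fit$n_iterations, 1L)
  expect_equal(unname(fit$assignments), unname(sim$truth$module_labels))
})

test_that("clusters emptied by reassignment are dropped", {
  sim <- generate_regulatory_data(n_modules = 2, genes_per_module = 10,
                                  n_conditions = 10, n_tfs = 4, seed = 8)
  xd <- sim$matrix[names(sim$truth$module_labels), ]
  tf_lev <- discretize_tf_matrix(sim$matrix, sim$tf_ids)
  # split one true module across two initial clusters: one should empty
  init <- sim$truth$module_labels
  init[1:3] <- 3L
  fit <- grn_fit(xd, tf_lev, init)
  expect_true(fit$converged)
  expect_lte(length(fit$modules), 3L)
  expect_equal(sort(unique(unname(fit$assignments))),
               seq_along(fit$modules))
})

test_that("fit artifacts are written in the documented formats", {
  sim <- generate_regulatory_data(n_modules = 2, genes_per_module = 5,
                                  n_conditions = 8, n_tfs = 4, seed = 12)
  xd <- sim$matrix[names(sim$truth$module_labels), ]
  tf_lev <- discretize_tf_matrix(sim$matrix, sim$tf_ids)
  fit <- grn_fit(xd, tf_lev, sim$truth$module_labels)
  dir <- withr::local_tempdir()
  write_fit_outputs(fit, dir)
  asg <- read.delim(file.path(dir, "assignments.tsv"))
  expect_setequal(asg$gene_id, rownames(xd))
  mods <- jsonlite::read_json(file.path(dir, "modules.json"))
  expect_length(mods, length(fit$modules))
  tree <- tree_from_list(mods[[1]]$tree)
  expect_s3_class(tree, "regulatory_tree")
  trace <- read.delim(file.path(dir, "trace.tsv"))
  expect_equal(nrow(trace), fit$n_iterations)
})
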