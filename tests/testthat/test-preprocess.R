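test_that("DEG selection is strict at the threshold and counts by condition", {
  x <- matrix(c(3.5, 0, 1, -1, 0, -3.2), 3, 2, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  deg <- select_degs(x, 3)
  expect_setequal(deg$selected_gene_ids, c("g1", "g3"))
  expect_equal(deg$per_condition_counts$n_up, c(1, 0))
  expect_equal(deg$per_condition_counts$n_down, c(0, 1))

  x2 <- matrix(runif(10, -2.9, 2.9), 5, 2,
               dimnames = list(paste0("g", 1:5), c("c1", "c2")))
  expect_length(select_degs(x2, 3)$selected_gene_ids, 0)

  # a value exactly at the threshold is not differentially expressed
  x3 <- matrix(c(3, -3, 0, 0), 2, 2,
               dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_length(select_degs(x3, 3)$selected_gene_ids, 0)
  expect_error(select_degs(x3, 0), "positive")
})

test_that("DEG selection is monotone in the threshold", {
  set.seed(21)
  for (i in 1:10) {
    x <- matrix(rnorm(60, sd = 3), 10, 6,
                dimnames = list(paste0("g", 1:10), paste0("c", 1:6)))
    lo <- select_degs(x, 2)$selected_gene_ids
    hi <- select_degs(x, 4)$selected_gene_ids
    expect_true(all(hi %in% lo))
  }
})

test_that("the number of TF levels follows the threshold categories", {
  expect_equal(choose_n_levels(c(4, -4, 0), 3), 3L)
  expect_equal(choose_n_levels(c(4, 4, 0), 3), 2L)
  expect_equal(choose_n_levels(c(4, -4), 3), 2L)  # no intermediate values
  expect_equal(choose_n_levels(c(1, -1), 3), 2L)
})

test_that("TF discretization labels separated profiles and maps levels by sign", {
  d <- discretize_tf(c(5, 5, -5, -5, 0, 0), 3)
  expect_equal(d$levels, c(1L, 1L, -1L, -1L, 0L, 0L))
  d <- discretize_tf(c(4, 4, 0.1, 0), 2)
  expect_equal(d$levels, c(1L, 1L, 0L, 0L))       # both centroids >= 0
  d <- discretize_tf(c(-4, -4, -0.1, 0), 2)
  expect_equal(d$levels, c(-1L, -1L, 0L, 0L))     # both centroids <= 0
  d <- discretize_tf(c(4, 4, -4, -4), 2)
  expect_equal(d$levels, c(1L, 1L, -1L, -1L))     # mixed signs
  expect_error(discretize_tf(rep(1, 5), 2), "degenerate")
})

test_that("exact 1-D K-means attains the global SSE optimum", {
  sse_of <- function(values, labels) {
    sum(vapply(unique(labels), function(l) {
      v <- values[labels == l]; sum((v - mean(v))^2)
    }, numeric(1)))
  }
  set.seed(33)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    k <- sample(2:3, 1)
    values <- round(rnorm(n, sd = 2), 2)
    if (length(unique(values)) < k) next
    km <- gremod:::kmeans_1d_exact(values, k)
    # brute force over every one of the k^n label assignments
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
    best <- Inf
    for (r in seq_len(nrow(grid))) {
      lab <- grid[r, ]
      if (length(unique(lab)) < k) next
      best <- min(best, sse_of(values, lab))
    }
    expect_equal(sse_of(values, km$labels), best, tolerance = 1e-9)
    # label order must follow centroid order
    d <- discretize_tf(values, k)
    means_by_level <- tapply(values, d$levels, mean)
    expect_true(!is.unsorted(means_by_level))
  }
})

test_that("matrix-level discretization drops degenerate TFs with a warning", {
  x <- rbind(TFa = c(5, 5, -5, -5), TFb = rep(2, 4), g1 = c(1, 2, 3, 4))
  colnames(x) <- paste0("c", 1:4)
  expect_warning(lev <- discretize_tf_matrix(x, c("TFa", "TFb")),
                 "degenerate")
  expect_equal(rownames(lev), "TFa")
  expect_equal(unname(lev["TFa", ]), c(1L, 1L, -1L, -1L))
  expect_warning(discretize_tf_matrix(x, c("TFa", "TFmissing")), "absent")
})

test_that("TF list TSV parsing accepts headered and headerless forms", {
  p1 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tf_id\tfamily", "TF01\tMYB", "TF02\tWRKY"), p1)
  df <- read_tf_list_tsv(p1)
  expect_equal(df$tf_id, c("TF01", "TF02"))
  expect_equal(df$family, c("MYB", "WRKY"))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("TF01", "TF02"), p2)
  expect_equal(read_tf_list_tsv(p2)$tf_id, c("TF01", "TF02"))
})
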