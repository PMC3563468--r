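#' Select differentially expressed genes
#'
#' A gene is differentially expressed if its normalized expression exceeds the
#' threshold in absolute value (strictly) in at least one condition. Also
#' returns, per condition, the number of up- and down-regulated genes.
#'
#' @param x expression matrix (genes x conditions).
#' @param threshold positive DEG cutoff on the normalized log scale
#'   (default 3).
#' @return list with `threshold`, `selected_gene_ids` (character),
#'   `per_condition_counts` (data.frame: condition_id, n_up, n_down).
#' @export
select_degs <- function(x, threshold = 3) {
  validate_expression_matrix(x)
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be positive")
  up <- x > threshold
  down <- x < -threshold
  up[is.na(up)] <- FALSE
  down[is.na(down)] <- FALSE
  sel <- rowSums(up | down) > 0L
  list(threshold = threshold,
       selected_gene_ids = rownames(x)[sel],
       per_condition_counts = data.frame(
         condition_id = colnames(x),
         n_up = colSums(up),
         n_down = colSums(down),
         row.names = NULL, stringsAsFactors = FALSE))
}

#' Write a DEG list, one gene id per line
#'
#' @param deg result of [select_degs()] or a character vector of gene ids.
#' @param path output path.
#' @export
write_deg_list <- function(deg, path) {
  ids <- if (is.list(deg)) deg$selected_gene_ids else as.character(deg)
  writeLines(ids, path)
  invisible(path)
}

# Exact 1-D k-means: optimal clusters of sorted values are contiguous, so the
# global optimum is found by searching contiguous partitions (dynamic program
# over split points). No initialization, hence no nondeterminism.
kmeans_1d_exact <- function(values, k) {
  ord <- order(values)
  v <- values[ord]
  n <- length(v)
  cs <- cumsum(v); cs2 <- cumsum(v^2)
  # sse of v[i..j]
  seg_sse <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  # dp[m, j]: min SSE of first j points in m clusters; bk: argmin split
  dp <- matrix(Inf, k, n)
  bk <- matrix(0L, k, n)
  for (j in 1:n) dp[1, j] <- seg_sse(1, j)
  if (k > 1) for (m in 2:k) for (j in m:n) {
    for (i in m:j) {
      cand <- dp[m - 1, i - 1] + seg_sse(i, j)
      if (cand < dp[m, j]) { dp[m, j] <- cand; bk[m, j] <- i }
    }
  }
  labels_sorted <- integer(n)
  j <- n
  for (m in k:1) {
    i <- if (m == 1) 1L else bk[m, j]
    labels_sorted[i:j] <- m
    j <- i - 1L
  }
  labels <- integer(n)
  labels[ord] <- labels_sorted
  centers <- vapply(1:k, function(m) mean(values[labels == m]), numeric(1))
  list(labels = labels, centers = centers, sse = dp[k, n])
}

#' Number of discrete levels for a TF profile
#'
#' A TF takes 3 discrete levels when its profile contains high (> threshold),
#' low (< -threshold) and intermediate values; otherwise 2.
#'
#' @param profile numeric vector of the TF's expression over conditions.
#' @param threshold positive DEG cutoff (default 3).
#' @return 2 or 3.
#' @export
choose_n_levels <- function(profile, threshold = 3) {
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be positive")
  has_high <- any(profile > threshold)
  has_low <- any(profile < -threshold)
  has_mid <- any(profile >= -threshold & profile <= threshold)
  if (has_high && has_low && has_mid) 3L else 2L
}

#' Discretize a TF expression profile into levels
#'
#' Clusters the profile into `n_levels` groups by exact one-dimensional
#' K-means and relabels clusters by ascending centroid: with 3 levels to
#' \{-1, 0, +1\} (lowly / normally / highly expressed); with 2 levels to
#' \{0, +1\} if both centroids are non-negative, \{-1, 0\} if both are
#' non-positive, and \{-1, +1\} otherwise.
#'
#' @param profile numeric vector over conditions with at least `n_levels`
#'   distinct values.
#' @param n_levels 2 or 3.
#' @param tf_id optional identifier stored in the result.
#' @return list with `tf_id`, `levels` (integer vector over conditions with
#'   entries in \{-1, 0, +1\}), `n_levels`, `centers` (ascending centroids).
#' @export
discretize_tf <- function(profile, n_levels, tf_id = NA_character_) {
  if (!n_levels %in% c(2L, 3L)) stop("n_levels must be 2 or 3")
  if (length(unique(profile)) < n_levels)
    stop("degenerate profile: fewer distinct values than levels")
  km <- kmeans_1d_exact(profile, n_levels)
  ord <- order(km$centers)
  centers <- km$centers[ord]
  rank_of <- match(km$labels, ord)  # 1 = lowest centroid
  if (n_levels == 3L) {
    level_map <- c(-1L, 0L, 1L)
  } else if (all(centers >= 0)) {
    level_map <- c(0L, 1L)
  } else if (all(centers <= 0)) {
    level_map <- c(-1L, 0L)
  } else {
    level_map <- c(-1L, 1L)
  }
  list(tf_id = tf_id, levels = level_map[rank_of],
       n_levels = n_levels, centers = centers)
}

#' Discretize the candidate TFs of an expression matrix
#'
#' For each candidate TF present in the matrix, picks 2 or 3 levels from the
#' profile's relation to the DEG threshold ([choose_n_levels()]) and
#' discretizes it ([discretize_tf()]). TFs absent from the matrix or with
#' (near-)constant profiles are dropped with a warning; they cannot split
#' conditions.
#'
#' @param x expression matrix.
#' @param tf_ids character vector of candidate TF gene ids.
#' @param threshold positive DEG cutoff (default 3).
#' @return integer matrix of discrete levels (TFs x conditions, entries in
#'   \{-1, 0, +1\}) with rownames = retained TF ids.
#' @export
discretize_tf_matrix <- function(x, tf_ids, threshold = 3) {
  validate_expression_matrix(x)
  tf_ids <- unique(as.character(tf_ids))
  missing <- setdiff(tf_ids, rownames(x))
  if (length(missing) > 0)
    warning(sprintf("%d candidate TF(s) absent from the expression matrix; dropped",
                    length(missing)))
  tf_ids <- intersect(tf_ids, rownames(x))
  lev <- matrix(NA_integer_, 0L, ncol(x))
  kept <- character()
  dropped_const <- 0L
  for (id in tf_ids) {
    prof <- x[id, ]
    nl <- choose_n_levels(prof, threshold)
    if (length(unique(prof)) < nl) { dropped_const <- dropped_const + 1L; next }
    d <- discretize_tf(prof, nl, tf_id = id)
    lev <- rbind(lev, d$levels)
    kept <- c(kept, id)
  }
  if (dropped_const > 0L)
    warning(sprintf("%d TF(s) with degenerate (near-constant) profiles dropped from candidacy",
                    dropped_const))
  rownames(lev) <- kept
  colnames(lev) <- colnames(x)
  lev
}

#' Read a candidate TF list from TSV
#'
#' Expected columns: `tf_id` and optionally `family`. A headerless single
#' column of ids is also accepted.
#'
#' @param path path to a TSV file.
#' @return data.frame with columns `tf_id` and `family` (NA when absent).
#' @export
read_tf_list_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("(^|\t)tf_id($|\t)", first)) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(df)[1] <- "tf_id"
    if (ncol(df) >= 2) names(df)[2] <- "family"
  }
  if (!"family" %in% names(df)) df$family <- NA_character_
  df[, c("tf_id", "family")]
}
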