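#' K-means clustering of gene expression profiles
#'
#' Clusters gene rows by Euclidean distance with K-means, keeping the best of
#' `n_restarts` runs by within-cluster sum of squares. Starting centers are
#' sampled from the distinct rows so duplicated profiles cannot break the
#' start; when the number of distinct rows equals `k`, those rows are the
#' (unique optimal) starting centers and a single run is performed.
#'
#' @param x expression matrix (genes x conditions).
#' @param k number of clusters (<= number of genes).
#' @param seed integer seed making the restarts reproducible.
#' @param n_restarts number of random restarts (default 10).
#' @return list with `k` (clusters actually occupied), `labels` (named integer
#'   vector, dense in 1..k), `sse` (total within-cluster SSE),
#'   `per_cluster_mean_corr` (mean pairwise Pearson per cluster, NA for
#'   singleton clusters), `mean_cluster_size`.
#' @export
kmeans_cluster <- function(x, k, seed = 0L, n_restarts = 10L) {
  validate_expression_matrix(x)
  n <- nrow(x)
  if (k > n) stop("k exceeds the number of genes")
  uniq <- x[!duplicated(as.data.frame(x)), , drop = FALSE]
  if (nrow(uniq) < k)
    stop("k exceeds the number of distinct expression profiles")
  run_one <- function(centers) {
    # Hartigan-Wong needs k < n; fall back to Lloyd for the k == n edge
    tryCatch(suppressWarnings(stats::kmeans(x, centers = centers,
                                            iter.max = 100L)),
             error = function(e) tryCatch(
               suppressWarnings(stats::kmeans(x, centers = centers,
                                              iter.max = 100L,
                                              algorithm = "Lloyd")),
               error = function(e) NULL))
  }
  set.seed(seed)
  best <- NULL
  if (nrow(uniq) == k) {
    best <- run_one(uniq)
  } else {
    for (r in seq_len(n_restarts)) {
      centers <- uniq[sample.int(nrow(uniq), k), , drop = FALSE]
      km <- run_one(centers)
      if (!is.null(km) &&
          (is.null(best) || km$tot.withinss < best$tot.withinss))
        best <- km
    }
  }
  if (is.null(best)) stop("k-means failed for every restart")
  labels <- best$cluster
  # drop empty clusters (possible with Lloyd-style degenerate starts)
  occupied <- sort(unique(labels))
  labels <- match(labels, occupied)
  names(labels) <- rownames(x)
  k_eff <- length(occupied)
  corr <- vapply(seq_len(k_eff), function(cl) {
    ids <- names(labels)[labels == cl]
    if (length(ids) < 2L) NA_real_
    else mean_pairwise_correlation(x, ids, warn_zero_variance = FALSE)
  }, numeric(1))
  list(k = k_eff, labels = labels, sse = best$tot.withinss,
       per_cluster_mean_corr = corr, mean_cluster_size = n / k_eff)
}

#' Choose the number of clusters by the knee rule
#'
#' For each candidate k the clustering trades off mean cluster size (falling
#' in k) against mean within-cluster pairwise Pearson correlation (rising in
#' k). The chosen k sits at the knee of the (mean size, mean correlation)
#' curve: the point of maximum perpendicular distance to the chord joining the
#' curve's endpoints, with both axes rescaled to the unit interval so the two
#' quantities weigh equally. Ties break toward the smallest k.
#'
#' @param x expression matrix (genes x conditions).
#' @param k_grid ascending integer grid of candidate k (length >= 3).
#' @param seed integer seed.
#' @param n_restarts restarts per K-means run (default 5).
#' @return list with `k` (the chosen value) and `curve` (data.frame: k,
#'   mean_size, mean_corr, knee_distance).
#' @export
choose_k <- function(x, k_grid, seed = 0L, n_restarts = 5L) {
  k_grid <- as.integer(k_grid)
  if (length(k_grid) < 3L) stop("k_grid must contain at least 3 values")
  if (is.unsorted(k_grid, strictly = TRUE)) stop("k_grid must be strictly ascending")
  pts <- t(vapply(k_grid, function(k) {
    km <- kmeans_cluster(x, k, seed = seed, n_restarts = n_restarts)
    c(mean_size = km$mean_cluster_size,
      mean_corr = mean(km$per_cluster_mean_corr, na.rm = TRUE))
  }, numeric(2)))
  rescale <- function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(0, length(v)) else (v - r[1]) / diff(r)
  }
  u <- rescale(pts[, "mean_size"])
  v <- rescale(pts[, "mean_corr"])
  a <- c(u[1], v[1]); b <- c(u[length(u)], v[length(v)])
  chord <- b - a
  len <- sqrt(sum(chord^2))
  dist <- if (len == 0) rep(0, length(u)) else
    abs(chord[1] * (v - a[2]) - chord[2] * (u - a[1])) / len
  list(k = k_grid[which.max(dist)],
       curve = data.frame(k = k_grid,
                          mean_size = pts[, "mean_size"],
                          mean_corr = pts[, "mean_corr"],
                          knee_distance = dist,
                          row.names = NULL))
}
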