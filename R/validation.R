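#' Mean pairwise Pearson correlation of a gene set (module coherence)
#'
#' Averages the Pearson correlation coefficient over all unordered pairs of
#' the module's gene expression profiles. Pairs involving a zero-variance
#' profile have undefined correlation and contribute 0 by convention.
#'
#' @param x expression matrix.
#' @param gene_ids at least two gene ids (or row indices).
#' @param warn_zero_variance warn when zero-variance profiles are present
#'   (default TRUE).
#' @return scalar in [-1, 1].
#' @export
mean_pairwise_correlation <- function(x, gene_ids, warn_zero_variance = TRUE) {
  idx <- resolve_gene_idx(x, gene_ids)
  if (length(idx) < 2L) stop("at least two genes are required")
  rows <- x[idx, , drop = FALSE]
  vars <- apply(rows, 1L, stats::var)
  if (any(vars == 0) && warn_zero_variance)
    warning(sprintf("%d zero-variance profile(s); their pairs contribute 0",
                    sum(vars == 0)))
  cc <- suppressWarnings(stats::cor(t(rows)))
  cc[!is.finite(cc)] <- 0
  mean(cc[upper.tri(cc)])
}

#' Build an annotation table for enrichment tests
#'
#' @param gene_ids character vector, one entry per (gene, term) annotation.
#' @param term_ids character vector parallel to `gene_ids`.
#' @param term_names optional named character vector: term id -> readable
#'   name.
#' @param background optional character vector of background gene ids;
#'   defaults to the annotated genes. Every annotated gene must be in the
#'   background.
#' @param namespaces optional character vector parallel to `gene_ids` (e.g.
#'   GO namespace); multiple-testing correction is applied within namespace.
#' @return object of class `annotation_table`: list with `gene2terms` (named
#'   list of character vectors), `term_names`, `term_namespace`,
#'   `background`.
#' @export
annotation_table <- function(gene_ids, term_ids, term_names = NULL,
                             background = NULL, namespaces = NULL) {
  gene_ids <- as.character(gene_ids)
  term_ids <- as.character(term_ids)
  if (length(gene_ids) != length(term_ids))
    stop("gene_ids and term_ids must have equal length")
  if (length(term_ids) > 0 && any(!nzchar(term_ids)))
    stop("term ids must be non-empty strings")
  if (is.null(background)) background <- unique(gene_ids)
  background <- unique(as.character(background))
  if (!all(gene_ids %in% background))
    stop("every annotated gene must be in the background")
  term_namespace <- NULL
  if (!is.null(namespaces)) {
    term_namespace <- tapply(as.character(namespaces), term_ids,
                             function(v) v[1])
    term_namespace <- stats::setNames(as.character(term_namespace),
                                      names(term_namespace))
  }
  structure(list(
    gene2terms = lapply(split(term_ids, gene_ids), unique),
    term_names = term_names,
    term_namespace = term_namespace,
    background = background), class = "annotation_table")
}

#' Read an annotation table from TSV
#'
#' Expected columns: `gene_id`, `term_id`, optional `term_name`, optional
#' `namespace`. A probe mapping to several genes is represented by one row
#' per mapped gene; all mapped genes count in enrichment.
#'
#' @param path path to a TSV file.
#' @param background optional character vector of background gene ids.
#' @return an `annotation_table`.
#' @export
read_annotations_tsv <- function(path, background = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(df)))
    stop("annotation TSV must contain gene_id and term_id columns")
  term_names <- NULL
  if ("term_name" %in% names(df)) {
    term_names <- tapply(df$term_name, df$term_id, function(v) v[1])
    term_names <- stats::setNames(as.character(term_names), names(term_names))
  }
  annotation_table(df$gene_id, df$term_id, term_names = term_names,
                   background = background,
                   namespaces = if ("namespace" %in% names(df)) df$namespace)
}

#' Hypergeometric function-term enrichment of a module
#'
#' For each term annotated on at least `min_hits` module genes, computes the
#' upper-tail hypergeometric probability of observing at least `a` annotated
#' genes in a module of size `n` drawn from a background of `N` genes of
#' which `K` carry the term, p = sum_{i >= a} C(K,i) C(N-K, n-i) / C(N,n).
#' Raw p-values are reported alongside Benjamini-Hochberg adjusted ones
#' (adjusted within namespace when the annotation table carries namespaces).
#'
#' @param module_genes character vector of module gene ids (subset of the
#'   background).
#' @param annotations an `annotation_table`.
#' @param min_hits minimum module hits for a term to be tested (default 3).
#' @return data.frame sorted by ascending p: term_id, term_name, module_hits,
#'   module_size, background_hits, background_size, p_value, adjusted_p.
#' @export
hypergeom_enrichment <- function(module_genes, annotations, min_hits = 3L) {
  module_genes <- unique(as.character(module_genes))
  if (!all(module_genes %in% annotations$background))
    stop("module gene(s) outside the annotation background")
  N <- length(annotations$background)
  n <- length(module_genes)
  ann <- annotations$gene2terms
  module_terms <- unlist(ann[intersect(module_genes, names(ann))],
                         use.names = FALSE)
  empty <- data.frame(term_id = character(), term_name = character(),
                      module_hits = integer(), module_size = integer(),
                      background_hits = integer(), background_size = integer(),
                      p_value = numeric(), adjusted_p = numeric(),
                      stringsAsFactors = FALSE)
  if (length(module_terms) == 0L) return(empty)
  hit_tab <- table(module_terms)
  terms <- names(hit_tab)[hit_tab >= min_hits]
  if (length(terms) == 0L) return(empty)
  all_terms <- unlist(ann, use.names = FALSE)
  K_tab <- table(all_terms)
  a <- as.integer(hit_tab[terms])
  K <- as.integer(K_tab[terms])
  p <- stats::phyper(a - 1L, K, N - K, n, lower.tail = FALSE)
  ns <- if (!is.null(annotations$term_namespace))
    annotations$term_namespace[terms] else rep("all", length(terms))
  ns[is.na(ns)] <- "all"
  adj <- stats::ave(p, ns, FUN = function(v) stats::p.adjust(v, "BH"))
  nm <- if (!is.null(annotations$term_names))
    unname(annotations$term_names[terms]) else rep(NA_character_, length(terms))
  out <- data.frame(term_id = terms, term_name = nm,
                    module_hits = a, module_size = n,
                    background_hits = K, background_size = N,
                    p_value = p, adjusted_p = adj,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-module validation report
#'
#' For every module: coherence (mean pairwise Pearson), gene count, number of
#' TFs in the regulatory tree, and — when annotations are given — the most
#' enriched term with its raw and adjusted p-values.
#'
#' @param fit a `grn_fit`.
#' @param annotations optional `annotation_table`.
#' @param min_hits minimum module hits for enrichment (default 3).
#' @return list with `report` (one data.frame row per module) and
#'   `enrichment` (named list of full per-module enrichment tables, NULL
#'   without annotations).
#' @export
summarize_modules <- function(fit, annotations = NULL, min_hits = 3L) {
  rows <- lapply(fit$modules, function(m) {
    data.frame(module_id = m$module_id,
               n_genes = length(m$gene_ids),
               n_tfs = length(tree_tfs(m$tree)),
               coherence = m$coherence,
               log_likelihood = m$log_likelihood,
               top_term = NA_character_,
               top_term_hits = NA_integer_,
               top_term_p = NA_real_,
               top_term_adjusted_p = NA_real_,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  enrich <- NULL
  if (!is.null(annotations)) {
    enrich <- lapply(fit$modules, function(m) {
      hypergeom_enrichment(intersect(m$gene_ids, annotations$background),
                           annotations, min_hits = min_hits)
    })
    names(enrich) <- report$module_id
    for (i in seq_along(enrich)) {
      e <- enrich[[i]]
      if (nrow(e) > 0) {
        report$top_term[i] <- e$term_id[1]
        report$top_term_hits[i] <- e$module_hits[1]
        report$top_term_p[i] <- e$p_value[1]
        report$top_term_adjusted_p[i] <- e$adjusted_p[1]
      }
    }
  }
  list(report = report, enrichment = enrich)
}

#' Histogram of module coherence values
#'
#' Bins module coherences over [-1, 1]; the table behind the usual coherence
#' histogram figure.
#'
#' @param fit a `grn_fit`.
#' @param breaks number of equal-width bins over [-1, 1] (default 20).
#' @return data.frame: bin_low, bin_high, n_modules.
#' @export
coherence_histogram <- function(fit, breaks = 20L) {
  co <- vapply(fit$modules, `[[`, numeric(1), "coherence")
  co <- co[!is.na(co)]
  edges <- seq(-1, 1, length.out = breaks + 1L)
  h <- graphics::hist(co, breaks = edges, plot = FALSE, include.lowest = TRUE)
  data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1],
             n_modules = h$counts)
}
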