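#' Default pipeline configuration
#'
#' Returns the full set of pipeline parameters at their defaults: DEG
#' threshold 3 (normalized log units), tree depth cap 5, minimum leaf size 2
#' conditions, minimum split gain 0, promoter window 500 bp, seed 0. A user
#' configuration (list or YAML) overrides any subset.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 0L,
    threshold = 3,
    k = NULL,                 # NULL: choose by the knee rule over k_grid
    k_grid = seq(10L, 150L, by = 10L),
    n_restarts = 5L,
    max_depth = 5L,
    min_leaf_conditions = 2L,
    min_gain = 0,
    max_iterations = 50L,
    self_exclude = FALSE,
    min_hits = 3L,
    window = 500L,
    output_dir = "gremod_out",
    expression = NULL,        # path to expression TSV
    tf_list = NULL,           # path to TF list TSV
    annotations = NULL,       # optional annotation TSV
    genome = NULL,            # optional genome FASTA
    gff = NULL,               # optional GFF3
    simulate = NULL           # optional list of generate_regulatory_data args
  )
}

load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full module-inference workflow
#'
#' Executes the pipeline end to end: DEG selection, TF discretization,
#' initial K-means clustering (with knee-based choice of k unless `k` is
#' given), iterative tree building and gene reassignment, module
#' summarization, and — when annotation / genome inputs are configured —
#' enrichment tests and promoter FASTA export. All artifacts plus a run log
#' are written under `output_dir`.
#'
#' @param config a named list or the path to a YAML file; see
#'   [default_config()] for the recognized keys. Provide either `expression`
#'   + `tf_list` paths or a `simulate` block of
#'   [generate_regulatory_data()] arguments.
#' @return invisibly, a list with the fit, the summary report, and the
#'   output directory.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$output_dir, "run_log.txt")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  cat(sprintf("gremod %s run, %s\n",
              as.character(utils::packageVersion("gremod")),
              format(Sys.time())),
      file = log_path)
  for (key in c("seed", "threshold", "max_depth", "min_leaf_conditions",
                "min_gain", "max_iterations", "window", "min_hits"))
    logf("parameter %s = %s", key, format(cfg[[key]]))

  if (!is.null(cfg$simulate)) {
    sim_args <- utils::modifyList(list(seed = cfg$seed), cfg$simulate)
    sim <- do.call(generate_regulatory_data, sim_args)
    x <- sim$matrix
    tf_ids <- sim$tf_ids
    write_expression_tsv(x, file.path(cfg$output_dir, "expression.tsv"))
    utils::write.table(data.frame(tf_id = tf_ids, family = NA_character_),
                       file.path(cfg$output_dir, "tf_list.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("simulated input: %d genes x %d conditions, %d TFs",
         nrow(x), ncol(x), length(tf_ids))
  } else {
    if (is.null(cfg$expression) || is.null(cfg$tf_list))
      stop("config must provide 'expression' and 'tf_list' paths, or a 'simulate' block")
    x <- read_expression_tsv(cfg$expression)
    tf_ids <- read_tf_list_tsv(cfg$tf_list)$tf_id
    logf("input: %d genes x %d conditions, %d candidate TFs",
         nrow(x), ncol(x), length(tf_ids))
  }

  deg <- select_degs(x, cfg$threshold)
  if (length(deg$selected_gene_ids) < 2L)
    stop("fewer than 2 differentially expressed genes at this threshold")
  write_deg_list(deg, file.path(cfg$output_dir, "degs.txt"))
  utils::write.table(deg$per_condition_counts,
                     file.path(cfg$output_dir, "deg_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("%d differentially expressed genes at |x| > %s",
       length(deg$selected_gene_ids), format(cfg$threshold))

  tf_levels <- withCallingHandlers(
    discretize_tf_matrix(x, tf_ids, cfg$threshold),
    warning = function(w) { logf("warning: %s", conditionMessage(w))
                            invokeRestart("muffleWarning") })
  if (nrow(tf_levels) == 0L) stop("no usable candidate TFs after discretization")
  logf("%d TFs discretized", nrow(tf_levels))

  xd <- x[deg$selected_gene_ids, , drop = FALSE]
  k <- cfg$k
  if (is.null(k)) {
    grid <- cfg$k_grid[cfg$k_grid <= nrow(xd)]
    if (length(grid) < 3L)
      grid <- unique(pmax(2L, round(seq(2L, max(2L, nrow(xd) - 1L),
                                        length.out = 5L))))
    kc <- choose_k(xd, grid, seed = cfg$seed, n_restarts = cfg$n_restarts)
    utils::write.table(kc$curve, file.path(cfg$output_dir, "k_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    k <- kc$k
    logf("knee rule selected k = %d over grid [%s]", k,
         paste(grid, collapse = ", "))
  } else logf("k = %d (configured)", k)

  init <- kmeans_cluster(xd, k, seed = cfg$seed, n_restarts = cfg$n_restarts)
  fit <- grn_fit(xd, tf_levels, init$labels,
                 max_depth = cfg$max_depth,
                 min_leaf_conditions = cfg$min_leaf_conditions,
                 min_gain = cfg$min_gain,
                 max_iterations = cfg$max_iterations,
                 self_exclude = cfg$self_exclude)
  logf("fit: %d modules, %s after %d iteration(s), total log-likelihood %.6f",
       length(fit$modules), if (fit$converged) "converged" else "iteration cap",
       fit$n_iterations, fit$total_log_likelihood)
  write_fit_outputs(fit, cfg$output_dir)

  ann <- NULL
  if (!is.null(cfg$annotations)) {
    ann <- read_annotations_tsv(cfg$annotations,
                                background = rownames(xd))
  }
  summ <- summarize_modules(fit, ann, min_hits = cfg$min_hits)
  utils::write.table(summ$report, file.path(cfg$output_dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(coherence_histogram(fit),
                     file.path(cfg$output_dir, "coherence_hist.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summ$enrichment)) {
    enr <- do.call(rbind, lapply(names(summ$enrichment), function(mid) {
      e <- summ$enrichment[[mid]]
      if (nrow(e) == 0L) return(NULL)
      cbind(module_id = mid, e)
    }))
    if (is.null(enr)) enr <- data.frame(module_id = character())
    utils::write.table(enr, file.path(cfg$output_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(cfg$genome) && !is.null(cfg$gff)) {
    for (m in fit$modules) {
      regions <- withCallingHandlers(
        extract_upstream(cfg$genome, cfg$gff, m$gene_ids,
                         window = cfg$window),
        warning = function(w) { logf("warning: %s", conditionMessage(w))
                                invokeRestart("muffleWarning") })
      if (nrow(regions) > 0L)
        export_motif_fasta(regions,
                           file.path(cfg$output_dir,
                                     sprintf("promoters_%s.fasta",
                                             m$module_id)))
    }
    logf("promoter windows (%d bp) exported per module", cfg$window)
  }

  invisible(list(fit = fit, report = summ$report,
                 output_dir = cfg$output_dir))
}
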