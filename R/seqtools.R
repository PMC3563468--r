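#' Extract promoter-oriented upstream regions for a set of genes
#'
#' For each gene, takes the `window` bases upstream of its start codon on the
#' gene's strand: on the + strand the bases immediately 5' of the anchor, and
#' on the - strand the bases immediately 3' of the gene end, reverse
#' complemented so the returned sequence reads promoter-to-gene. The anchor
#' is the first CDS start when CDS features exist for the gene (directly or
#' via its mRNA children), otherwise the 5' end of the gene feature. Windows
#' are truncated at contig edges. GFF3 coordinates (1-based inclusive) are
#' converted to 0-based half-open forward-strand coordinates in the output.
#'
#' @param genome a `DNAStringSet` or path to a FASTA file; names are
#'   truncated at the first whitespace.
#' @param features a `GRanges` from a GFF3 file or the path to one.
#' @param gene_ids character vector of gene identifiers (matched against the
#'   GFF3 `ID` attribute).
#' @param window positive window length in bases (default 500).
#' @return data.frame: gene_id, contig, start, end (0-based half-open,
#'   forward strand), strand, sequence. Genes missing from the GFF3 or with
#'   no upstream bases are omitted with a warning; a contig missing from the
#'   FASTA is an error.
#' @export
extract_upstream <- function(genome, features, gene_ids, window = 500L) {
  if (window <= 0) stop("window must be positive")
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- if (is.character(features))
    rtracklayer::import(features, format = "GFF3") else features
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  parents <- if (!is.null(gr$Parent)) gr$Parent else NULL
  parent_has <- function(i, set) {
    if (is.null(parents)) FALSE
    else length(intersect(as.character(parents[[i]]), set)) > 0
  }

  out <- list()
  for (gid in gene_ids) {
    hit <- which(!is.na(ids) & ids == gid)
    if (length(hit) == 0L) {
      warning(sprintf("gene '%s' not found in the feature table; skipped", gid))
      next
    }
    is_gene <- as.character(gr$type[hit]) == "gene"
    feat <- gr[hit[if (any(is_gene)) which(is_gene)[1] else 1L]]
    contig <- as.character(GenomicRanges::seqnames(feat))
    if (!contig %in% names(genome))
      stop(sprintf("contig '%s' missing from the genome FASTA", contig))
    strand <- as.character(GenomicRanges::strand(feat))
    if (!strand %in% c("+", "-"))
      stop(sprintf("gene '%s' has no strand in the feature table", gid))

    # CDS anchored at the gene or at one of its transcripts
    child_ids <- ids[vapply(seq_along(gr), parent_has, logical(1), set = gid)]
    child_ids <- child_ids[!is.na(child_ids)]
    cds_idx <- which(as.character(gr$type) == "CDS" &
                       vapply(seq_along(gr), parent_has, logical(1),
                              set = c(gid, child_ids)))
    clen <- length(genome[[contig]])
    if (strand == "+") {
      anchor <- if (length(cds_idx) > 0)
        min(GenomicRanges::start(gr[cds_idx])) else GenomicRanges::start(feat)
      s1 <- max(1L, anchor - window)
      e1 <- anchor - 1L
    } else {
      anchor <- if (length(cds_idx) > 0)
        max(GenomicRanges::end(gr[cds_idx])) else GenomicRanges::end(feat)
      s1 <- anchor + 1L
      e1 <- min(clen, anchor + window)
    }
    if (s1 > e1) {
      warning(sprintf("gene '%s' has no upstream bases on its contig; skipped",
                      gid))
      next
    }
    seq <- Biostrings::subseq(genome[[contig]], s1, e1)
    if (strand == "-") seq <- Biostrings::reverseComplement(seq)
    out[[length(out) + 1L]] <- data.frame(
      gene_id = gid, contig = contig,
      start = s1 - 1L, end = e1, strand = strand,
      sequence = as.character(seq), stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Export upstream regions as a motif-discovery-ready FASTA
#'
#' Writes one record per gene (header = gene id) plus a sidecar text file
#' (`<path>.settings.txt`) recording the intended external motif-search
#' settings: motif widths 6-18 nt and a site p-value cutoff of 0.001.
#'
#' @param regions data.frame from [extract_upstream()] (non-empty).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
export_motif_fasta <- function(regions, path) {
  if (is.null(regions) || nrow(regions) == 0L)
    stop("no regions to export")
  seqs <- Biostrings::DNAStringSet(stats::setNames(regions$sequence,
                                                   regions$gene_id))
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  writeLines(c(
    "Suggested external motif discovery settings (MEME-style):",
    "  minimum motif width: 6",
    "  maximum motif width: 18",
    "  site p-value cutoff for putative motifs: < 0.001"),
    paste0(path, ".settings.txt"))
  invisible(path)
}

#' Load an externally produced motif-hit table
#'
#' Parses a TSV of motif hits (shaped like a MEME/TomTom summary) with at
#' least the columns `module_id`, `consensus`, `p_value`; any extra columns
#' (matched TF motif, TF family, ...) are carried through. Rows whose p-value
#' does not parse are skipped with a warning. A `putative` flag marks hits
#' passing the p < 0.001 cutoff.
#'
#' @param path path to a TSV file (may be empty).
#' @return data.frame with a logical `putative` column appended.
#' @export
load_motif_hits <- function(path) {
  empty <- data.frame(module_id = character(), consensus = character(),
                      p_value = numeric(), putative = logical(),
                      stringsAsFactors = FALSE)
  if (!file.exists(path) || length(readLines(path, n = 1L)) == 0L)
    return(empty)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("module_id", "consensus", "p_value")
  if (!all(need %in% names(df)))
    stop("motif-hit table must contain columns module_id, consensus, p_value")
  if (nrow(df) == 0L) return(empty)
  p <- suppressWarnings(as.numeric(df$p_value))
  bad <- !is.finite(p)
  if (any(bad)) {
    warning(sprintf("%d malformed motif-hit row(s) skipped", sum(bad)))
    df <- df[!bad, , drop = FALSE]
    p <- p[!bad]
  }
  df$p_value <- p
  df$putative <- df$p_value < 0.001
  rownames(df) <- NULL
  df
}
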