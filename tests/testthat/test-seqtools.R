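test_that("upstream windows are sliced, truncated and strand-oriented correctly", {
  fx <- make_promoter_fixture(withr::local_tempdir())
  regions <- suppressWarnings(
    extract_upstream(fx$fa, fx$gff, c("geneA", "geneB", "geneC", "geneD"),
                     window = 500))
  rownames(regions) <- regions$gene_id

  # + strand gene starting at base 501: the full 500 bp window, bases 1..500
  expect_equal(regions["geneA", "sequence"], substr(fx$contig1, 1, 500))
  expect_equal(regions["geneA", "start"], 0L)
  expect_equal(regions["geneA", "end"], 500L)

  # + strand gene starting at base 3: truncated to 2 bases
  expect_equal(regions["geneB", "sequence"], substr(fx$contig1, 1, 2))
  expect_equal(nchar(regions["geneB", "sequence"]), 2L)

  # - strand gene ending at base 96 of a 100-base contig whose last four
  # bases are ACGT: upstream is the reverse complement of that slice
  expect_equal(regions["geneC", "sequence"],
               revcomp_str(substr(fx$contig2, 97, 100)))
  expect_equal(regions["geneC", "strand"], "-")

  # CDS present: the window anchors at the first CDS start, not the gene start
  expect_equal(regions["geneD", "sequence"], substr(fx$contig1, 1, 259))
  expect_equal(nchar(regions["geneD", "sequence"]), 259L)

  # length always equals the coordinate span
  expect_equal(nchar(regions$sequence), regions$end - regions$start)
})

test_that("missing genes warn and missing contigs are fatal", {
  fx <- make_promoter_fixture(withr::local_tempdir())
  expect_warning(res <- extract_upstream(fx$fa, fx$gff,
                                         c("geneA", "nosuchgene"), 500),
                 "not found")
  expect_equal(res$gene_id, "geneA")
  gff2 <- file.path(dirname(fx$fa), "bad.gff3")
  writeLines(c("##gff-version 3",
               "chrX\ttest\tgene\t501\t600\t.\t+\t.\tID=geneZ"), gff2)
  expect_error(extract_upstream(fx$fa, gff2, "geneZ"), "contig")
  expect_error(extract_upstream(fx$fa, fx$gff, "geneA", window = 0),
               "positive")
})

test_that("motif FASTA export round trips byte-stably", {
  fx <- make_promoter_fixture(withr::local_tempdir())
  regions <- extract_upstream(fx$fa, fx$gff, c("geneA", "geneC"), 500)
  out <- file.path(withr::local_tempdir(), "promoters.fasta")
  export_motif_fasta(regions, out)
  back <- Biostrings::readDNAStringSet(out)
  expect_equal(names(back), regions$gene_id)
  expect_equal(as.character(back), setNames(regions$sequence,
                                            regions$gene_id))
  expect_true(file.exists(paste0(out, ".settings.txt")))
  # rewriting produces identical bytes
  out2 <- file.path(dirname(out), "again.fasta")
  export_motif_fasta(regions, out2)
  expect_identical(readLines(out), readLines(out2))
  # N bases pass through verbatim
  regN <- regions[1, ]; regN$sequence <- "ACGTNNNACGT"
  outN <- file.path(dirname(out), "n.fasta")
  export_motif_fasta(regN, outN)
  expect_equal(as.character(Biostrings::readDNAStringSet(outN)[[1]]),
               "ACGTNNNACGT")
  expect_error(export_motif_fasta(regions[0, ], out), "no regions")
})

test_that("motif-hit tables parse with the putative cutoff applied", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("module_id\tconsensus\tp_value\tmatched_tf",
               "M001\tTGACGTCA\t1.68e-05\tbZIP",
               "M001\tAAAAAA\t0.01\tNA",
               "M002\tCCGCGG\tnot_a_number\tNA"), p)
  expect_warning(hits <- load_motif_hits(p), "malformed")
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$putative, c(TRUE, FALSE))
  expect_true("matched_tf" %in% names(hits))
  # an empty file yields an empty table
  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_equal(nrow(load_motif_hits(empty)), 0L)
})
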