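Package: gremod
Title: Gene Regulatory Module Inference via Transcription-Factor Decision Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers modules of co-regulated genes from a normalized expression
    matrix by iteratively (1) building a binary regulatory decision tree of
    transcription factors per gene cluster that partitions experimental
    conditions into Gaussian-modeled subgroups and (2) reassigning each gene to
    the tree under which its expression profile has maximum likelihood, until
    the assignment stabilizes. Includes differential-expression gene selection,
    exact one-dimensional K-means discretization of transcription-factor
    profiles, knee-based choice of the initial cluster number, module coherence
    and hypergeometric function-term enrichment statistics, promoter upstream
    sequence extraction for external motif analysis, and a synthetic data
    generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
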