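Package: polyAprofiler
Title: Poly(A) Tail Profiling from Nanopore Direct RNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of per-read poly(A) tail length estimates
    from nanopore direct RNA sequencing (DRS). Ingests Nanopolish "polya"
    tables, applies QC-tag filtering, collapses reads to per-transcript tail
    summaries (count, mean, median, geometric mean), normalizes abundances
    to library size with optional qPCR-derived coefficients, bins transcripts
    by expression, calls mRNAs with a substantial oligoadenylated fraction by
    comparing total and poly(A)+ libraries, classifies nuclease substrates
    from tail-length changes between strains, and runs tie-corrected
    Kruskal-Wallis, Dunn post-hoc and Holm-adjusted group statistics with
    ranked epsilon squared effect sizes. Includes a seeded read-level
    simulator of tail-length distributions, capture bias and spike-ins so
    the full pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
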