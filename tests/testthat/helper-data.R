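# Small in-code fixtures shared across test files.

makeRecords <- function(tails, transcript = "t1", sample = "s1",
                        qc = "PASS") {
    n <- length(tails)
    data.frame(read_id = sprintf("%s_r%03d", sample, seq_len(n)),
               transcript_id = rep_len(transcript, n),
               position = rep(0L, n),
               polya_length = tails,
               qc_tag = rep_len(qc, n),
               sample_id = rep(sample, n),
               stringsAsFactors = FALSE)
}

# a normalized summary table built directly (bypassing reads) for caller
# tests: one row per transcript
makeSummary <- function(ids, counts, meanTails, sample = "s",
                        displayScale = 1600000) {
    s <- data.frame(transcript_id = ids, n_reads = counts,
                    mean_tail = meanTails, median_tail = meanTails,
                    geom_mean_tail = meanTails, sample_id = sample,
                    stringsAsFactors = FALSE)
    normalizeLibrarySize(applyMinReadFilter(s), displayScale)
}

toyAnnotation <- function(ids, biotypes = "mRNA") {
    GenomicRanges::GRanges(
        seqnames = "chrT",
        ranges = IRanges::IRanges(start = seq_along(ids) * 1000L,
                                  width = 500L),
        strand = "+",
        feature_id = ids,
        biotype = rep_len(biotypes, length(ids)))
}
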