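## Detection filter, library-size normalization, expression binning and the
## ncRNA load ratio.

#' Apply the minimum-read detection filter
#'
#' Transcripts detected by `minReads` reads or fewer are kept in the table
#' but all their tail statistics are replaced by the placeholder value and
#' the record is flagged, so undetected transcripts can still enter
#' cross-library comparisons as sentinels. Raw read counts are retained
#' untouched for library-size accounting.
#'
#' @param summaries per-library summary data frame
#'   ([summarizeTranscripts()]).
#' @param minReads detection threshold; \code{n_reads <= minReads} is
#'   filtered (default 5, i.e. 6 reads are needed to count as detected).
#' @param placeholder sentinel value (default 0.01).
#' @return `summaries` with tail columns replaced by `placeholder` on
#'   filtered rows and a logical \code{placeholder_flag} column.
#' @export
applyMinReadFilter <- function(summaries, minReads = 5, placeholder = 0.01) {
    flag <- summaries$n_reads <= minReads
    for (col in intersect(c("mean_tail", "median_tail", "geom_mean_tail"),
                          names(summaries)))
        summaries[[col]][flag] <- placeholder
    summaries$placeholder_flag <- flag
    summaries
}

#' Normalize counts to library size
#'
#' Converts raw per-transcript read counts to reads per `displayScale`
#' mapped reads, optionally scaled by a per-library qPCR-derived
#' coefficient. The library total is the sum of all mapped PASS reads in the
#' library (including reads on transcripts later masked by the detection
#' filter), so normalization is independent of the filter. Placeholder rows
#' keep the placeholder as their normalized count and get \code{NA}
#' log2 abundance.
#'
#' The display scale (default 1,600,000, approximately the largest yeast DRS
#' library) affects only \code{norm_count}; \code{log2_abundance} is taken
#' on the library fraction itself so the expression-bin cutoffs
#' (-10, -12, -14) correspond to fractions 2^-10 and so on.
#'
#' @param summaries output of [applyMinReadFilter()] (or a raw summary
#'   table, in which case no placeholders exist).
#' @param displayScale multiplier applied to the library fraction for
#'   display.
#' @param qpcrCoefficient per-library multiplicative scalar (default 1).
#' @param placeholder sentinel value used by the detection filter.
#' @return `summaries` plus columns \code{norm_count},
#'   \code{log2_abundance} and \code{bin} ([binByExpression()]).
#' @export
normalizeLibrarySize <- function(summaries, displayScale = 1600000,
                                 qpcrCoefficient = 1, placeholder = 0.01) {
    if (is.null(summaries$placeholder_flag))
        summaries$placeholder_flag <- FALSE
    total <- sum(summaries$n_reads)
    if (total <= 0) stop("zero library total")
    frac <- summaries$n_reads / total * qpcrCoefficient
    summaries$norm_count <- ifelse(summaries$placeholder_flag, placeholder,
                                   frac * displayScale)
    summaries$log2_abundance <- ifelse(summaries$placeholder_flag, NA_real_,
                                       log2(frac))
    summaries$bin <- binByExpression(summaries$log2_abundance)
    summaries
}

#' Assign expression bins
#'
#' Bins log2 library-fraction abundances into the four expression classes:
#' \code{high} (x >= -10), \code{mod_high} (-12 < x < -10), \code{mod_min}
#' (-14 < x <= -12) and \code{minimal} (x <= -14). The -10 boundary, which
#' the printed definitions of the top two bins both contain, is assigned to
#' the higher bin.
#'
#' @param log2Abundance numeric vector; \code{NA} propagates, \code{NaN} is
#'   an error.
#' @return Factor with levels [EXPRESSION_BINS].
#' @examples
#' binByExpression(c(-9, -10, -11, -12, -13, -14, -15))
#' @export
binByExpression <- function(log2Abundance) {
    if (any(is.nan(log2Abundance)))
        stop("NaN log2 abundance")
    bin <- rep(NA_character_, length(log2Abundance))
    ok <- !is.na(log2Abundance)
    x <- log2Abundance[ok]
    bin[ok] <- ifelse(x >= -10, "high",
               ifelse(x > -12, "mod_high",
               ifelse(x > -14, "mod_min", "minimal")))
    factor(bin, levels = EXPRESSION_BINS)
}

#' ncRNA read load relative to protein-coding output
#'
#' For each noncoding biotype, the summed raw read count over all annotated
#' loci of that class divided by the summed count over all mRNA loci.
#' Annotated loci without reads contribute zero, so the ratio reflects the
#' class's total load, not just detected members.
#'
#' @param summaries per-library summary data frame with raw \code{n_reads}.
#' @param annotation `GRanges` annotation supplying the locus universe and
#'   biotypes.
#' @param biotypes noncoding classes to report.
#' @return Named numeric vector of count ratios.
#' @export
ncRNALoadRatio <- function(summaries, annotation,
                           biotypes = c("CUT", "SUT", "XUT", "sn_snoRNA",
                                        "rRNA")) {
    counts <- summaries$n_reads[match(annotation$feature_id,
                                      summaries$transcript_id)]
    counts[is.na(counts)] <- 0
    mrna <- sum(counts[annotation$biotype == "mRNA"])
    if (mrna <= 0) stop("no mRNA reads: zero denominator")
    vapply(setNames(biotypes, biotypes), function(b)
        sum(counts[annotation$biotype == b]) / mrna, numeric(1))
}
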