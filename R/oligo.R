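## Oligoadenylated-fraction caller: per-bin noise cutoffs estimated from WT
## replicates, then the two-criterion decision rule against total vs
## poly(A)+ libraries.

#' Estimate per-bin mean-tail noise cutoffs from replicate libraries
#'
#' The precision of a transcript's mean-tail estimate falls with its
#' abundance, so the caller uses a separate cutoff per expression bin. For
#' every transcript detected (non-placeholder) in at least two replicates,
#' the sample SD of its per-replicate mean tails is taken; each bin's cutoff
#' is then the chosen aggregate of these SDs over the transcripts assigned
#' to it (by replicate-averaged log2 abundance).
#'
#' @param replicateSummaries list of >= 2 normalized per-replicate summary
#'   tables ([normalizeLibrarySize()]).
#' @param aggregate how to pool per-transcript SDs within a bin:
#'   \code{"mean"} (default) or \code{"median"}.
#' @return An [OligoCutoffs-class]; errors if any bin is empty or its
#'   cutoff degenerates to zero.
#' @export
computeBinSDCutoffs <- function(replicateSummaries,
                                aggregate = c("mean", "median")) {
    aggregate <- match.arg(aggregate)
    if (!is.list(replicateSummaries) || length(replicateSummaries) < 2L)
        stop("need >= 2 replicate summary tables")
    long <- do.call(rbind, lapply(replicateSummaries, function(s)
        s[!s$placeholder_flag,
          c("transcript_id", "mean_tail", "log2_abundance")]))
    tally <- table(long$transcript_id)
    keep <- names(tally)[tally >= 2L]
    long <- long[long$transcript_id %in% keep, , drop = FALSE]
    if (nrow(long) == 0L) stop("no transcript detected in >= 2 replicates")
    sds <- tapply(long$mean_tail, long$transcript_id, sd)
    ab <- tapply(long$log2_abundance, long$transcript_id, mean)
    bins <- binByExpression(as.numeric(ab))
    agg <- if (aggregate == "mean") mean else median
    cut <- vapply(EXPRESSION_BINS, function(b) {
        v <- sds[!is.na(bins) & bins == b]
        if (length(v) == 0L)
            stop("no qualifying transcripts in bin '", b, "'")
        agg(v)
    }, numeric(1))
    if (any(cut <= 0))
        stop("degenerate input: zero replicate variability in bin(s) ",
             paste(EXPRESSION_BINS[cut <= 0], collapse = ", "))
    new("OligoCutoffs", cutoffs = cut)
}

#' Call mRNAs with a substantial oligoadenylated fraction
#'
#' Oligo-(dT) selection loses molecules with very short tails, so a
#' transcript with a large oligoadenylated subpopulation is (i) upregulated
#' in the total-RNA library relative to the poly(A)+ library and (ii) has a
#' lower mean tail there. The caller flags transcripts whose total/poly(A)+
#' normalized-abundance ratio exceeds `foldThreshold` AND whose mean-tail
#' change (total minus poly(A)+) is at most minus the cutoff of their
#' expression bin (taken from the poly(A)+ reference library).
#'
#' Only transcripts detected (non-placeholder) in both fractions are
#' evaluated.
#'
#' @param total,polyA normalized summary tables ([normalizeLibrarySize()])
#'   for the total and poly(A)+ libraries of one strain.
#' @param cutoffs an [OligoCutoffs-class].
#' @param foldThreshold minimum total/poly(A)+ abundance ratio (default
#'   1.2).
#' @return Data frame with one row per evaluated transcript:
#'   \code{transcript_id}, \code{fold_change_total_vs_polyA},
#'   \code{delta_mean_tail}, \code{bin}, \code{cutoff_used},
#'   \code{flagged}.
#' @export
callOligoFraction <- function(total, polyA, cutoffs, foldThreshold = 1.2) {
    stopifnot(is(cutoffs, "OligoCutoffs"))
    shared <- intersect(total$transcript_id[!total$placeholder_flag],
                        polyA$transcript_id[!polyA$placeholder_flag])
    ti <- match(shared, total$transcript_id)
    pi <- match(shared, polyA$transcript_id)
    ratio <- total$norm_count[ti] / polyA$norm_count[pi]
    delta <- total$mean_tail[ti] - polyA$mean_tail[pi]
    bin <- polyA$bin[pi]
    cut <- binCutoffs(cutoffs)[as.character(bin)]
    if (anyNA(cut)) stop("missing bin cutoff")
    data.frame(transcript_id = shared,
               fold_change_total_vs_polyA = ratio,
               delta_mean_tail = delta,
               bin = bin,
               cutoff_used = unname(cut),
               flagged = ratio > foldThreshold & delta <= -cut,
               row.names = NULL, stringsAsFactors = FALSE)
}
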