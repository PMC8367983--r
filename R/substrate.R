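## Strain-vs-strain tail and abundance changes, strong-target selection and
## nuclease-substrate categories.

#' Per-transcript changes between two libraries
#'
#' For every transcript detected (non-placeholder) in both the mutant and
#' reference tables: the change in mean tail (mutant minus reference,
#' adenosines) and the log2 fold change of normalized abundance. Any
#' library may serve as reference, so double-mutant vs single-mutant
#' contrasts are expressed the same way as mutant vs WT.
#'
#' @param mutant,reference normalized summary tables
#'   ([normalizeLibrarySize()]).
#' @return Data frame with \code{transcript_id}, \code{delta_mean_tail},
#'   \code{log2_fold_change_abundance}; empty if the detected sets do not
#'   intersect.
#' @export
computeDeltas <- function(mutant, reference) {
    shared <- intersect(mutant$transcript_id[!mutant$placeholder_flag],
                        reference$transcript_id[!reference$placeholder_flag])
    mi <- match(shared, mutant$transcript_id)
    ri <- match(shared, reference$transcript_id)
    data.frame(transcript_id = shared,
               delta_mean_tail = mutant$mean_tail[mi] -
                   reference$mean_tail[ri],
               log2_fold_change_abundance =
                   log2(mutant$norm_count[mi] / reference$norm_count[ri]),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Select strong nuclease targets
#'
#' Transcripts whose mean poly(A) tail is longer in the nuclease-deficient
#' strain by at least `elongationThreshold` adenosines (boundary inclusive).
#' Replicate-to-replicate mean-tail estimates oscillate within roughly +/-10
#' adenosines, so an elongation beyond that threshold is unlikely to be an
#' artifact -- hence the default of 10.
#'
#' @param deltas output of [computeDeltas()] against the matched control.
#' @param elongationThreshold minimum tail elongation in adenosines
#'   (default 10).
#' @return Character vector of flagged transcript ids.
#' @export
flagStrongTargets <- function(deltas, elongationThreshold = 10) {
    deltas$transcript_id[deltas$delta_mean_tail >= elongationThreshold]
}

SUBSTRATE_CATEGORIES <- c("exosome_only", "cytoplasmic_only", "both",
                          "unaffected", "undetected")

#' Classify mRNAs by nuclease sensitivity
#'
#' Partitions the annotated mRNA set by which decay machinery elongates its
#' tail when impaired: the nuclear exosome only, the cytoplasmic
#' deadenylases (PAN2/3 and/or CCR4-NOT) only, both, neither
#' (\code{unaffected}), or not detectable (\code{undetected}).
#'
#' @param exosomeSet,pan2Set,ccr4Set transcript ids flagged by
#'   [flagStrongTargets()] in the respective depletion/deletion strains.
#' @param detectedSet transcripts reproducibly detected by DRS.
#' @param annotatedMRNAs the full annotated mRNA universe.
#' @return Data frame with \code{transcript_id}, logical
#'   \code{exosome_target}, \code{pan2_target}, \code{ccr4_target} and a
#'   \code{category} factor; categories partition `annotatedMRNAs`.
#' @export
classifySubstrates <- function(exosomeSet, pan2Set, ccr4Set, detectedSet,
                               annotatedMRNAs) {
    sets <- list(exosome = exosomeSet, pan2 = pan2Set, ccr4 = ccr4Set,
                 detected = detectedSet)
    for (nm in names(sets)) {
        extra <- setdiff(sets[[nm]], annotatedMRNAs)
        if (length(extra))
            stop(nm, " set contains ids outside the annotation: ",
                 paste(utils::head(extra, 3), collapse = ", "))
    }
    exo <- annotatedMRNAs %in% exosomeSet
    cyt <- annotatedMRNAs %in% pan2Set | annotatedMRNAs %in% ccr4Set
    det <- annotatedMRNAs %in% detectedSet
    category <- ifelse(!det, "undetected",
                ifelse(exo & cyt, "both",
                ifelse(exo, "exosome_only",
                ifelse(cyt, "cytoplasmic_only", "unaffected"))))
    data.frame(transcript_id = annotatedMRNAs,
               exosome_target = exo,
               pan2_target = annotatedMRNAs %in% pan2Set,
               ccr4_target = annotatedMRNAs %in% ccr4Set,
               category = factor(category, levels = SUBSTRATE_CATEGORIES),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Substrate share of detected and annotated mRNAs
#'
#' From a classification (or raw category counts), the percentage of
#' detected and of annotated mRNAs that are substrates of at least one
#' nuclease (exosome-only + cytoplasmic-only + both).
#'
#' @param classification output of [classifySubstrates()], or a named
#'   numeric vector of category counts containing \code{exosome_only},
#'   \code{cytoplasmic_only} and \code{both}.
#' @param nDetected,nAnnotated denominators; derived from the
#'   classification when omitted (`nDetected` then counts every category
#'   except \code{undetected}).
#' @return Named numeric: \code{n_substrates}, \code{pct_of_detected},
#'   \code{pct_of_annotated}.
#' @examples
#' substrateFractions(c(exosome_only = 1643, cytoplasmic_only = 625,
#'                      both = 1588), nDetected = 4665, nAnnotated = 6230)
#' @export
substrateFractions <- function(classification, nDetected = NULL,
                               nAnnotated = NULL) {
    if (is.data.frame(classification)) {
        counts <- table(classification$category)
        if (is.null(nDetected))
            nDetected <- sum(counts[setdiff(SUBSTRATE_CATEGORIES,
                                            "undetected")])
        if (is.null(nAnnotated)) nAnnotated <- nrow(classification)
    } else counts <- classification
    need <- c("exosome_only", "cytoplasmic_only", "both")
    if (!all(need %in% names(counts)))
        stop("counts must include ", paste(need, collapse = ", "))
    if (is.null(nDetected) || is.null(nAnnotated))
        stop("nDetected and nAnnotated required with raw counts")
    if (nDetected <= 0 || nAnnotated <= 0) stop("zero denominator")
    if (nAnnotated < nDetected)
        stop("nAnnotated must be >= detected count")
    nsub <- sum(as.numeric(counts[need]))
    c(n_substrates = nsub,
      pct_of_detected = 100 * nsub / nDetected,
      pct_of_annotated = 100 * nsub / nAnnotated)
}
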