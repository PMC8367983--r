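#' @import methods
#' @importFrom stats median quantile rnorm runif rmultinom sd setNames
#'   pchisq pnorm dnorm qnorm plogis rbinom cor
#' @importFrom utils read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
NULL

## Controlled vocabularies shared across the package ------------------------

#' QC tags emitted by the Nanopolish polya segmentation
#'
#' Only reads tagged \code{PASS} carry a usable tail-length estimate; the
#' remaining tags mark segmentation failures and are excluded from all
#' downstream statistics.
#'
#' @format Character vector of the five tag values.
#' @export
QC_TAGS <- c("PASS", "ADAPTER", "NOREGION", "READ_FAILED_LOAD", "SUFFCLIP")

#' Transcript biotype vocabulary
#'
#' Biotypes carried by annotation features: protein-coding mRNA, the yeast
#' noncoding classes (CUTs, SUTs, XUTs, sn-/snoRNA, rRNA) and a catch-all
#' noncoding class.
#'
#' @format Character vector of biotype labels.
#' @export
BIOTYPES <- c("mRNA", "CUT", "SUT", "XUT", "sn_snoRNA", "rRNA", "other_nc")

#' Expression bin labels, highest first
#'
#' Four abundance classes on log2 library-fraction scale: \code{high}
#' (>= -10), \code{mod_high} (-12, -10), \code{mod_min} (-14, -12], and
#' \code{minimal} (<= -14). The -10 boundary is assigned upward to
#' \code{high}; -12 and -14 belong to the lower bin of each pair.
#'
#' @format Character vector of the four bin labels, ordered high to minimal.
#' @export
EXPRESSION_BINS <- c("high", "mod_high", "mod_min", "minimal")

## SimConfig -----------------------------------------------------------------

#' Configuration for the read-level DRS simulator
#'
#' Holds every knob of the synthetic data generator: the per-transcript
#' expression model, the steady-state and de novo tail-length models, the
#' oligoadenylated subpopulation, tail-dependent poly(A)+ capture, per-read
#' estimation noise, strain effects and spike-in designs. Construct with
#' [SimConfig()].
#'
#' @slot nTranscripts number of simulated transcripts.
#' @slot expressionLog2Mean,expressionLog2Sd location and spread of
#'   per-transcript log2 expression weights.
#' @slot wtTailMeanHigh,wtTailMeanLow steady-state mean tail (adenosines) at
#'   the highest and lowest expression; per-transcript means interpolate
#'   linearly in log2 expression between the two.
#' @slot tailSd within-transcript biological tail spread (adenosines).
#' @slot denovoMean,denovoCap de novo (export-blocked) tail model: normal
#'   mean and hard upper truncation, both in adenosines.
#' @slot oligoTranscriptFraction proportion of transcripts carrying an
#'   oligoadenylated subpopulation.
#' @slot oligoWeight per-read probability of the oligo component on flagged
#'   transcripts.
#' @slot oligoTailMax upper bound (adenosines) of oligo-component tails,
#'   drawn uniformly on [0, oligoTailMax].
#' @slot captureMidpoint,captureSteepness logistic tail-dependent poly(A)+
#'   capture: retention probability plogis((tail - midpoint) * steepness).
#' @slot estimationNoiseSd additive per-read measurement noise (adenosines).
#' @slot strains character vector of strain names; the first is the
#'   reference.
#' @slot denovoStrains strains whose reads are drawn from the de novo model.
#' @slot effectMap named list (by strain) of lists with elements
#'   \code{targets} (transcript ids), \code{tailShift} (adenosines, additive)
#'   and \code{abundanceFold} (multiplies expression weight).
#' @slot nReplicates biological replicates per strain.
#' @slot libSize reads per replicate library.
#' @slot qcFailRate fraction of reads given a random non-PASS tag.
#' @slot spikeinLengths designed spike-in tail lengths (adenosines).
#' @slot seed integer master seed; per-sample streams are derived from it.
#'
#' @seealso [simulateExperiment()], [simulateTotalVsPolyA()],
#'   [simulateSpikeins()]
#' @export
setClass("SimConfig", representation(
    nTranscripts = "integer",
    expressionLog2Mean = "numeric",
    expressionLog2Sd = "numeric",
    wtTailMeanHigh = "numeric",
    wtTailMeanLow = "numeric",
    tailSd = "numeric",
    denovoMean = "numeric",
    denovoCap = "numeric",
    oligoTranscriptFraction = "numeric",
    oligoWeight = "numeric",
    oligoTailMax = "numeric",
    captureMidpoint = "numeric",
    captureSteepness = "numeric",
    estimationNoiseSd = "numeric",
    strains = "character",
    denovoStrains = "character",
    effectMap = "list",
    nReplicates = "integer",
    libSize = "integer",
    qcFailRate = "numeric",
    spikeinLengths = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (length(object@nTranscripts) != 1L || is.na(object@nTranscripts) ||
        object@nTranscripts < 1L)
        msg <- c(msg, "nTranscripts must be a positive integer")
    lenpars <- c(
        wtTailMeanHigh = object@wtTailMeanHigh,
        wtTailMeanLow = object@wtTailMeanLow,
        tailSd = object@tailSd,
        denovoMean = object@denovoMean,
        denovoCap = object@denovoCap,
        oligoTailMax = object@oligoTailMax,
        estimationNoiseSd = object@estimationNoiseSd
    )
    if (any(!is.finite(lenpars)) || any(lenpars < 0))
        msg <- c(msg, "all length parameters must be finite and >= 0")
    if (object@denovoCap < object@denovoMean)
        msg <- c(msg, "denovoCap must be >= denovoMean")
    if (object@oligoWeight < 0 || object@oligoWeight > 1)
        msg <- c(msg, "oligoWeight must lie in [0, 1]")
    if (object@oligoTranscriptFraction < 0 || object@oligoTranscriptFraction > 1)
        msg <- c(msg, "oligoTranscriptFraction must lie in [0, 1]")
    if (object@qcFailRate < 0 || object@qcFailRate > 1)
        msg <- c(msg, "qcFailRate must lie in [0, 1]")
    if (object@captureSteepness <= 0)
        msg <- c(msg, "captureSteepness must be > 0")
    if (length(object@spikeinLengths) && any(object@spikeinLengths <= 0))
        msg <- c(msg, "spikeinLengths must be positive")
    if (!all(object@denovoStrains %in% object@strains))
        msg <- c(msg, "denovoStrains must be a subset of strains")
    if (length(object@effectMap) &&
        !all(names(object@effectMap) %in% object@strains))
        msg <- c(msg, "effectMap names must be strains")
    if (object@libSize < 1L) msg <- c(msg, "libSize must be >= 1")
    if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
    if (length(msg)) msg else TRUE
})

## OligoCutoffs ---------------------------------------------------------------

#' Per-expression-bin tail-decrease cutoffs for the oligo-fraction caller
#'
#' One positive magnitude (adenosines) per expression bin: the largest
#' decrease in mean tail between total and poly(A)+ fractions still
#' attributable to estimation noise at that abundance. A transcript must
#' drop by more than its bin's cutoff (and be >1.2-fold upregulated in
#' total RNA) to be called oligoadenylated. Construct with [OligoCutoffs()]
#' or estimate from replicate libraries with [computeBinSDCutoffs()].
#'
#' @slot cutoffs named numeric, one positive value per bin in
#'   [EXPRESSION_BINS].
#' @export
setClass("OligoCutoffs", representation(cutoffs = "numeric"))

setValidity("OligoCutoffs", function(object) {
    msg <- character()
    if (!identical(names(object@cutoffs), EXPRESSION_BINS))
        msg <- c(msg, sprintf("cutoffs must be named exactly: %s",
                              paste(EXPRESSION_BINS, collapse = ", ")))
    if (any(!is.finite(object@cutoffs)) || any(object@cutoffs <= 0))
        msg <- c(msg, "all cutoffs must be finite and > 0")
    if (length(msg)) msg else TRUE
})

## PolyATailExperiment --------------------------------------------------------

#' Transcript-by-sample container for tail profiling results
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding, per
#' transcript and library, the read counts and mean tail lengths produced by
#' the pipeline (assays \code{counts} and \code{meanTail}; optionally
#' \code{normCounts} and \code{log2Abundance} after normalization). Row
#' metadata carries the biotype; column metadata the sample sheet.
#'
#' @seealso [buildTailExperiment()], [readCounts()], [tailMeans()]
#' @export
setClass("PolyATailExperiment",
         contains = "SummarizedExperiment")

setValidity("PolyATailExperiment", function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("counts", "meanTail") %in% an))
        msg <- c(msg, "assays must include 'counts' and 'meanTail'")
    if (!"biotype" %in% colnames(SummarizedExperiment::rowData(object)))
        msg <- c(msg, "rowData must contain a 'biotype' column")
    if (length(msg)) msg else TRUE
})
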