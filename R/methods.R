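#' Create a simulator configuration
#'
#' Defaults describe a steady-state yeast DRS experiment: per-transcript
#' expression spanning roughly four log2 decades, mean steady-state tails of
#' about 40 adenosines read-weighted (30 A at the highest expression, 50 A at
#' the lowest), de novo tails of mean 50 A hard-capped at 200 A, a logistic
#' oligo-(dT) capture curve with midpoint 10 A, and spike-ins of 10-90 A in
#' steps of 10.
#'
#' @param nTranscripts number of transcripts to simulate.
#' @param expressionLog2Mean,expressionLog2Sd normal location/spread of
#'   per-transcript log2 expression weights.
#' @param wtTailMeanHigh,wtTailMeanLow steady-state mean tail (adenosines) at
#'   the highest/lowest expression.
#' @param tailSd within-transcript biological tail SD (adenosines).
#' @param denovoMean,denovoCap de novo tail normal mean and upper truncation.
#' @param oligoTranscriptFraction fraction of transcripts given an
#'   oligoadenylated subpopulation.
#' @param oligoWeight per-read probability of the oligo component.
#' @param oligoTailMax oligo-component tails are Uniform(0, oligoTailMax).
#' @param captureMidpoint,captureSteepness logistic poly(A)+ capture
#'   parameters (adenosines; 1/adenosines).
#' @param estimationNoiseSd per-read Gaussian measurement noise SD.
#' @param strains strain names; the first is the reference.
#' @param denovoStrains strains drawing tails from the de novo model.
#' @param effectMap named list per strain: \code{list(targets=, tailShift=,
#'   abundanceFold=)}.
#' @param nReplicates replicates per strain.
#' @param libSize reads per replicate library.
#' @param qcFailRate fraction of reads tagged non-PASS.
#' @param spikeinLengths designed spike-in lengths (adenosines).
#' @param seed integer master seed.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- SimConfig(nTranscripts = 100, libSize = 5000, seed = 1)
#' cfg
#' @export
SimConfig <- function(nTranscripts = 3000L,
                      expressionLog2Mean = 0,
                      expressionLog2Sd = 2,
                      wtTailMeanHigh = 30,
                      wtTailMeanLow = 50,
                      tailSd = 12,
                      denovoMean = 50,
                      denovoCap = 200,
                      oligoTranscriptFraction = 0.1,
                      oligoWeight = 0.4,
                      oligoTailMax = 9,
                      captureMidpoint = 10,
                      captureSteepness = 1,
                      estimationNoiseSd = 5,
                      strains = "WT",
                      denovoStrains = character(),
                      effectMap = list(),
                      nReplicates = 1L,
                      libSize = 300000L,
                      qcFailRate = 0.1,
                      spikeinLengths = seq(10, 90, by = 10),
                      seed = 1L) {
    new("SimConfig",
        nTranscripts = as.integer(nTranscripts),
        expressionLog2Mean = as.numeric(expressionLog2Mean),
        expressionLog2Sd = as.numeric(expressionLog2Sd),
        wtTailMeanHigh = as.numeric(wtTailMeanHigh),
        wtTailMeanLow = as.numeric(wtTailMeanLow),
        tailSd = as.numeric(tailSd),
        denovoMean = as.numeric(denovoMean),
        denovoCap = as.numeric(denovoCap),
        oligoTranscriptFraction = as.numeric(oligoTranscriptFraction),
        oligoWeight = as.numeric(oligoWeight),
        oligoTailMax = as.numeric(oligoTailMax),
        captureMidpoint = as.numeric(captureMidpoint),
        captureSteepness = as.numeric(captureSteepness),
        estimationNoiseSd = as.numeric(estimationNoiseSd),
        strains = as.character(strains),
        denovoStrains = as.character(denovoStrains),
        effectMap = effectMap,
        nReplicates = as.integer(nReplicates),
        libSize = as.integer(libSize),
        qcFailRate = as.numeric(qcFailRate),
        spikeinLengths = as.numeric(spikeinLengths),
        seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig\n")
    cat("  transcripts:", object@nTranscripts,
        " strains:", paste(object@strains, collapse = ", "), "\n")
    cat("  replicates:", object@nReplicates,
        " library size:", object@libSize, "reads\n")
    cat(sprintf("  steady-state tails: %.0f-%.0f A (sd %.1f), de novo %.0f A (cap %.0f)\n",
                object@wtTailMeanHigh, object@wtTailMeanLow, object@tailSd,
                object@denovoMean, object@denovoCap))
    cat(sprintf("  oligo: %.0f%% of transcripts, weight %.2f, tails <= %.0f A\n",
                100 * object@oligoTranscriptFraction, object@oligoWeight,
                object@oligoTailMax))
    cat(sprintf("  capture: logistic(midpoint %.0f A, steepness %.2f); noise sd %.1f A\n",
                object@captureMidpoint, object@captureSteepness,
                object@estimationNoiseSd))
    cat("  seed:", object@seed, "\n")
    invisible(object)
})

#' Construct per-bin oligo-calling cutoffs
#'
#' The defaults are the cutoffs used throughout yeast DRS work of this kind:
#' the replicate-to-replicate standard deviation of per-transcript mean-tail
#' estimates in each abundance bin, growing as expression (and hence read
#' depth) falls.
#'
#' @param high,modHigh,modMin,minimal positive cutoff magnitudes
#'   (adenosines) per expression bin.
#' @return An [OligoCutoffs-class] object.
#' @examples
#' OligoCutoffs()
#' @export
OligoCutoffs <- function(high = 1.727579, modHigh = 2.080906,
                         modMin = 2.763902, minimal = 4.157491) {
    new("OligoCutoffs", cutoffs = c(high = high, mod_high = modHigh,
                                    mod_min = modMin, minimal = minimal))
}

#' @rdname OligoCutoffs-class
#' @aliases binCutoffs,OligoCutoffs-method
#' @export
setMethod("binCutoffs", "OligoCutoffs", function(x) x@cutoffs)

setMethod("show", "OligoCutoffs", function(object) {
    cat("OligoCutoffs (adenosines, magnitude of allowed mean-tail decrease)\n")
    print(round(object@cutoffs, 6))
    invisible(object)
})

#' Assemble a transcript-by-sample tail experiment
#'
#' Binds a list of per-library summary tables (as returned by
#' [summarizeTranscripts()] or [normalizeLibrarySize()]) into a
#' [PolyATailExperiment-class]. Transcripts absent from a library get count 0
#' and NA tail.
#'
#' @param summaries named list of per-library summary data frames; names are
#'   sample ids.
#' @param annotation optional `GRanges` annotation (from
#'   [readAnnotationBED()] or the simulator); supplies biotypes and the
#'   transcript universe.
#' @param sampleData optional data frame of per-sample metadata, one row per
#'   element of `summaries`.
#' @return A [PolyATailExperiment-class] with assays `counts` and `meanTail`
#'   (plus `normCounts` / `log2Abundance` when present in the input).
#' @export
buildTailExperiment <- function(summaries, annotation = NULL,
                                sampleData = NULL) {
    stopifnot(is.list(summaries), length(summaries) >= 1L,
              !is.null(names(summaries)))
    ids <- unique(unlist(lapply(summaries, `[[`, "transcript_id")))
    if (!is.null(annotation))
        ids <- union(annotation$feature_id, ids)
    pull <- function(col, fill) {
        m <- vapply(summaries, function(s) {
            v <- s[[col]][match(ids, s$transcript_id)]
            if (is.null(s[[col]])) rep(NA_real_, length(ids))
            else { v[is.na(v)] <- fill; as.numeric(v) }
        }, numeric(length(ids)))
        m <- matrix(m, nrow = length(ids),
                    dimnames = list(ids, names(summaries)))
        m
    }
    assays <- list(counts = pull("n_reads", 0),
                   meanTail = pull("mean_tail", NA_real_))
    if (all(vapply(summaries, function(s) "norm_count" %in% names(s),
                   logical(1)))) {
        assays$normCounts <- pull("norm_count", NA_real_)
        assays$log2Abundance <- pull("log2_abundance", NA_real_)
    }
    biotype <- rep(NA_character_, length(ids))
    if (!is.null(annotation))
        biotype <- annotation$biotype[match(ids, annotation$feature_id)]
    else {
        bt <- do.call(rbind, lapply(summaries, function(s)
            if ("biotype" %in% names(s))
                s[, c("transcript_id", "biotype")] else NULL))
        if (!is.null(bt))
            biotype <- bt$biotype[match(ids, bt$transcript_id)]
    }
    cd <- if (is.null(sampleData))
        S4Vectors::DataFrame(sample_id = names(summaries),
                             row.names = names(summaries))
    else S4Vectors::DataFrame(sampleData, row.names = names(summaries))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays,
        rowData = S4Vectors::DataFrame(biotype = biotype, row.names = ids),
        colData = cd)
    new("PolyATailExperiment", se)
}

#' @rdname PolyATailExperiment-class
#' @aliases readCounts,PolyATailExperiment-method
#' @export
setMethod("readCounts", "PolyATailExperiment", function(x)
    SummarizedExperiment::assay(x, "counts"))

#' @rdname PolyATailExperiment-class
#' @aliases tailMeans,PolyATailExperiment-method
#' @export
setMethod("tailMeans", "PolyATailExperiment", function(x)
    SummarizedExperiment::assay(x, "meanTail"))

setMethod("show", "PolyATailExperiment", function(object) {
    callNextMethod()
    bt <- table(SummarizedExperiment::rowData(object)$biotype, useNA = "no")
    if (length(bt))
        cat("biotypes:", paste(sprintf("%s(%d)", names(bt), bt),
                               collapse = " "), "\n")
    invisible(object)
})
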