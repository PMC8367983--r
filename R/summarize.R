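## Per-transcript tail summaries and replicate pooling.

#' Summarize QC-PASS reads per transcript
#'
#' Collapses per-read tail estimates to one row per transcript: read count,
#' arithmetic mean, median (mean-of-middle-two for even n) and geometric
#' mean. For the geometric mean each tail is floored at 0.01 A so
#' zero-length tails do not annihilate it; this matches the 0.01 placeholder
#' scale used throughout the pipeline.
#'
#' @param records data frame of QC-filtered per-read records
#'   ([filterQCPass()]).
#' @param annotation optional `GRanges` annotation; adds a \code{biotype}
#'   column matched on \code{feature_id}.
#' @param geomFloor positivity floor (adenosines) applied before the
#'   geometric mean.
#' @return Data frame with columns \code{transcript_id}, \code{biotype} (if
#'   annotation given), \code{n_reads}, \code{mean_tail}, \code{median_tail},
#'   \code{geom_mean_tail}, \code{sample_id}; empty input gives an empty
#'   frame.
#' @examples
#' r <- data.frame(read_id = paste0("r", 1:3), transcript_id = "t1",
#'                 position = 0L, polya_length = c(10, 20, 40),
#'                 qc_tag = "PASS", sample_id = "s1")
#' summarizeTranscripts(r)  # mean 23.33, median 20, geometric mean 20
#' @export
summarizeTranscripts <- function(records, annotation = NULL,
                                 geomFloor = 0.01) {
    if (nrow(records) == 0L) {
        out <- data.frame(transcript_id = character(), n_reads = integer(),
                          mean_tail = numeric(), median_tail = numeric(),
                          geom_mean_tail = numeric(),
                          sample_id = character())
        return(out)
    }
    sample_id <- unique(records$sample_id)
    if (length(sample_id) != 1L)
        sample_id <- paste(sample_id, collapse = "+")
    tails <- split(records$polya_length, records$transcript_id)
    out <- data.frame(
        transcript_id = names(tails),
        n_reads = vapply(tails, length, integer(1)),
        mean_tail = vapply(tails, mean, numeric(1)),
        median_tail = vapply(tails, median, numeric(1)),
        geom_mean_tail = vapply(tails, function(x)
            exp(mean(log(pmax(x, geomFloor)))), numeric(1)),
        sample_id = sample_id,
        row.names = NULL, stringsAsFactors = FALSE)
    if (!is.null(annotation)) {
        out$biotype <- annotation$biotype[match(out$transcript_id,
                                                annotation$feature_id)]
        out <- out[, c("transcript_id", "biotype", "n_reads", "mean_tail",
                       "median_tail", "geom_mean_tail", "sample_id")]
    }
    out
}

#' Pool replicate libraries at the read level
#'
#' Replicates of one strain/condition/fraction are summed: records are
#' concatenated and all downstream summaries are recomputed on the pooled
#' reads, so counts add and tail statistics are read-depth weighted.
#'
#' @param recordList list of per-replicate read data frames.
#' @param sampleSheet optional sample sheet; when given, the replicates'
#'   sample ids must map to a single (strain, condition, fraction).
#' @param pooledId sample id given to the pooled records.
#' @return One data frame of concatenated records with
#'   \code{sample_id = pooledId}.
#' @export
poolReplicates <- function(recordList, sampleSheet = NULL,
                           pooledId = "pooled") {
    stopifnot(is.list(recordList), length(recordList) >= 1L)
    if (!is.null(sampleSheet)) {
        ids <- unique(unlist(lapply(recordList, `[[`, "sample_id")))
        rows <- sampleSheet[match(ids, sampleSheet$sample_id), , drop = FALSE]
        if (anyNA(rows$sample_id))
            stop("sample id(s) not in sample sheet: ",
                 paste(setdiff(ids, sampleSheet$sample_id), collapse = ", "))
        grp <- unique(rows[, c("strain", "condition", "fraction")])
        if (nrow(grp) != 1L)
            stop("cannot pool replicates from different ",
                 "strain/condition/fraction groups")
    }
    pooled <- do.call(rbind, recordList)
    pooled$sample_id <- pooledId
    rownames(pooled) <- NULL
    pooled
}

#' Empirical tail-length quantile
#'
#' Linear-interpolation empirical quantile of per-read tails; with
#' \code{q = 0.995} this is the convention used to report a gene set's
#' tail-length upper limit.
#'
#' @param x numeric tail vector, or a per-read data frame with a
#'   \code{polya_length} column.
#' @param q probability in (0, 1); default 0.995.
#' @return Tail length in adenosines.
#' @examples
#' tailQuantile(1:100, 0.5)  # 50.5
#' @export
tailQuantile <- function(x, q = 0.995) {
    if (is.data.frame(x)) x <- x$polya_length
    if (length(x) == 0L) stop("no tails supplied")
    if (!is.numeric(q) || any(q <= 0) || any(q >= 1))
        stop("q must lie strictly in (0, 1)")
    unname(quantile(x, probs = q, type = 7))
}
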