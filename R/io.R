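## Nanopolish polya tables, sample sheets and BED annotation.

NANOPOLISH_COLS <- c("readname", "contig", "position", "leader_start",
                     "adapter_start", "polya_start", "transcript_start",
                     "read_rate", "polya_length", "qc_tag")

#' Read a Nanopolish polya table
#'
#' Parses the 10-column TSV written by the Nanopolish \code{polya} command
#' and returns the per-read fields the pipeline uses. Row order is
#' preserved; signal-segmentation columns other than those below are
#' ignored.
#'
#' @param path path to a tab-delimited polya table with the standard header.
#' @param sampleId sample identifier attached to every record.
#' @return A data frame with columns \code{read_id}, \code{transcript_id},
#'   \code{position}, \code{polya_length}, \code{qc_tag}, \code{sample_id}.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writePolyATable(data.frame(read_id = "r1", transcript_id = "t1",
#'                            position = 0L, polya_length = 42,
#'                            qc_tag = "PASS", sample_id = "s1"), f)
#' readPolyATable(f, "s1")
#' @export
readPolyATable <- function(path, sampleId = basename(path)) {
    if (!file.exists(path)) stop("no such file: ", path)
    header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    missing <- setdiff(NANOPOLISH_COLS, header)
    if (length(missing))
        stop("not a Nanopolish polya table (", path,
             "): missing column(s) ", paste(missing, collapse = ", "))
    tab <- read.delim(path, sep = "\t", header = TRUE,
                      colClasses = "character", check.names = FALSE,
                      quote = "", comment.char = "")
    len <- suppressWarnings(as.numeric(tab$polya_length))
    bad <- which(!is.finite(len))
    if (length(bad))
        stop(sprintf("unparseable polya_length %s on line %d of %s",
                     dQuote(tab$polya_length[bad[1]]), bad[1] + 1L, path))
    len[len < 0] <- 0  # failed-segmentation sentinel (-1) carries no estimate
    bad_tag <- setdiff(unique(tab$qc_tag), QC_TAGS)
    if (length(bad_tag))
        stop("unknown qc_tag value(s): ", paste(bad_tag, collapse = ", "))
    data.frame(read_id = tab$readname,
               transcript_id = tab$contig,
               position = as.integer(tab$position),
               polya_length = len,
               qc_tag = tab$qc_tag,
               sample_id = rep(sampleId, nrow(tab)),
               stringsAsFactors = FALSE)
}

#' Write per-read records as a Nanopolish polya table
#'
#' Emits the full 10-column dialect so files round-trip through
#' [readPolyATable()]; signal columns the pipeline does not model are filled
#' with \code{-1} and \code{read_rate} with \code{0}.
#'
#' @param records data frame of per-read records (see [readPolyATable()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePolyATable <- function(records, path) {
    out <- data.frame(readname = records$read_id,
                      contig = records$transcript_id,
                      position = records$position,
                      leader_start = -1L,
                      adapter_start = -1L,
                      polya_start = -1L,
                      transcript_start = -1L,
                      read_rate = 0,
                      polya_length = format(records$polya_length,
                                            trim = TRUE, scientific = FALSE),
                      qc_tag = records$qc_tag,
                      stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Keep only QC-PASS reads
#'
#' Nanopolish tags each read's tail estimate; only \code{PASS} estimates are
#' admissible. Order is preserved and the operation is idempotent.
#'
#' @param records per-read data frame with a \code{qc_tag} column.
#' @return The subset of rows with \code{qc_tag == "PASS"}.
#' @export
filterQCPass <- function(records) {
    records[records$qc_tag == "PASS", , drop = FALSE]
}

#' Read or write a sample sheet
#'
#' The sample sheet maps each library file to its strain, condition,
#' fraction (\code{polyA_plus} or \code{total}) and replicate; an optional
#' \code{qpcr_coefficient} column carries per-library normalization scalars.
#'
#' @param path TSV path.
#' @return `readSampleSheet`: a data frame with one row per library;
#'   (strain, condition, fraction, replicate) must be unique.
#' @export
readSampleSheet <- function(path) {
    ss <- read.delim(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE, quote = "")
    need <- c("sample_id", "strain", "condition", "fraction", "replicate",
              "path")
    missing <- setdiff(need, names(ss))
    if (length(missing))
        stop("sample sheet missing column(s): ",
             paste(missing, collapse = ", "))
    if (!all(ss$fraction %in% c("polyA_plus", "total")))
        stop("fraction must be 'polyA_plus' or 'total'")
    key <- paste(ss$strain, ss$condition, ss$fraction, ss$replicate)
    if (anyDuplicated(key))
        stop("duplicate (strain, condition, fraction, replicate) in sample sheet")
    if (is.null(ss$qpcr_coefficient)) ss$qpcr_coefficient <- 1
    ss
}

#' @rdname readSampleSheet
#' @param sheet sample-sheet data frame.
#' @export
writeSampleSheet <- function(sheet, path) {
    write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read or write annotation as BED with a biotype column
#'
#' Six standard BED columns (0-based half-open) plus a 7th biotype column
#' from [BIOTYPES] (or the excluded classes handled by
#' [buildCustomAnnotation()]).
#'
#' @param path BED path.
#' @return `readAnnotationBED`: a `GRanges` with metadata columns
#'   \code{feature_id} and \code{biotype}.
#' @export
readAnnotationBED <- function(path) {
    tab <- read.delim(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, quote = "")
    if (ncol(tab) < 7L)
        stop("annotation BED needs 7 columns (chrom start end name score ",
             "strand biotype)")
    names(tab)[1:7] <- c("chrom", "start", "end", "name", "score", "strand",
                         "biotype")
    if (any(tab$end <= tab$start))
        stop("annotation features with end <= start")
    GenomicRanges::GRanges(
        seqnames = tab$chrom,
        ranges = IRanges::IRanges(start = tab$start + 1L, end = tab$end),
        strand = tab$strand,
        feature_id = tab$name,
        biotype = tab$biotype)
}

#' @rdname readAnnotationBED
#' @param gr annotation `GRanges` with \code{feature_id} and \code{biotype}.
#' @export
writeAnnotationBED <- function(gr, path) {
    tab <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr) - 1L,
        end = GenomicRanges::end(gr),
        name = gr$feature_id,
        score = 0L,
        strand = as.character(GenomicRanges::strand(gr)),
        biotype = gr$biotype)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Build a merged custom annotation
#'
#' Combines feature sets into one annotation the way custom yeast DRS
#' annotations are assembled: excluded biotypes (LTRs, transposons, tRNAs,
#' replication origins by default) are dropped, noncoding features shorter
#' than `minNCLength` are removed (reads that short cannot be mapped;
#' mRNAs are exempt), and overlapping same-strand noncoding features are
#' merged into a single feature spanning their union, its id concatenating
#' the constituent ids with \code{"|"} in coordinate order.
#'
#' @param featureSets a `GRanges` or list of `GRanges`, each with
#'   \code{feature_id} and \code{biotype} metadata columns.
#' @param minNCLength minimum noncoding feature length in bp (default 50).
#' @param excludedBiotypes biotype labels removed outright.
#' @return A `GRanges` annotation in which no two same-strand noncoding
#'   features overlap and every \code{feature_id} is unique.
#' @examples
#' gr <- GenomicRanges::GRanges("chrI",
#'     IRanges::IRanges(c(1, 100, 150), width = c(80, 80, 80)),
#'     strand = "+", feature_id = c("m1", "c1", "c2"),
#'     biotype = c("mRNA", "CUT", "CUT"))
#' buildCustomAnnotation(gr)
#' @export
buildCustomAnnotation <- function(featureSets, minNCLength = 50,
                                  excludedBiotypes = c("LTR", "transposon",
                                                       "tRNA",
                                                       "replication_origin")) {
    if (is(featureSets, "GRanges")) featureSets <- list(featureSets)
    gr <- suppressWarnings(do.call(c, unname(featureSets)))
    if (any(GenomicRanges::width(gr) < 1L))
        stop("features with end <= start")
    gr <- gr[!(gr$biotype %in% excludedBiotypes)]
    nc <- gr$biotype != "mRNA"
    gr <- gr[!(nc & GenomicRanges::width(gr) < minNCLength)]
    coding <- gr[gr$biotype == "mRNA"]
    noncod <- gr[gr$biotype != "mRNA"]
    if (length(noncod)) {
        red <- GenomicRanges::reduce(noncod, with.revmap = TRUE,
                                     ignore.strand = FALSE)
        ids <- vapply(red$revmap, function(i) {
            ord <- i[order(GenomicRanges::start(noncod)[i],
                           GenomicRanges::end(noncod)[i])]
            paste(noncod$feature_id[ord], collapse = "|")
        }, character(1))
        bts <- vapply(red$revmap, function(i) {
            u <- unique(noncod$biotype[i])
            if (length(u) == 1L) u else "other_nc"
        }, character(1))
        red$revmap <- NULL
        red$feature_id <- ids
        red$biotype <- bts
        out <- c(coding, red)
    } else out <- coding
    out <- GenomicRanges::sort(out, ignore.strand = TRUE)
    if (anyDuplicated(out$feature_id))
        stop("duplicate feature ids after merging")
    out
}
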