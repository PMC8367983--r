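## End-to-end orchestration: ingest -> QC filter -> pool -> summarize ->
## filter/normalize/bin -> oligo calling -> deltas/targets -> group stats,
## with a JSON run manifest. The pipeline itself is deterministic; the only
## randomness in the package lives in the simulator.

#' Read a pipeline run configuration
#'
#' Loads a YAML configuration and fills defaults for every analysis
#' constant: `min_reads` 5, `placeholder` 0.01, `display_scale` 1600000,
#' `fold_threshold` 1.2, `elongation_threshold` 10, `quantile` 0.995,
#' `cutoffs` \code{"auto"} (estimate from reference replicates when
#' possible, else the package defaults).
#'
#' @param path YAML file with at least `sample_sheet` and `annotation`
#'   paths; `outdir` may be overridden at run time.
#' @param overrides named list applied over the file's values (the CLI
#'   flag mechanism).
#' @return Named list of configuration values.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
    cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
    defaults <- list(sample_sheet = NULL, annotation = NULL, outdir = NULL,
                     min_reads = 5, placeholder = 0.01,
                     display_scale = 1600000, fold_threshold = 1.2,
                     elongation_threshold = 10, quantile = 0.995,
                     cutoffs = "auto", reference_strain = NULL,
                     seed = 1L, log_level = "info")
    cfg <- utils::modifyList(defaults, cfg)
    utils::modifyList(cfg, overrides)
}

.logmsg <- function(cfg, ...) {
    if (identical(cfg$log_level, "quiet")) return(invisible())
    message("[polyAprofiler] ", ...)
}

.resolveCutoffs <- function(cfg, repSummaries) {
    if (is(cfg$cutoffs, "OligoCutoffs")) return(cfg$cutoffs)
    if (is.numeric(cfg$cutoffs) && length(cfg$cutoffs) == 4L)
        return(OligoCutoffs(cfg$cutoffs[1], cfg$cutoffs[2], cfg$cutoffs[3],
                            cfg$cutoffs[4]))
    if (identical(cfg$cutoffs, "auto") && length(repSummaries) >= 2L) {
        ok <- try(computeBinSDCutoffs(repSummaries), silent = TRUE)
        if (!inherits(ok, "try-error")) return(ok)
    }
    OligoCutoffs()
}

#' Run the full poly(A) tail analysis pipeline
#'
#' Executes every stage on the libraries listed in the sample sheet and
#' writes, under `config$outdir`: per-group summary and normalized TSVs, a
#' transcript-by-sample matrix TSV of counts and mean tails, oligo calls
#' (when a strain has both fractions), per-strain delta and strong-target
#' TSVs against the reference strain, a group-statistics TSV, and
#' `manifest.json` recording the configuration, package version and input
#' checksums. Identical configuration and inputs produce identical outputs;
#' on error any partial outputs are removed.
#'
#' @param config list from [readRunConfig()] (or assembled directly).
#' @return Invisibly, a list with the in-memory results: `summaries`
#'   (normalized, one per pooled strain/condition/fraction group),
#'   `experiment` (a [PolyATailExperiment-class]), `oligoCalls`, `deltas`,
#'   `strongTargets`, `stats`, `manifest`.
#' @export
runPipeline <- function(config) {
    for (key in c("sample_sheet", "annotation", "outdir"))
        if (is.null(config[[key]])) stop("config lacks ", key)
    ## validate all inputs before producing any output
    sheet <- readSampleSheet(config$sample_sheet)
    ## relative library paths resolve against the sample sheet's directory
    rel <- !grepl("^(/|[A-Za-z]:)", sheet$path)
    sheet$path[rel] <- file.path(dirname(config$sample_sheet),
                                 sheet$path[rel])
    missing <- sheet$path[!file.exists(sheet$path)]
    if (length(missing))
        stop("sample sheet references missing file(s): ",
             paste(missing, collapse = ", "))
    annotation <- readAnnotationBED(config$annotation)
    outdir <- config$outdir
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    written <- character()
    emit <- function(obj, name) {
        p <- file.path(outdir, name)
        write.table(obj, p, sep = "\t", quote = FALSE, row.names = FALSE)
        written <<- c(written, p)
        p
    }
    tryCatch({
        .logmsg(config, "ingesting ", nrow(sheet), " libraries")
        perSample <- lapply(seq_len(nrow(sheet)), function(i)
            filterQCPass(readPolyATable(sheet$path[i], sheet$sample_id[i])))
        names(perSample) <- sheet$sample_id

        ## pool replicates within strain/condition/fraction
        grp <- paste(sheet$strain, sheet$condition, sheet$fraction,
                     sep = ".")
        pooled <- lapply(split(seq_len(nrow(sheet)), grp), function(idx)
            poolReplicates(perSample[idx], sheet,
                           pooledId = grp[idx[1]]))
        groupMeta <- sheet[!duplicated(grp),
                           c("strain", "condition", "fraction")]
        rownames(groupMeta) <- unique(grp)
        qpcr <- vapply(split(sheet$qpcr_coefficient, grp), mean, numeric(1))

        .logmsg(config, "summarizing ", length(pooled), " pooled groups")
        normalized <- lapply(names(pooled), function(g) {
            s <- summarizeTranscripts(pooled[[g]], annotation)
            s <- applyMinReadFilter(s, config$min_reads, config$placeholder)
            normalizeLibrarySize(s, config$display_scale, qpcr[[g]],
                                 config$placeholder)
        })
        names(normalized) <- names(pooled)
        for (g in names(normalized))
            emit(normalized[[g]], paste0(g, ".summary.tsv"))

        exper <- buildTailExperiment(normalized, annotation,
                                     groupMeta[names(normalized), ])
        mat <- data.frame(transcript_id = rownames(exper),
                          biotype =
                              SummarizedExperiment::rowData(exper)$biotype,
                          readCounts(exper), tailMeans(exper),
                          check.names = FALSE)
        names(mat) <- c("transcript_id", "biotype",
                        paste0("count.", colnames(exper)),
                        paste0("mean_tail.", colnames(exper)))
        emit(mat, "transcript_matrix.tsv")

        ## oligo calling wherever a strain/condition has both fractions
        refStrain <- if (is.null(config$reference_strain))
            groupMeta$strain[1] else config$reference_strain
        refReps <- sheet$sample_id[sheet$strain == refStrain &
                                   sheet$fraction == "polyA_plus"]
        repSumm <- lapply(perSample[refReps], function(r)
            normalizeLibrarySize(applyMinReadFilter(
                summarizeTranscripts(r, annotation),
                config$min_reads, config$placeholder),
                config$display_scale, 1, config$placeholder))
        cutoffs <- .resolveCutoffs(config, repSumm)
        oligoCalls <- list()
        for (sc in unique(paste(groupMeta$strain, groupMeta$condition,
                                sep = "."))) {
            gTot <- rownames(groupMeta)[paste(groupMeta$strain,
                                              groupMeta$condition,
                                              sep = ".") == sc &
                                        groupMeta$fraction == "total"]
            gPol <- rownames(groupMeta)[paste(groupMeta$strain,
                                              groupMeta$condition,
                                              sep = ".") == sc &
                                        groupMeta$fraction == "polyA_plus"]
            if (length(gTot) == 1L && length(gPol) == 1L) {
                oc <- callOligoFraction(normalized[[gTot]],
                                        normalized[[gPol]], cutoffs,
                                        config$fold_threshold)
                oligoCalls[[sc]] <- oc
                emit(oc, paste0(sc, ".oligo_calls.tsv"))
            }
        }

        ## deltas and strong targets vs the reference strain
        polyGroups <- rownames(groupMeta)[groupMeta$fraction ==
                                          "polyA_plus"]
        refGroup <- polyGroups[groupMeta[polyGroups, "strain"] ==
                               refStrain][1]
        deltas <- list(); strong <- list()
        if (!is.na(refGroup)) {
            for (g in setdiff(polyGroups, refGroup)) {
                d <- computeDeltas(normalized[[g]], normalized[[refGroup]])
                deltas[[g]] <- d
                strong[[g]] <- flagStrongTargets(
                    d, config$elongation_threshold)
                emit(d, paste0(g, ".deltas.tsv"))
                emit(data.frame(transcript_id = strong[[g]]),
                     paste0(g, ".strong_targets.tsv"))
            }
        }

        ## group statistics on detected mean tails across strains
        stats <- NULL
        if (length(polyGroups) >= 2L) {
            groupsTails <- lapply(normalized[polyGroups], function(s)
                s$mean_tail[!s$placeholder_flag])
            names(groupsTails) <- polyGroups
            stats <- compareGroups(groupsTails)
            statTab <- data.frame(
                comparison = "mean_tail_across_groups",
                H = stats$H, p_value = stats$p_value,
                epsilon_sq = stats$epsilon_sq, n_total = stats$n_total)
            emit(statTab, "group_stats.tsv")
            emit(stats$pairwise, "group_stats_pairwise.tsv")
        }

        manifest <- list(
            package = "polyAprofiler",
            version = as.character(utils::packageVersion("polyAprofiler")),
            config = config[!vapply(config, is.object, logical(1))],
            inputs = list(
                sample_sheet = unname(tools::md5sum(config$sample_sheet)),
                annotation = unname(tools::md5sum(config$annotation)),
                libraries = as.list(tools::md5sum(sheet$path))),
            cutoffs = as.list(binCutoffs(cutoffs)),
            outputs = basename(written))
        manifestPath <- file.path(outdir, "manifest.json")
        jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                             pretty = TRUE, digits = NA)
        written <- c(written, manifestPath)
        .logmsg(config, "wrote ", length(written), " files to ", outdir)
        invisible(list(summaries = normalized, experiment = exper,
                       oligoCalls = oligoCalls, deltas = deltas,
                       strongTargets = strong, stats = stats,
                       manifest = manifest))
    }, error = function(e) {
        unlink(written)
        stop(e)
    })
}
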