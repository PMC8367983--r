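## Seeded read-level simulator of DRS poly(A) tail data. One RNG stream per
## sample file, with the stream seed derived from (master seed, sample id),
## so adding a sample never perturbs the others.

## Deterministic 32-bit-safe seed derived from the master seed and a label
## (FNV-style accumulation over the label's bytes).
.deriveSeed <- function(seed, label) {
    h <- (as.numeric(seed) %% 2147483647) + 1
    for (b in utf8ToInt(label))
        h <- (h * 131 + b) %% 2147483647
    as.integer(h)
}

.withStream <- function(seed, label, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(.deriveSeed(seed, label))
    force(expr)
}

## Truncated-normal draws on [lo, hi] by inverse-CDF (exact, vectorized).
.rtruncnorm <- function(n, mean, sd, lo = 0, hi = Inf) {
    if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
    plo <- pnorm(lo, mean, sd)
    phi <- pnorm(hi, mean, sd)
    qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

## Mean of the truncated normal on [lo, hi] (closed form).
.truncnormMean <- function(mean, sd, lo = 0, hi = Inf) {
    if (sd == 0) return(pmin(pmax(mean, lo), hi))
    a <- (lo - mean) / sd
    b <- (hi - mean) / sd
    mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

## Per-transcript expression weights and steady-state mean tails. Tail
## length anticorrelates with expression: per-transcript means interpolate
## linearly in log2 expression between the configured extremes.
.transcriptModel <- function(cfg) {
    ids <- sprintf("TX%05d", seq_len(cfg@nTranscripts))
    log2expr <- .withStream(cfg@seed, "transcript_model",
        rnorm(cfg@nTranscripts, cfg@expressionLog2Mean, cfg@expressionLog2Sd))
    rng <- range(log2expr)
    relExpr <- if (diff(rng) > 0) (log2expr - rng[1]) / diff(rng)
               else rep(0.5, cfg@nTranscripts)
    meanTail <- cfg@wtTailMeanLow +
        relExpr * (cfg@wtTailMeanHigh - cfg@wtTailMeanLow)
    ## oligo subpopulation membership: probability of carrying one grows
    ## with expression rank, scaled so the expected fraction matches cfg
    prob <- if (cfg@oligoTranscriptFraction >= 1) rep(1, cfg@nTranscripts)
            else if (cfg@oligoTranscriptFraction <= 0)
                rep(0, cfg@nTranscripts)
            else {
                pr <- rank(log2expr) / cfg@nTranscripts
                pr * cfg@oligoTranscriptFraction /
                    mean(pr)  # E[flag] = oligoTranscriptFraction
            }
    oligo <- .withStream(cfg@seed, "oligo_flags",
                         runif(cfg@nTranscripts) < pmin(prob, 1))
    data.frame(transcript_id = ids, log2_expression = log2expr,
               wt_mean_tail = meanTail, oligo = oligo,
               stringsAsFactors = FALSE)
}

## Strain-adjusted expression weights and true mean tails.
.strainModel <- function(cfg, model, strain) {
    eff <- cfg@effectMap[[strain]]
    w <- 2^model$log2_expression
    mu <- if (strain %in% cfg@denovoStrains)
        rep(.truncnormMean(cfg@denovoMean, cfg@tailSd, 0, cfg@denovoCap),
            nrow(model))
    else model$wt_mean_tail
    target <- rep(FALSE, nrow(model))
    if (!is.null(eff)) {
        unknown <- setdiff(eff$targets, model$transcript_id)
        if (length(unknown))
            stop("effectMap for ", strain, " references unknown ",
                 "transcript(s): ", paste(utils::head(unknown, 3),
                                          collapse = ", "))
        target <- model$transcript_id %in% eff$targets
        if (!is.null(eff$tailShift)) mu[target] <- mu[target] + eff$tailShift
        if (!is.null(eff$abundanceFold))
            w[target] <- w[target] * eff$abundanceFold
    }
    list(weights = w / sum(w), trueMean = mu, target = target)
}

## Draw one library's reads for a strain. Component draw, then additive
## estimation noise, then floor at zero.
.drawLibrary <- function(cfg, model, sm, sampleId, oligoActive = FALSE) {
    counts <- drop(rmultinom(1, cfg@libSize, sm$weights))
    n <- sum(counts)
    tx <- rep.int(seq_len(nrow(model)), counts)
    isDenovo <- isTRUE(attr(sm, "denovo"))
    if (isDenovo) {
        comp <- .rtruncnorm(n, cfg@denovoMean, cfg@tailSd, 0, cfg@denovoCap)
        shift <- sm$trueMean[tx] -
            .truncnormMean(cfg@denovoMean, cfg@tailSd, 0, cfg@denovoCap)
        comp <- comp + shift  # effect-map shifts on top of de novo draw
    } else {
        comp <- pmax(0, rnorm(n, sm$trueMean[tx], cfg@tailSd))
    }
    if (oligoActive && any(model$oligo) && cfg@oligoWeight > 0) {
        isOligo <- model$oligo[tx] & runif(n) < cfg@oligoWeight
        comp[isOligo] <- runif(sum(isOligo), 0, cfg@oligoTailMax)
    } else isOligo <- rep(FALSE, n)
    tail <- pmax(0, comp + rnorm(n, 0, cfg@estimationNoiseSd))
    qc <- rep("PASS", n)
    nfail <- rbinom(1, n, cfg@qcFailRate)
    if (nfail > 0) {
        idx <- sample.int(n, nfail)
        qc[idx] <- sample(setdiff(QC_TAGS, "PASS"), nfail, replace = TRUE)
    }
    data.frame(read_id = sprintf("%s_read%07d", sampleId, seq_len(n)),
               transcript_id = model$transcript_id[tx],
               position = 0L,
               polya_length = round(tail, 2),
               qc_tag = qc,
               sample_id = sampleId,
               oligo_component = isOligo,
               stringsAsFactors = FALSE)
}

.simAnnotation <- function(model) {
    n <- nrow(model)
    width <- 1500L
    GenomicRanges::GRanges(
        seqnames = "chrSim",
        ranges = IRanges::IRanges(start = seq_len(n) * 2000L,
                                  width = width),
        strand = "+",
        feature_id = model$transcript_id,
        biotype = "mRNA")
}

#' Simulate a multi-strain DRS poly(A)+ experiment
#'
#' Draws, for every configured strain and replicate, a read-level table in
#' the Nanopolish polya dialect: per-transcript read counts are multinomial
#' over expression weights; per-read tails are the strain's component draw
#' (steady-state normal, or a [0, cap]-truncated normal for de novo
#' strains) plus additive Gaussian estimation noise, floored at zero; a
#' configurable fraction of reads receives a random non-PASS QC tag.
#' Strain effects from the config's \code{effectMap} shift the target
#' transcripts' tails and scale their abundance.
#'
#' @param cfg a [SimConfig-class].
#' @param dir optional directory; when given, read tables, annotation,
#'   sample sheet and ground truth are also written there as TSV/BED.
#' @return List with \code{reads} (named list of per-sample read data
#'   frames), \code{annotation} (`GRanges`), \code{sampleSheet},
#'   and \code{truth} (list \code{transcripts} -- one row per transcript
#'   per strain with the true mean tail, oligo flag/weight and target
#'   status -- \code{librarySizes}, \code{spikeinLengths}).
#' @export
simulateExperiment <- function(cfg, dir = NULL) {
    stopifnot(is(cfg, "SimConfig"))
    validObject(cfg)
    model <- .transcriptModel(cfg)
    reads <- list()
    sheet <- list()
    truthTx <- list()
    for (strain in cfg@strains) {
        sm <- .strainModel(cfg, model, strain)
        attr(sm, "denovo") <- strain %in% cfg@denovoStrains
        truthTx[[strain]] <- data.frame(
            transcript_id = model$transcript_id,
            strain = strain,
            true_mean_tail = sm$trueMean,
            oligo = model$oligo,
            oligo_weight = ifelse(model$oligo, cfg@oligoWeight, 0),
            target = sm$target,
            stringsAsFactors = FALSE)
        for (rep_i in seq_len(cfg@nReplicates)) {
            sampleId <- sprintf("%s_rep%d", strain, rep_i)
            reads[[sampleId]] <- .withStream(cfg@seed, sampleId,
                .drawLibrary(cfg, model, sm, sampleId))
            sheet[[sampleId]] <- data.frame(
                sample_id = sampleId, strain = strain,
                condition = "steady_state", fraction = "polyA_plus",
                replicate = rep_i,
                ## relative to the sample sheet's own location, so a
                ## simulated dataset is relocatable and byte-reproducible
                path = paste0(sampleId, ".polya.tsv"),
                qpcr_coefficient = 1,
                stringsAsFactors = FALSE)
        }
    }
    sampleSheet <- do.call(rbind, c(sheet, make.row.names = FALSE))
    truth <- list(
        transcripts = do.call(rbind, c(truthTx, make.row.names = FALSE)),
        librarySizes = vapply(reads, nrow, integer(1)),
        spikeinLengths = cfg@spikeinLengths)
    annotation <- .simAnnotation(model)
    out <- list(reads = lapply(reads, function(r) {
                    r$oligo_component <- NULL; r
                }),
                annotation = annotation, sampleSheet = sampleSheet,
                truth = truth)
    if (!is.null(dir)) .writeSimulation(out, dir)
    out
}

.writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (sid in names(sim$reads))
        writePolyATable(sim$reads[[sid]],
                        file.path(dir, paste0(sid, ".polya.tsv")))
    writeAnnotationBED(sim$annotation, file.path(dir, "annotation.bed"))
    writeSampleSheet(sim$sampleSheet, file.path(dir, "sample_sheet.tsv"))
    write.table(sim$truth$transcripts, file.path(dir, "ground_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' Simulate paired total and poly(A)+ libraries
#'
#' Emulates oligo-(dT) capture bias: the "total" library contains every
#' read, including the oligoadenylated component (tails uniform on
#' [0, oligoTailMax]) on oligo-flagged transcripts; the "poly(A)+" library
#' retains each read with probability
#' \code{plogis((tail - captureMidpoint) * captureSteepness)} (a step
#' function at the midpoint when steepness is infinite). Oligo-flagged
#' transcripts therefore show a higher total/poly(A)+ count ratio and a
#' lower total-fraction mean tail.
#'
#' @param cfg a [SimConfig-class]; only its first strain is used.
#' @param dir optional output directory, as in [simulateExperiment()].
#' @return List with \code{total} and \code{polyA} read data frames (the
#'   poly(A)+ reads are a subset of the total reads), \code{annotation},
#'   \code{sampleSheet} and \code{truth}.
#' @export
simulateTotalVsPolyA <- function(cfg, dir = NULL) {
    stopifnot(is(cfg, "SimConfig"))
    validObject(cfg)
    if (cfg@captureSteepness <= 0) stop("captureSteepness must be > 0")
    model <- .transcriptModel(cfg)
    strain <- cfg@strains[1]
    sm <- .strainModel(cfg, model, strain)
    attr(sm, "denovo") <- FALSE
    sampleId <- paste0(strain, "_total")
    total <- .withStream(cfg@seed, sampleId,
        .drawLibrary(cfg, model, sm, sampleId, oligoActive = TRUE))
    retain <- if (is.infinite(cfg@captureSteepness))
        as.numeric(total$polya_length > cfg@captureMidpoint)
    else plogis((total$polya_length - cfg@captureMidpoint) *
                cfg@captureSteepness)
    keep <- .withStream(cfg@seed, paste0(sampleId, "_capture"),
                        runif(nrow(total)) < retain)
    polyA <- total[keep, , drop = FALSE]
    polyA$sample_id <- paste0(strain, "_polyA")
    rownames(polyA) <- NULL
    truthTx <- data.frame(
        transcript_id = model$transcript_id,
        strain = strain,
        true_mean_tail = sm$trueMean,
        oligo = model$oligo,
        oligo_weight = ifelse(model$oligo, cfg@oligoWeight, 0),
        target = sm$target,
        stringsAsFactors = FALSE)
    sheet <- data.frame(
        sample_id = c(sampleId, paste0(strain, "_polyA")),
        strain = strain, condition = "steady_state",
        fraction = c("total", "polyA_plus"), replicate = 1L,
        path = paste0(c(sampleId, paste0(strain, "_polyA")), ".polya.tsv"),
        qpcr_coefficient = 1, stringsAsFactors = FALSE)
    total$oligo_component <- NULL
    polyA$oligo_component <- NULL
    out <- list(total = total, polyA = polyA,
                annotation = .simAnnotation(model), sampleSheet = sheet,
                truth = list(transcripts = truthTx,
                             librarySizes = c(total = nrow(total),
                                              polyA = nrow(polyA)),
                             spikeinLengths = cfg@spikeinLengths))
    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        writePolyATable(total, file.path(dir, sheet$path[1]))
        writePolyATable(polyA, file.path(dir, sheet$path[2]))
        writeAnnotationBED(out$annotation, file.path(dir, "annotation.bed"))
        writeSampleSheet(sheet, file.path(dir, "sample_sheet.tsv"))
        write.table(truthTx, file.path(dir, "ground_truth.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out
}

#' Simulate spike-in reads of designed tail lengths
#'
#' Emits `nReadsEach` PASS reads per designed length; each read's tail is
#' the designed length plus Gaussian noise, floored at zero. Spike-ins of
#' designed lengths 10-90 A are the calibration standard for DRS tail
#' estimation.
#'
#' @param lengths positive designed tail lengths (adenosines).
#' @param nReadsEach reads per designed length.
#' @param noiseSd per-read measurement noise SD (adenosines).
#' @param seed integer seed.
#' @return Per-read data frame; \code{transcript_id} is
#'   \code{spike_<length>A}.
#' @examples
#' head(simulateSpikeins(c(10, 90), nReadsEach = 3, noiseSd = 0, seed = 1))
#' @export
simulateSpikeins <- function(lengths = seq(10, 90, by = 10),
                             nReadsEach = 1000, noiseSd = 2, seed = 1L) {
    if (length(lengths) == 0L) stop("empty lengths")
    if (any(lengths <= 0)) stop("lengths must be positive")
    n <- length(lengths) * nReadsEach
    designed <- rep(lengths, each = nReadsEach)
    tails <- .withStream(seed, "spikeins",
                         pmax(0, designed + rnorm(n, 0, noiseSd)))
    data.frame(read_id = sprintf("spike_read%07d", seq_len(n)),
               transcript_id = sprintf("spike_%gA", designed),
               position = 0L,
               polya_length = round(tails, 2),
               qc_tag = "PASS",
               sample_id = "spikein",
               designed_length = designed,
               stringsAsFactors = FALSE)
}
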