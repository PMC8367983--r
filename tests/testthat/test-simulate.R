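test_that("noise-free degenerate config yields constant tails", {
    cfg <- SimConfig(nTranscripts = 1, libSize = 100, seed = 7,
                     wtTailMeanHigh = 50, wtTailMeanLow = 50,
                     tailSd = 0, estimationNoiseSd = 0, qcFailRate = 0.2)
    sim <- simulateExperiment(cfg)
    reads <- sim$reads[[1]]
    expect_equal(nrow(reads), 100L)
    pass <- filterQCPass(reads)
    expect_true(all(pass$polya_length == 50))
    expect_true(all(reads$qc_tag %in% QC_TAGS))
    expect_gt(sum(reads$qc_tag != "PASS"), 0)
})

test_that("identical config and seed give byte-identical output files", {
    cfg <- SimConfig(nTranscripts = 20, libSize = 2000, seed = 7,
                     nReplicates = 2)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    simulateExperiment(cfg, dir = d1)
    simulateExperiment(cfg, dir = d2)
    files <- list.files(d1)
    expect_true(length(files) >= 4)
    for (f in files)
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)),
                         label = f)
})

test_that("adding a strain leaves existing samples untouched", {
    base <- SimConfig(nTranscripts = 30, libSize = 1000, seed = 12)
    more <- SimConfig(nTranscripts = 30, libSize = 1000, seed = 12,
                      strains = c("WT", "mutX"),
                      effectMap = list(mutX = list(targets = "TX00001",
                                                   tailShift = 12)))
    s1 <- simulateExperiment(base)
    s2 <- simulateExperiment(more)
    expect_identical(s1$reads$WT_rep1, s2$reads$WT_rep1)
})

test_that("de novo tails match the truncated-normal mean by integration", {
    cfg <- SimConfig(nTranscripts = 1, libSize = 10000, seed = 31,
                     strains = "denovo", denovoStrains = "denovo",
                     denovoMean = 50, tailSd = 15, denovoCap = 200,
                     estimationNoiseSd = 0, qcFailRate = 0)
    sim <- simulateExperiment(cfg)
    tails <- filterQCPass(sim$reads[[1]])$polya_length
    oracle <- truncNormMeanNum(50, 15, 0, 200)
    expect_lt(abs(mean(tails) - oracle), 3 * 15 / sqrt(10000))
    expect_true(all(tails <= 200))
    expect_true(all(tails >= 0))
    # and the recorded ground truth carries the same mean
    expect_lt(abs(sim$truth$transcripts$true_mean_tail[1] - oracle), 0.01)
})

test_that("ground truth covers every transcript once per strain", {
    cfg <- SimConfig(nTranscripts = 25, libSize = 500, seed = 9,
                     strains = c("WT", "m1"),
                     effectMap = list(m1 = list(targets = c("TX00003"),
                                                tailShift = 10)))
    sim <- simulateExperiment(cfg)
    tt <- sim$truth$transcripts
    expect_equal(nrow(tt), 50L)
    expect_equal(as.integer(table(tt$strain)), c(25L, 25L))
    expect_false(anyDuplicated(tt[, c("transcript_id", "strain")]) > 0)
    # emitted reads only reference known transcripts
    expect_true(all(sim$reads$m1_rep1$transcript_id %in% tt$transcript_id))
    # library sizes are conserved
    expect_equal(unname(sim$truth$librarySizes),
                 vapply(sim$reads, nrow, integer(1), USE.NAMES = FALSE))
})

test_that("invalid configurations are rejected", {
    expect_error(SimConfig(nTranscripts = 0), "positive")
    expect_error(SimConfig(denovoMean = 60, denovoCap = 50), "denovoCap")
    expect_error(SimConfig(oligoWeight = 1.5), "oligoWeight")
    expect_error(SimConfig(captureSteepness = 0), "captureSteepness")
    expect_error(simulateExperiment(
        SimConfig(nTranscripts = 5, libSize = 100,
                  strains = c("WT", "m"),
                  effectMap = list(m = list(targets = "nope",
                                            tailShift = 5)))),
        "unknown")
})

test_that("infinite capture steepness is a step function at the midpoint", {
    cfg <- SimConfig(nTranscripts = 10, libSize = 5000, seed = 17,
                     captureSteepness = Inf, captureMidpoint = 10,
                     oligoTranscriptFraction = 0.5, oligoWeight = 0.3)
    tv <- simulateTotalVsPolyA(cfg)
    expect_true(all(tv$polyA$polya_length > 10))
    lost <- setdiff(tv$total$read_id, tv$polyA$read_id)
    expect_true(all(tv$total$polya_length[tv$total$read_id %in% lost] <= 10))
    # poly(A)+ reads are a subset of total reads
    expect_true(all(tv$polyA$read_id %in% tv$total$read_id))
})

test_that("without oligo reads, capture of long tails is near-lossless", {
    cfg <- SimConfig(nTranscripts = 10, libSize = 10000, seed = 23,
                     oligoTranscriptFraction = 0, oligoWeight = 0,
                     wtTailMeanHigh = 40, wtTailMeanLow = 60, tailSd = 3,
                     estimationNoiseSd = 0, captureMidpoint = 10,
                     captureSteepness = 1, qcFailRate = 0)
    tv <- simulateTotalVsPolyA(cfg)
    ratio <- nrow(tv$total) / nrow(tv$polyA)
    expect_lt(abs(ratio - 1), 0.01)
})

test_that("oligo component inflates the total/poly(A)+ count ratio as derived", {
    cfg <- SimConfig(nTranscripts = 1, libSize = 5000, seed = 29,
                     oligoTranscriptFraction = 1, oligoWeight = 0.4,
                     oligoTailMax = 9,
                     wtTailMeanHigh = 40, wtTailMeanLow = 40, tailSd = 3,
                     estimationNoiseSd = 0, captureMidpoint = 10,
                     captureSteepness = Inf, qcFailRate = 0)
    tv <- simulateTotalVsPolyA(cfg)
    # analytic retention: oligo reads (tails < 10) all lost, rest kept
    # up to the negligible P(N(40,3) <= 10) tail
    ratio <- nrow(tv$total) / nrow(tv$polyA)
    se <- sqrt(0.6 * 0.4 / 5000) / 0.6^2  # delta-method SE of 1/p-hat
    expect_lt(abs(ratio - 1 / 0.6), 3 * se)
})

test_that("spike-in simulation reproduces designed lengths", {
    sp0 <- simulateSpikeins(c(10, 90), nReadsEach = 50, noiseSd = 0,
                            seed = 2)
    m <- tapply(sp0$polya_length, sp0$designed_length, mean)
    expect_equal(as.numeric(m), c(10, 90))

    sp <- simulateSpikeins(seq(10, 90, by = 10), nReadsEach = 2000,
                           noiseSd = 2, seed = 2)
    expect_equal(length(unique(sp$transcript_id)), 9L)
    expect_true(all(sp$qc_tag == "PASS"))
    m <- tapply(sp$polya_length, sp$designed_length, mean)
    expect_true(all(abs(m - seq(10, 90, by = 10)) < 3 * 2 / sqrt(2000)))

    expect_error(simulateSpikeins(numeric(0)), "empty")
    expect_error(simulateSpikeins(c(10, -5)), "positive")
})
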