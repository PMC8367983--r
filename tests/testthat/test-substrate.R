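test_that("deltas cover exactly the transcripts detected in both tables", {
    ref <- makeSummary(c("a", "b", "c"), c(100L, 100L, 100L), c(40, 50, 60))
    mut <- makeSummary(c("a", "b", "c"), c(100L, 4L, 100L), c(45, 50, 58))
    d <- computeDeltas(mut, ref)
    expect_setequal(d$transcript_id, c("a", "c"))  # b placeholder in mutant
    expect_equal(d$delta_mean_tail[d$transcript_id == "a"], 5)

    same <- computeDeltas(ref, ref)
    expect_true(all(same$delta_mean_tail == 0))
    expect_true(all(same$log2_fold_change_abundance == 0))
})

test_that("deltas match element-wise brute-force recomputation", {
    set.seed(31)
    ids <- sprintf("t%02d", 1:40)
    cA <- as.integer(sample(6:500, 40)); cB <- as.integer(sample(6:500, 40))
    tA <- runif(40, 20, 70); tB <- runif(40, 20, 70)
    A <- makeSummary(ids, cA, tA); B <- makeSummary(ids, cB, tB)
    d <- computeDeltas(A, B)
    i <- match(d$transcript_id, ids)
    expect_equal(d$delta_mean_tail, tA[i] - tB[i])
    expect_equal(d$log2_fold_change_abundance,
                 log2((cA[i] / sum(cA)) / (cB[i] / sum(cB))))
})

test_that("strong-target rule is boundary-inclusive at ten adenosines", {
    d <- data.frame(transcript_id = c("x", "y", "z"),
                    delta_mean_tail = c(10.0, 9.99, 25),
                    log2_fold_change_abundance = 0)
    expect_setequal(flagStrongTargets(d), c("x", "z"))
    # raising the threshold never adds transcripts
    expect_true(all(flagStrongTargets(d, 15) %in% flagStrongTargets(d, 10)))
    expect_true(all(flagStrongTargets(d, 10) %in% flagStrongTargets(d, 5)))
})

test_that("null delta flagging matches the normal tail probability", {
    set.seed(41)
    n <- 20000
    d <- data.frame(transcript_id = sprintf("t%05d", 1:n),
                    delta_mean_tail = rnorm(n, 0, 3.3),
                    log2_fold_change_abundance = 0)
    frac <- length(flagStrongTargets(d)) / n
    p <- pnorm(10, 0, 3.3, lower.tail = FALSE)
    expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("substrate categories partition the annotated mRNA set", {
    ann <- sprintf("m%03d", 1:100)
    det <- ann[1:80]
    exo <- ann[1:30]
    pan2 <- ann[21:45]
    ccr4 <- ann[40:55]
    cl <- classifySubstrates(exo, pan2, ccr4, det, ann)
    expect_equal(nrow(cl), 100L)
    expect_equal(sum(table(cl$category)), 100)

    # brute-force set algebra per transcript
    for (id in ann[c(1, 25, 42, 50, 60, 90)]) {
        inExo <- id %in% exo
        inCyt <- id %in% pan2 || id %in% ccr4
        want <- if (!(id %in% det)) "undetected"
                else if (inExo && inCyt) "both"
                else if (inExo) "exosome_only"
                else if (inCyt) "cytoplasmic_only" else "unaffected"
        expect_equal(as.character(cl$category[cl$transcript_id == id]),
                     want)
    }
    expect_equal(cl$ccr4_target, ann %in% ccr4)
    expect_error(classifySubstrates("nope", pan2, ccr4, det, ann),
                 "outside")
})

test_that("random substrate sets reproduce brute-force category counts", {
    set.seed(51)
    ann <- sprintf("g%03d", 1:100)
    for (i in 1:10) {
        det <- sample(ann, sample(50:100, 1))
        exo <- sample(det, sample(0:40, 1))
        pan2 <- sample(det, sample(0:40, 1))
        ccr4 <- sample(det, sample(0:40, 1))
        cl <- classifySubstrates(exo, pan2, ccr4, det, ann)
        counts <- table(cl$category)
        cyt <- union(pan2, ccr4)
        expect_equal(unname(counts["both"]),
                     length(intersect(exo, cyt)))
        expect_equal(unname(counts["exosome_only"]),
                     length(setdiff(exo, cyt)))
        expect_equal(unname(counts["cytoplasmic_only"]),
                     length(setdiff(cyt, exo)))
        expect_equal(unname(counts["undetected"]),
                     length(ann) - length(det))
        expect_equal(sum(counts), length(ann))
    }
})

test_that("substrate fractions reproduce the category arithmetic", {
    fr <- substrateFractions(c(exosome_only = 1643, cytoplasmic_only = 625,
                               both = 1588),
                             nDetected = 4665, nAnnotated = 6230)
    expect_equal(unname(fr["n_substrates"]), 3856)
    expect_equal(unname(fr["pct_of_detected"]), 100 * 3856 / 4665)
    expect_equal(unname(fr["pct_of_annotated"]), 100 * 3856 / 6230)

    empty <- substrateFractions(c(exosome_only = 0, cytoplasmic_only = 0,
                                  both = 0),
                                nDetected = 10, nAnnotated = 20)
    expect_equal(unname(empty["pct_of_detected"]), 0)
    expect_equal(unname(empty["pct_of_annotated"]), 0)

    expect_error(substrateFractions(
        c(exosome_only = 1, cytoplasmic_only = 1, both = 1),
        nDetected = 0, nAnnotated = 5), "denominator")
    expect_error(substrateFractions(
        c(exosome_only = 1, cytoplasmic_only = 1, both = 1),
        nDetected = 10, nAnnotated = 5), ">=")

    # data-frame input derives its own denominators
    ann <- sprintf("m%02d", 1:50)
    cl <- classifySubstrates(ann[1:10], ann[11:15], ann[14:20], ann[1:40],
                             ann)
    fr2 <- substrateFractions(cl)
    expect_equal(unname(fr2["n_substrates"]), 20)
    expect_equal(unname(fr2["pct_of_detected"]), 50)
    expect_equal(unname(fr2["pct_of_annotated"]), 40)
})
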